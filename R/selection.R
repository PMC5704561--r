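# Pairwise dN/dS by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction, plus per-group median summaries.
#
# Conventions (standard NG86): synonymous site counts average the fraction
# of synonymous single-nucleotide changes at each codon position; changes
# to stop codons count as nonsynonymous, so S + N = 3 x codons identically.
# Between codons differing at 2-3 positions, mutational pathways are
# averaged uniformly over orderings, excluding pathways that cross a stop
# codon (if every pathway crosses a stop, all are used with stop-crossing
# steps counted as nonsynonymous).

# Per-codon synonymous site count (sum over positions of the fraction of
# synonymous changes among the three alternatives).
#' @noRd
syn_sites <- function() {
  if (!is.null(.pkg_cache$SYN_SITES)) return(.pkg_cache$SYN_SITES)
  gc <- genetic_code()
  codons <- sense_codons()
  s <- vapply(codons, function(cod) {
    aa <- gc[cod]
    tot <- 0
    for (p in 1:3) for (nt in NUC4) {
      if (substr(cod, p, p) == nt) next
      mut <- cod
      substr(mut, p, p) <- nt
      if (gc[mut] != "*" && gc[mut] == aa) tot <- tot + 1 / 3
    }
    tot
  }, numeric(1))
  .pkg_cache$SYN_SITES <- s
  s
}

# Average (sd, nd) over mutational pathways between two codons.
#' @noRd
codon_path_diffs <- function(c1, c2) {
  gc <- genetic_code()
  pos <- which(chars(c1) != chars(c2))
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(pos) else
    if (d == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  walk <- function(order, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*") {
        if (!allow_stop) return(NULL)
        nd <- nd + 1
      } else if (gc[nxt] == gc[cur] && gc[cur] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' Pairwise dN/dS (Nei-Gojobori 1986 with Jukes-Cantor correction)
#'
#' Codon columns containing a gap in either row are skipped. Site counts
#' are averaged between the two sequences; raw proportions ps = sd/S,
#' pn = nd/N are corrected by d = -(3/4) ln(1 - 4p/3). The ratio is flagged
#' invalid when either proportion reaches the correction domain limit
#' (p >= 0.75) or dS = 0.
#'
#' @param a,b equal-length in-frame aligned CDS strings (lengths divisible
#'   by 3).
#' @param id_a,id_b optional pair identifiers carried into the result.
#' @return list of class \code{dnds_result}: dN, dS, ratio, ps, pn, S, N,
#'   codons_compared, valid.
#' @export
ng86_pair <- function(a, b, id_a = "a", id_b = "b") {
  if (nchar(a) != nchar(b)) stop("aligned CDS rows differ in length")
  if (nchar(a) %% 3 != 0) stop("length not divisible by 3")
  ca <- split_codons(a); cb <- split_codons(b)
  ok <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[ok]; cb <- cb[ok]
  gc <- genetic_code()
  if (any(gc[ca] == "*") || any(gc[cb] == "*"))
    stop("internal stop codon in compared region")
  ss <- syn_sites()
  S <- sum((ss[ca] + ss[cb]) / 2)
  L <- length(ca)
  N <- 3 * L - S
  sd <- 0; nd <- 0
  for (k in seq_len(L)) {
    if (ca[k] == cb[k]) next
    dd <- codon_path_diffs(ca[k], cb[k])
    sd <- sd + unname(dd["sd"]); nd <- nd + unname(dd["nd"])
  }
  S <- unname(S); N <- unname(N)
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(ps); dN <- jc(pn)
  valid <- !is.na(dS) && !is.na(dN) && dS > 0
  structure(list(id_a = id_a, id_b = id_b,
                 dN = dN, dS = dS,
                 ratio = if (valid) dN / dS else NA_real_,
                 ps = ps, pn = pn, S = S, N = N,
                 codons_compared = L, valid = valid),
            class = "dnds_result")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each protein gap to a 3-nucleotide gap and enforces that every
#' ungapped codon translates to the aligned protein residue.
#'
#' @param protein_aln an \code{msa} of kind \code{"protein"}.
#' @param cds a \code{seq_records} set of kind \code{"cds"} containing a
#'   record for every alignment row (matched by id).
#' @return an \code{msa} of kind \code{"cds"} (one protein column = one
#'   codon column).
#' @export
backtranslate <- function(protein_aln, cds) {
  rows <- character(length(protein_aln$ids))
  for (i in seq_along(protein_aln$ids)) {
    id <- protein_aln$ids[i]
    k <- match(id, cds$id)
    if (is.na(k)) stop("no CDS for alignment row ", id)
    nt <- ungap(cds$residues[k])
    aa_aln <- chars(protein_aln$seqs[i])
    aa <- aa_aln[aa_aln != "-"]
    tr <- chars(translate_cds(nt))
    # tolerate a trailing stop codon on the CDS
    if (length(tr) == length(aa) + 1 && tr[length(tr)] == "*") {
      tr <- tr[-length(tr)]
      nt <- substr(nt, 1, nchar(nt) - 3)
    }
    if (length(tr) != length(aa) || any(tr != aa)) {
      pos <- if (length(tr) != length(aa)) min(length(tr), length(aa)) + 1 else
        which(tr != aa)[1]
      stop(sprintf("translation mismatch for row %s at residue %d", id, pos))
    }
    cods <- split_codons(nt)
    out <- rep("---", length(aa_aln))
    out[aa_aln != "-"] <- cods
    rows[i] <- paste(out, collapse = "")
  }
  msa(protein_aln$ids, protein_aln$genome_ids, rows, kind = "cds")
}

#' Per-group median dN/dS
#'
#' @param results list of \code{dnds_result}s.
#' @param labels named character vector mapping sequence/gene id to a group
#'   label (e.g. \code{"CAS"} or \code{"solo"}); a pair belongs to a group
#'   when both members carry the label.
#' @return list with \code{medians} (named numeric over groups with >= 1
#'   valid ratio; groups with none are absent) and \code{counts} (data
#'   frame group, n_valid, n_invalid).
#' @export
group_medians <- function(results, labels) {
  grp <- vapply(results, function(r) {
    la <- labels[r$id_a]; lb <- labels[r$id_b]
    if (is.na(la) || is.na(lb) || la != lb) NA_character_ else unname(la)
  }, character(1))
  ratio <- vapply(results, function(r) if (isTRUE(r$valid)) r$ratio else NA_real_,
                  numeric(1))
  keep <- !is.na(grp)
  grp <- grp[keep]; ratio <- ratio[keep]
  groups <- sort(unique(grp))
  counts <- data.frame(group = groups,
                       n_valid = vapply(groups, function(g) sum(!is.na(ratio[grp == g])), integer(1)),
                       n_invalid = vapply(groups, function(g) sum(is.na(ratio[grp == g])), integer(1)),
                       stringsAsFactors = FALSE)
  meds <- vapply(groups, function(g) median(ratio[grp == g], na.rm = TRUE),
                 numeric(1))
  meds <- meds[counts$n_valid > 0]
  list(medians = meds, counts = counts)
}
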