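# BLASTCLUST-style greedy clustering by identity + coverage, progressive
# profile alignment within clusters, and the alignment-column filter
# (gap fraction > 0.5 OR homogeneity < 0.1 removes a column).

#' Multiple sequence alignment container
#'
#' Rows are gapped sequences of equal length; \code{column_mask} records
#' which columns are kept after filtering. Ungapping any row reproduces its
#' input sequence exactly.
#'
#' @param ids,genome_ids,seqs parallel vectors of row metadata and gapped
#'   sequences.
#' @param kind \code{"protein"}, \code{"cds"} or \code{"rrna"}.
#' @param column_mask logical keep-vector, defaults to all \code{TRUE}.
#' @return an object of class \code{msa}.
#' @export
msa <- function(ids, genome_ids, seqs, kind = "protein", column_mask = NULL) {
  w <- unique(nchar(seqs))
  if (length(w) > 1) stop("alignment rows have unequal lengths")
  w <- if (length(w)) w else 0L
  if (is.null(column_mask)) column_mask <- rep(TRUE, w)
  if (length(column_mask) != w) stop("column_mask length != alignment width")
  structure(list(ids = as.character(ids),
                 genome_ids = as.character(genome_ids),
                 seqs = as.character(seqs), kind = kind,
                 column_mask = column_mask,
                 column_stats = NULL),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns (%d kept), kind=%s\n",
              length(x$seqs), length(x$column_mask), sum(x$column_mask),
              x$kind))
  invisible(x)
}

#' @noRd
ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Pairwise global alignment identity and coverage
#'
#' Needleman-Wunsch/Gotoh global alignment (BLOSUM62 for proteins; +1/-1 for
#' nucleotides) with affine gaps. Identity is matches over aligned columns
#' excluding terminal-gap columns (internal gaps count as mismatches);
#' coverage of each sequence is the fraction of its residues inside the
#' terminal-gap-trimmed region. Symmetric: swapping the arguments swaps the
#' coverages and preserves identity.
#'
#' @param a,b residue strings (same alphabet), or single-row
#'   \code{seq_records}.
#' @param kind \code{"protein"} or \code{"nucleotide"}.
#' @return list with \code{identity}, \code{coverage_a}, \code{coverage_b},
#'   \code{score}.
#' @export
pairwise_identity <- function(a, b, kind = "protein") {
  if (is.data.frame(a)) { kind <- if (a$kind[1] == "protein") "protein" else "nucleotide"; a <- a$residues[1] }
  if (is.data.frame(b)) b <- b$residues[1]
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  kind <- match.arg(kind, c("protein", "nucleotide"))
  sm <- score_matrix_for(if (kind == "protein") "protein" else "nucleotide")
  g <- gap_costs(if (kind == "protein") "protein" else "nucleotide")
  ca <- chars(a); cb <- chars(b)
  S <- sm[ca, cb, drop = FALSE]
  al <- affine_align_cpp(S, g["open"], g["ext"], 0L, FALSE)
  ai <- al$a; bi <- al$b
  ncol_all <- length(ai)
  gapcol <- ai == 0L | bi == 0L
  # trim terminal gap runs
  keep <- rep(TRUE, ncol_all)
  k <- 1L
  while (k <= ncol_all && gapcol[k]) { keep[k] <- FALSE; k <- k + 1L }
  k <- ncol_all
  while (k >= 1L && gapcol[k]) { keep[k] <- FALSE; k <- k - 1L }
  core <- which(keep)
  if (length(core) == 0L)
    return(list(identity = 0, coverage_a = 0, coverage_b = 0, score = al$score))
  m <- sum(ai[core] > 0L & bi[core] > 0L & ca[pmax(ai[core], 1L)] == cb[pmax(bi[core], 1L)] &
             ai[core] > 0L)
  identity <- m / length(core)
  list(identity = identity,
       coverage_a = sum(ai[core] > 0L) / length(ca),
       coverage_b = sum(bi[core] > 0L) / length(cb),
       score = al$score)
}

#' All-against-all identity matrix
#' @noRd
identity_matrix <- function(records) {
  n <- nrow(records)
  kind <- if (records$kind[1] == "protein") "protein" else "nucleotide"
  idm <- matrix(1, n, n, dimnames = list(records$id, records$id))
  cvm <- matrix(1, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      p <- pairwise_identity(records$residues[i], records$residues[j], kind)
      idm[i, j] <- idm[j, i] <- p$identity
      cvm[i, j] <- cvm[j, i] <- min(p$coverage_a, p$coverage_b)
    }
  }
  list(identity = idm, min_coverage = cvm)
}

#' Greedy single-linkage clustering by identity and coverage
#'
#' BLASTCLUST-style: two sequences are linked when global-alignment identity
#' is at least \code{identity_threshold} and both coverages are at least
#' \code{coverage_threshold}; clusters are the connected components of the
#' resulting graph. Clusters are ordered by decreasing size, ties broken by
#' the lexicographically smallest member; the result is invariant to input
#' order.
#'
#' @param records a \code{seq_records} data frame (at least one sequence).
#' @param identity_threshold,coverage_threshold fractions in [0,1]. The
#'   defaults are the family-protein thresholds (0.5 identity, 0.8
#'   coverage); use 0.9/0.9 for 16S rRNA.
#' @return an object of class \code{cluster_set}: list with \code{clusters}
#'   (list of member-id vectors) and \code{members} (data frame cluster_id,
#'   member_id).
#' @export
greedy_cluster <- function(records, identity_threshold = 0.5,
                           coverage_threshold = 0.8) {
  if (nrow(records) < 1) stop("need at least one sequence")
  stopifnot(identity_threshold >= 0, identity_threshold <= 1,
            coverage_threshold >= 0, coverage_threshold <= 1)
  ord <- order(records$id)
  records <- records[ord, , drop = FALSE]  # input-order invariance
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (n >= 2) {
    m <- identity_matrix(records)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (m$identity[i, j] >= identity_threshold &&
          m$min_coverage[i, j] >= coverage_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(records$id, comp)
  groups <- lapply(groups, sort)
  sizes <- lengths(groups)
  firsts <- vapply(groups, `[`, character(1), 1)
  groups <- groups[order(-sizes, firsts)]
  names(groups) <- sprintf("C%03d", seq_along(groups))
  members <- data.frame(
    cluster_id = rep(names(groups), lengths(groups)),
    member_id = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(clusters = groups, members = members,
                 params = list(identity_threshold = identity_threshold,
                               coverage_threshold = coverage_threshold)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d sequences (sizes: %s)\n",
              length(x$clusters), nrow(x$members),
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

# Column frequency matrix over the residue alphabet, gaps diluting
# (f = count / nrows). Used for guide-tree-free profile merging scores.
#' @noRd
merge_freqs <- function(seqs, alphabet) {
  m <- seq_char_matrix(seqs)
  f <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = alphabet))
    as.numeric(tab) / nrow(m)
  }, numeric(length(alphabet)))
  rownames(f) <- alphabet
  f
}

# Align two alignments by profile-profile global alignment; returns merged
# gapped rows (rows of x then rows of y).
#' @noRd
merge_alignments <- function(xseqs, yseqs, kind) {
  alphabet <- if (kind == "protein") AA20 else NUC4
  sm <- score_matrix_for(if (kind == "protein") "protein" else "nucleotide")
  g <- gap_costs(if (kind == "protein") "protein" else "nucleotide")
  fx <- merge_freqs(xseqs, alphabet); fy <- merge_freqs(yseqs, alphabet)
  S <- t(fx) %*% sm %*% fy
  al <- affine_align_cpp(S, g["open"], g["ext"], 0L, FALSE)
  mx <- seq_char_matrix(xseqs); my <- seq_char_matrix(yseqs)
  ncols <- length(al$a)
  outx <- matrix("-", nrow(mx), ncols)
  outy <- matrix("-", nrow(my), ncols)
  ix <- al$a > 0L; iy <- al$b > 0L
  outx[, ix] <- mx[, al$a[ix], drop = FALSE]
  outy[, iy] <- my[, al$b[iy], drop = FALSE]
  c(collapse_rows(outx), collapse_rows(outy))
}

#' Progressive multiple alignment of a sequence set
#'
#' UPGMA guide tree on (1 - pairwise identity) distances, then
#' profile-profile Needleman-Wunsch merges up the guide tree (column score
#' is the frequency-weighted sum-of-pairs substitution score, affine gaps).
#' Ungapping any output row reproduces its input sequence; deterministic.
#'
#' @param records a \code{seq_records} data frame (>= 1 sequence).
#' @return an \code{msa}.
#' @export
progressive_align <- function(records) {
  if (nrow(records) < 1) stop("need at least one sequence")
  kind <- records$kind[1]
  if (nrow(records) == 1)
    return(msa(records$id, records$genome_id, records$residues, kind))
  if (nrow(records) == 2) {
    merged <- merge_alignments(records$residues[1], records$residues[2], kind)
    return(msa(records$id, records$genome_id, merged, kind))
  }
  m <- identity_matrix(records)
  D <- as.dist(1 - m$identity)
  hc <- hclust(D, method = "average")
  node_aln <- vector("list", nrow(records) + nrow(hc$merge))
  node_rows <- vector("list", length(node_aln))
  n <- nrow(records)
  get_node <- function(k) if (k < 0) list(aln = records$residues[-k], rows = -k) else
    list(aln = node_aln[[n + k]], rows = node_rows[[n + k]])
  for (s in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[s, 1]); b <- get_node(hc$merge[s, 2])
    merged <- merge_alignments(a$aln, b$aln, kind)
    node_aln[[n + s]] <- merged
    node_rows[[n + s]] <- c(a$rows, b$rows)
  }
  rows <- node_rows[[n + nrow(hc$merge)]]
  aln <- node_aln[[n + nrow(hc$merge)]]
  ord <- order(rows)
  msa(records$id[rows][ord], records$genome_id[rows][ord], aln[ord], kind)
}

#' @noRd
column_gap_fraction <- function(colv) mean(colv == "-")

# Fraction of identical unordered residue pairs among non-gap residues in a
# column; 1.0 when fewer than 2 non-gap residues.
#' @noRd
column_homogeneity <- function(colv) {
  r <- colv[colv != "-"]
  n <- length(r)
  if (n < 2) return(1.0)
  tab <- table(r)
  sum(choose(tab, 2)) / choose(n, 2)
}

#' Filter alignment columns by gap fraction and homogeneity
#'
#' A column is removed (masked out) iff its gap fraction exceeds
#' \code{max_gap_fraction} or its homogeneity falls below
#' \code{min_homogeneity}. Homogeneity is the fraction of identical
#' unordered residue pairs among the column's non-gap residues (1.0 for
#' fewer than two residues). Idempotent; kept columns are never reordered.
#'
#' @param aln an \code{msa}.
#' @param max_gap_fraction,min_homogeneity thresholds (defaults 0.5, 0.1).
#' @return the \code{msa} with \code{column_mask} and \code{column_stats}
#'   updated.
#' @export
filter_columns <- function(aln, max_gap_fraction = 0.5, min_homogeneity = 0.1) {
  w <- length(aln$column_mask)
  if (w == 0) stop("alignment has zero columns")
  m <- seq_char_matrix(aln$seqs)
  gf <- apply(m, 2, column_gap_fraction)
  hom <- apply(m, 2, column_homogeneity)
  keep <- !(gf > max_gap_fraction | hom < min_homogeneity)
  aln$column_mask <- keep
  aln$column_stats <- data.frame(column = seq_len(w), kept = keep,
                                 gap_fraction = gf, homogeneity = hom)
  aln
}

#' Sequence profile: per-column residue frequencies
#'
#' Frequencies are computed on kept columns only, gaps excluded from the
#' denominator, with an add-1/20 pseudocount:
#' f(a) = (count(a) + 0.05) / (n_nongap + 1). Columns with no residues are
#' flagged empty.
#'
#' @param aln an \code{msa} with at least one kept column.
#' @return an object of class \code{seq_profile} with \code{freq} (alphabet
#'   x kept-columns matrix), \code{empty} flags, \code{n_seq} and
#'   \code{kind}.
#' @export
build_profile <- function(aln) {
  keep <- which(aln$column_mask)
  if (length(keep) == 0) stop("empty profile: all columns masked")
  alphabet <- if (aln$kind == "protein") AA20 else NUC4
  m <- seq_char_matrix(aln$seqs)[, keep, drop = FALSE]
  K <- length(alphabet)
  freq <- vapply(seq_len(ncol(m)), function(j) {
    r <- m[, j]; r <- r[r != "-"]
    n <- length(r)
    if (n == 0) return(rep(0, K))
    tab <- table(factor(r, levels = alphabet))
    (as.numeric(tab) + 1 / K) / (n + 1)
  }, numeric(K))
  freq <- matrix(freq, nrow = K, dimnames = list(alphabet, NULL))
  structure(list(freq = freq,
                 empty = colSums(freq) == 0,
                 n_seq = length(aln$seqs),
                 kind = aln$kind),
            class = "seq_profile")
}
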