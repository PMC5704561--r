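# Genomic-context classification of family members: CRISPR-associated
# (CAS), solo, or MGE-resident, plus adaptation-module arrangement typing
# and weighted presence/absence summaries.

CAS_EVIDENCE <- c("cas1", "cas2", "cas6", "crispr_array")

#' Detect a cas4/cas1 fusion annotation
#'
#' Fused genes count as CRISPR-associated regardless of neighbors.
#'
#' @param annotation annotation string (or a single feature row).
#' @return logical.
#' @export
fusion_detect <- function(annotation) {
  if (is.data.frame(annotation)) annotation <- annotation$annotation
  annotation == "cas4/cas1 fusion"
}

# Match the window's annotation sequence against the typical adaptation
# module arrangements (either reading direction); the matched segment must
# contain the focal gene. Longer (more specific) patterns win.
#' @noRd
match_arrangement <- function(ann, focal) {
  pats <- list("cas4-cas1-cas2-cas6" = c("cas4", "cas1", "cas2", "cas6"),
               "two-cas4" = c("cas4", "cas4", "cas1", "cas2"),
               "cas4-cas1-cas2" = c("cas4", "cas1", "cas2"),
               "fusion-cas2" = c("cas4/cas1 fusion", "cas2"))
  for (nm in names(pats)) {
    p <- pats[[nm]]
    for (dir in 1:2) {
      a <- if (dir == 1) ann else rev(ann)
      f <- if (dir == 1) focal else rev(focal)
      L <- length(a)
      if (L < length(p)) next
      for (s in seq_len(L - length(p) + 1)) {
        e <- s + length(p) - 1
        if (all(a[s:e] == p) && any(f[s:e])) return(nm)
      }
    }
  }
  "none"
}

#' Classify one family gene by genomic context
#'
#' CAS if any cas1/cas2/cas6/effector/crispr_array feature lies within
#' \code{window_genes} features on the same contig (or the gene itself is a
#' cas4/cas1 fusion); otherwise MGE if the contig's replicon class is viral
#' or plasmid or an mge_marker lies within the window; otherwise solo.
#'
#' @param gene_id id of the family gene (must be present in
#'   \code{features}).
#' @param features a \code{gene_features} table (the gene's contig is
#'   extracted from it).
#' @param window_genes neighborhood radius in genes (default 10; the
#'   operational cutoff separating "associated" from solo is not a
#'   published constant and is configurable).
#' @return list of class \code{locus_classification}: gene_id, category
#'   (CAS/solo/MGE), arrangement, standalone_adaptation_module, subtype
#'   (effector subtype label in the window or NA), evidence (neighbor
#'   annotations supporting the call).
#' @export
classify_locus <- function(gene_id, features, window_genes = 10) {
  k <- match(gene_id, features$gene_id)
  if (is.na(k)) stop("gene not found in feature table: ", gene_id)
  contig <- features$contig_id[k]
  nb <- features[features$contig_id == contig, , drop = FALSE]
  nb <- nb[order(nb$start), , drop = FALSE]
  i <- match(gene_id, nb$gene_id)
  win <- nb[max(1, i - window_genes):min(nrow(nb), i + window_genes), ,
            drop = FALSE]
  wi <- match(gene_id, win$gene_id)
  ann <- win$annotation
  is_eff <- grepl("^effector", ann)
  cas_ev <- ann %in% CAS_EVIDENCE | is_eff
  cas_ev[wi] <- FALSE
  fused <- fusion_detect(nb$annotation[i])
  category <-
    if (fused || any(cas_ev)) "CAS"
    else if (features$replicon_class[k] %in% c("viral", "plasmid") ||
             any(ann[-wi] == "mge_marker")) "MGE"
    else "solo"
  arrangement <- if (category == "CAS")
    match_arrangement(ann, seq_along(ann) == wi) else "none"
  subtype <- if (any(is_eff))
    sub("^effector_", "", ann[is_eff][1]) else NA_character_
  standalone <- category == "CAS" && any(ann == "cas1") &&
    any(ann == "cas2") && !any(is_eff)
  evidence <- ann[(cas_ev | ann == "mge_marker")]
  structure(list(gene_id = gene_id, category = category,
                 arrangement = arrangement,
                 standalone_adaptation_module = standalone,
                 subtype = subtype, evidence = evidence),
            class = "locus_classification")
}

#' Classify many family genes
#'
#' @param gene_ids character vector of family gene ids.
#' @param features a \code{gene_features} table.
#' @param window_genes neighborhood radius.
#' @return data frame: gene_id, genome_id, category, arrangement,
#'   standalone_adaptation_module, subtype.
#' @export
classify_all <- function(gene_ids, features, window_genes = 10) {
  res <- lapply(gene_ids, classify_locus, features = features,
                window_genes = window_genes)
  data.frame(
    gene_id = gene_ids,
    genome_id = features$genome_id[match(gene_ids, features$gene_id)],
    category = vapply(res, `[[`, character(1), "category"),
    arrangement = vapply(res, `[[`, character(1), "arrangement"),
    standalone_adaptation_module =
      vapply(res, `[[`, logical(1), "standalone_adaptation_module"),
    subtype = vapply(res, `[[`, character(1), "subtype"),
    stringsAsFactors = FALSE)
}

#' Per-species genome weights
#'
#' Each genome's weight is inversely proportional to the number of genomes
#' of its species, so weights within a species sum to 1.
#'
#' @param genomes data frame with columns genome_id, species_id.
#' @return data frame genome_id, species_id, weight.
#' @export
genome_weights <- function(genomes) {
  stopifnot(all(c("genome_id", "species_id") %in% names(genomes)))
  n <- table(genomes$species_id)
  data.frame(genome_id = genomes$genome_id,
             species_id = genomes$species_id,
             weight = 1 / as.numeric(n[genomes$species_id]),
             stringsAsFactors = FALSE)
}

#' Weighted presence/absence summary per domain
#'
#' For each domain (e.g. archaea/bacteria) the weighted fractions of
#' genomes with CAS members only, solo members only, both, or neither.
#' MGE-only genomes count as neither (members outside characterized
#' cellular contexts). The four fractions partition each domain and sum
#' to 1.
#'
#' @param classifications data frame with genome_id and category (from
#'   [classify_all()]).
#' @param weights data frame genome_id, weight (see [genome_weights()]);
#'   every genome to be summarized must be present.
#' @param domains named character vector genome_id -> domain label.
#' @return data frame: domain, cas_only, solo_only, both, neither.
#' @export
presence_summary <- function(classifications, weights, domains) {
  genomes <- weights$genome_id
  if (anyNA(domains[genomes])) stop("missing domain label for a genome")
  has_cas <- genomes %in%
    classifications$genome_id[classifications$category == "CAS"]
  has_solo <- genomes %in%
    classifications$genome_id[classifications$category == "solo"]
  cls <- ifelse(has_cas & has_solo, "both",
                ifelse(has_cas, "cas_only",
                       ifelse(has_solo, "solo_only", "neither")))
  out <- lapply(split(seq_along(genomes), domains[genomes]), function(idx) {
    w <- weights$weight[idx]
    tot <- sum(w)
    vapply(c("cas_only", "solo_only", "both", "neither"),
           function(cat) sum(w[cls[idx] == cat]) / tot, numeric(1))
  })
  df <- do.call(rbind, out)
  data.frame(domain = rownames(df), df, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Species-deduplicated counts per category (and CAS subtype)
#'
#' Within each counting group (solo, MGE, and CAS split by effector
#' subtype), each species contributes at most one genome; the
#' representative is the lexicographically smallest genome id.
#'
#' @param classifications data frame from [classify_all()].
#' @param species named character vector genome_id -> species_id.
#' @return data frame group, count.
#' @export
one_per_species_counts <- function(classifications, species) {
  grp <- ifelse(classifications$category == "CAS",
                paste0("CAS:", ifelse(is.na(classifications$subtype),
                                      "unknown", classifications$subtype)),
                classifications$category)
  sp <- species[classifications$genome_id]
  if (anyNA(sp)) stop("missing species assignment for a genome")
  df <- data.frame(group = grp, species = sp,
                   genome = classifications$genome_id,
                   stringsAsFactors = FALSE)
  df <- df[order(df$genome), ]
  df <- df[!duplicated(df[c("group", "species")]), ]
  agg <- table(df$group)
  data.frame(group = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE)
}
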