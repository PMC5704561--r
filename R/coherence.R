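# HGT quantification: genome-pair distance tables from protein and rRNA
# trees under sentinel and shortest-distance rules, and their Spearman rank
# correlation ("coherence" between gene evolution and the species tree).

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths on the unique leaf-to-leaf path; symmetric with a
#' zero diagonal.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @return numeric matrix over leaves.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(!is.finite(tree$edge.length)))
    stop("tree has missing or non-finite branch lengths")
  stats::cophenetic(tree)
}

#' One side (protein or rRNA) of the coherence comparison
#'
#' Bundles the per-cluster trees (sequences in different elements were never
#' aligned together, so their cross distances take the sentinel value) with
#' the leaf-to-genome mapping. Singleton clusters enter as bare leaf ids.
#'
#' @param trees list of \code{phylo} trees (may be empty).
#' @param genome_of named character vector: leaf id -> genome id.
#' @param singletons character vector of leaf ids not in any tree.
#' @return an object of class \code{distance_side}.
#' @export
distance_side <- function(trees, genome_of, singletons = character()) {
  trees <- trees %||% list()
  dmats <- lapply(trees, patristic_distances)
  leaves <- c(unlist(lapply(dmats, rownames), use.names = FALSE), singletons)
  if (anyDuplicated(leaves)) stop("leaf ids duplicated across clusters")
  miss <- setdiff(leaves, names(genome_of))
  if (length(miss)) stop("no genome mapping for leaf: ", miss[1])
  group <- integer(0)
  for (k in seq_along(dmats))
    group <- c(group, setNames(rep(k, nrow(dmats[[k]])), rownames(dmats[[k]])))
  group <- c(group, setNames(rep(seq_along(singletons) + length(dmats),
                                 length(singletons)), singletons))
  structure(list(dmats = dmats, group = group,
                 genome_of = genome_of[leaves], leaves = leaves),
            class = "distance_side")
}

#' @noRd
side_pair_distance <- function(side, la, lb, sentinel) {
  ga <- side$group[la]; gb <- side$group[lb]
  if (ga == gb && ga <= length(side$dmats))
    side$dmats[[ga]][la, lb]
  else
    sentinel
}

#' Assemble the genome-pair distance table
#'
#' One row per unordered genome pair with at least one family member in
#' each genome on the protein side. The protein distance is the minimum
#' over all cross-genome member pairs of (tree distance if both members lie
#' in one aligned cluster tree, else the protein sentinel); the minimum is
#' taken after sentinel substitution, so one in-tree pair beats any
#' sentinel. rRNA distances are computed analogously with the rRNA
#' sentinel. Genomes absent from the rRNA side are omitted (not
#' sentineled).
#'
#' @param protein_side,rrna_side \code{distance_side} objects.
#' @param protein_sentinel high distance for protein pairs in never-aligned
#'   clusters (default 12).
#' @param rrna_sentinel high distance for rRNA pairs in never-aligned
#'   clusters (default 3).
#' @return data frame of class \code{genome_pair_table}: genome_a,
#'   genome_b (genome_a < genome_b), protein_distance, rrna_distance,
#'   protein_sentinel, rrna_sentinel (flags).
#' @export
assemble_pairs <- function(protein_side, rrna_side,
                           protein_sentinel = 12, rrna_sentinel = 3) {
  pg <- sort(unique(protein_side$genome_of))
  rg <- unique(rrna_side$genome_of)
  genomes <- intersect(pg, rg)
  if (length(genomes) < 2) stop("need at least two genomes with members")
  prot_members <- split(protein_side$leaves, protein_side$genome_of[protein_side$leaves])
  rrna_members <- split(rrna_side$leaves, rrna_side$genome_of[rrna_side$leaves])
  pairs <- combn(genomes, 2)
  n <- ncol(pairs)
  pd <- numeric(n); rd <- numeric(n); pf <- logical(n); rf <- logical(n)
  for (k in seq_len(n)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    best <- Inf
    for (la in prot_members[[a]]) for (lb in prot_members[[b]])
      best <- min(best, side_pair_distance(protein_side, la, lb,
                                           protein_sentinel))
    pd[k] <- best
    pf[k] <- best == protein_sentinel
    best <- Inf
    for (la in rrna_members[[a]]) for (lb in rrna_members[[b]])
      best <- min(best, side_pair_distance(rrna_side, la, lb, rrna_sentinel))
    rd[k] <- best
    rf[k] <- best == rrna_sentinel
  }
  out <- data.frame(genome_a = pairs[1, ], genome_b = pairs[2, ],
                    protein_distance = pd, rrna_distance = rd,
                    protein_sentinel = pf, rrna_sentinel = rf,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_pair_table", "data.frame")
  out
}

#' Spearman rank correlation of protein and rRNA distances
#'
#' Average ranks for ties (sentinel rows form large tie blocks).
#'
#' @param table a \code{genome_pair_table}, or a numeric vector (then
#'   \code{y} must be given).
#' @param y optional second numeric vector.
#' @return Spearman rho in [-1, 1].
#' @export
rank_correlation <- function(table, y = NULL) {
  if (is.data.frame(table)) {
    x <- table$protein_distance; y <- table$rrna_distance
  } else x <- table
  if (length(x) < 3) stop("need at least 3 rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  cor(x, y, method = "spearman")
}

#' Spearman correlation between two genes' distances for co-located pairs
#'
#' @param table_a,table_b \code{genome_pair_table}s over the same genome
#'   pairs (co-located gene pairs only).
#' @return Spearman rho.
#' @export
colocated_gene_correlation <- function(table_a, table_b) {
  ka <- paste(table_a$genome_a, table_a$genome_b)
  kb <- paste(table_b$genome_a, table_b$genome_b)
  if (length(ka) != length(kb) || !all(sort(ka) == sort(kb)))
    stop("tables cover different genome-pair sets")
  table_b <- table_b[match(ka, kb), ]
  if (length(ka) < 3) stop("need at least 3 rows")
  if (stats::sd(table_a$protein_distance) == 0 ||
      stats::sd(table_b$protein_distance) == 0)
    stop("undefined correlation: zero variance")
  cor(table_a$protein_distance, table_b$protein_distance,
      method = "spearman")
}
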