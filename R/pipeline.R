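# End-to-end orchestration: simulate -> cluster -> align -> merge -> trees
# -> coherence -> dN/dS -> locus classification, with a deterministic
# report.

#' @noRd
two_leaf_tree <- function(ids, d) {
  ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);", ids[1], d / 2,
                                ids[2], d / 2))
}

# Per-cluster trees from merged alignments: phylo for >= 2 rows (midpoint
# rooted), bare leaf id for singletons.
#' @noRd
cluster_subtrees <- function(alignments, model, bootstrap, seed) {
  out <- list()
  for (nm in names(alignments)) {
    a <- alignments[[nm]]
    n <- length(a$ids)
    if (n == 1) {
      out[[nm]] <- a$ids
    } else if (n == 2) {
      d <- aln_distances(a, model)[1, 2]
      out[[nm]] <- two_leaf_tree(a$ids, d)
    } else {
      tr <- nj_tree(a, model, bootstrap = bootstrap,
                    seed = derive_seed(seed, paste0("tree_", nm)))
      out[[nm]] <- midpoint_root(tr)
    }
  }
  out
}

#' @noRd
filtered_cluster_alignments <- function(records, cluster_set) {
  out <- list()
  for (nm in names(cluster_set$clusters)) {
    sub <- records[records$id %in% cluster_set$clusters[[nm]], , drop = FALSE]
    aln <- progressive_align(sub)
    aln <- filter_columns(aln)
    if (!any(aln$column_mask))  # pathological: keep everything rather than die
      aln$column_mask <- rep(TRUE, length(aln$column_mask))
    out[[nm]] <- aln
  }
  out
}

# identity between two gapped rows over shared non-gap columns
#' @noRd
row_identity <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) return(0)
  mean(ca[ok] == cb[ok])
}

#' Run the whole pipeline on one simulated family
#'
#' Simulates a family from \code{config}, clusters the proteins (identity
#' 0.5, coverage 0.8), aligns and filters within clusters, iteratively
#' merges clusters by profile self-score ratio, builds per-cluster NJ trees
#' and the cluster dendrogram, grafts them into one family tree, computes
#' the gene-vs-16S coherence statistic (sentinels 12/3, shortest-distance
#' rule), estimates pairwise dN/dS within clusters, and classifies every
#' family gene by genomic context. Re-running with the same config
#' reproduces an identical report.
#'
#' @param config a \code{sim_config}.
#' @param out_dir if non-NULL, stage outputs (FASTA/TSV/Newick/JSON) are
#'   written there.
#' @param bootstrap NJ bootstrap replicates (default 25 at desk scale).
#' @param window_genes classification window.
#' @param ratio_threshold cluster merge threshold (default 0.1).
#' @param dnds_identity_range protein identity window for dN/dS pair
#'   selection (default c(0.5, 0.95)).
#' @param max_dnds_pairs cap on scored pairs (deterministic id-order
#'   selection).
#' @return report list of class \code{pipeline_report}.
#' @export
run_all <- function(config, out_dir = NULL, bootstrap = 25,
                    window_genes = 10, ratio_threshold = 0.1,
                    dnds_identity_range = c(0.5, 0.95),
                    max_dnds_pairs = 500) {
  sim <- simulate_family(config)
  genome_of <- setNames(sim$gene_map$genome_id, sim$gene_map$gene_id)

  clusters <- greedy_cluster(sim$sequences$protein, 0.5, 0.8)
  alns <- filtered_cluster_alignments(sim$sequences$protein, clusters)
  merged <- iterative_merge(alns, ratio_threshold)
  subtrees <- cluster_subtrees(merged$alignments, "protein", bootstrap,
                               config$seed)
  family_tree <- if (length(subtrees) == 1) {
    st <- subtrees[[1]]
    if (is.character(st)) NULL else st
  } else {
    D <- similarity_to_distance(merged$scores, merged$self_scores)
    graft(upgma_tree(D), subtrees)
  }

  rclusters <- greedy_cluster(sim$sequences$rrna, 0.9, 0.9)
  ralns <- filtered_cluster_alignments(sim$sequences$rrna, rclusters)
  rsubtrees <- cluster_subtrees(ralns, "nucleotide", 0, config$seed)

  side_of <- function(subs, genome_map) {
    trees <- Filter(function(x) inherits(x, "phylo"), subs)
    singles <- unlist(Filter(is.character, subs), use.names = FALSE)
    distance_side(unname(trees), genome_map, singles %||% character())
  }
  prot_side <- side_of(subtrees, genome_of)
  rrna_map <- setNames(sim$sequences$rrna$genome_id, sim$sequences$rrna$id)
  rrna_side <- side_of(rsubtrees, rrna_map)
  pairs <- assemble_pairs(prot_side, rrna_side)
  rho <- tryCatch(rank_correlation(pairs), error = function(e) NA_real_)

  classes <- classify_all(sim$gene_map$gene_id, sim$features, window_genes)
  labels <- setNames(classes$category, classes$gene_id)

  dnds <- list()
  for (nm in names(merged$alignments)) {
    a <- merged$alignments[[nm]]
    if (length(a$ids) < 2) next
    caln <- backtranslate(a, sim$sequences$cds)
    cmb <- combn(seq_along(a$ids), 2)
    for (k in seq_len(ncol(cmb))) {
      if (length(dnds) >= max_dnds_pairs) break
      i <- cmb[1, k]; j <- cmb[2, k]
      idp <- row_identity(a$seqs[i], a$seqs[j])
      if (idp < dnds_identity_range[1] || idp > dnds_identity_range[2]) next
      dnds[[length(dnds) + 1]] <-
        ng86_pair(caln$seqs[i], caln$seqs[j], a$ids[i], a$ids[j])
    }
  }
  gm <- group_medians(dnds, labels)

  report <- list(
    config = unclass(config),
    n_sequences = nrow(sim$sequences$protein),
    n_clusters_initial = length(clusters$clusters),
    n_clusters_final = length(merged$alignments),
    cluster_sizes = unname(vapply(merged$alignments,
                                  function(a) length(a$ids), integer(1))),
    merge_log = merged$log,
    n_transfers = nrow(sim$transfer_events),
    coherence_rho = rho,
    n_genome_pairs = nrow(pairs),
    dnds_medians = as.list(gm$medians),
    dnds_counts = gm$counts,
    category_counts = as.list(table(classes$category)),
    truth_agreement = mean(
      c(CAS = "cas_operon", solo = "solo", MGE = "mge")[classes$category] ==
        sim$true_labels[classes$gene_id])
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$sequences$protein, file.path(out_dir, "family.faa"))
    write_fasta(sim$sequences$cds, file.path(out_dir, "family.fna"))
    write_fasta(sim$sequences$rrna, file.path(out_dir, "rrna.fna"))
    write_feature_table(sim$features, file.path(out_dir, "features.tsv"))
    write_newick(sim$species_tree, file.path(out_dir, "species_tree.nwk"))
    write_newick(sim$gene_tree, file.path(out_dir, "gene_tree.nwk"))
    if (!is.null(family_tree))
      write_newick(family_tree, file.path(out_dir, "family_tree.nwk"))
    write.table(pairs, file.path(out_dir, "genome_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(classes, file.path(out_dir, "classifications.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
  }
  structure(c(report,
              list(family_tree = family_tree, pairs = pairs,
                   classifications = classes, simulation = sim)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  sequences: %d  clusters: %d -> %d after merging\n",
              x$n_sequences, x$n_clusters_initial, x$n_clusters_final))
  cat(sprintf("  transfers simulated: %d\n", x$n_transfers))
  cat(sprintf("  coherence rho (gene vs 16S): %.3f over %d genome pairs\n",
              x$coherence_rho, x$n_genome_pairs))
  if (length(x$dnds_medians))
    cat("  dN/dS medians:",
        paste(sprintf("%s=%.3f", names(x$dnds_medians),
                      unlist(x$dnds_medians)), collapse = ", "), "\n")
  cat("  categories:",
      paste(sprintf("%s=%d", names(x$category_counts),
                    unlist(x$category_counts)), collapse = ", "), "\n")
  cat(sprintf("  context label recovery vs truth: %.1f%%\n",
              100 * x$truth_agreement))
  invisible(x)
}
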