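# Iterative diverse-family tree construction: profile-profile cluster
# similarity, self-score-ratio merging, UPGMA dendrogram over clusters,
# per-cluster neighbor-joining trees, midpoint rooting and grafting.
#
# The profile-profile local scorer is an in-package stand-in for an
# HMM-HMM search tool; NJ on corrected distances stands in for approximate
# maximum likelihood. Both substitutions are deliberate: downstream steps
# consume only tree distances and supports, and these builders are exactly
# testable against additive-matrix and brute-force oracles.

# Distance cap shared with the coherence sentinel for saturated pairs.
SATURATION_CAP <- 12

#' Profile-profile similarity score
#'
#' Best local (Smith-Waterman) alignment of two column-frequency profiles
#' under the column score S(c1,c2) = sum_a sum_b f1(a) f2(b) B(a,b) with
#' BLOSUM62 B and affine gaps. Symmetric in its arguments.
#'
#' @param p,q \code{seq_profile} objects of the same kind.
#' @return numeric score (>= 0).
#' @export
profile_score <- function(p, q) {
  if (!inherits(p, "seq_profile") || !inherits(q, "seq_profile"))
    stop("profile_score expects seq_profile objects")
  if (ncol(p$freq) == 0 || ncol(q$freq) == 0) stop("empty profile")
  sm <- score_matrix_for(if (p$kind == "protein") "protein" else "nucleotide")
  g <- gap_costs(if (p$kind == "protein") "protein" else "nucleotide")
  S <- t(p$freq) %*% sm %*% q$freq
  affine_align_cpp(S, g["open"], g["ext"], 1L, TRUE)$score
}

#' @noRd
profile_self_score <- function(p) profile_score(p, p)

#' Iteratively merge similar clusters by profile self-score ratio
#'
#' Repeats until a fixed point: all pairwise profile-profile scores are
#' computed; every pair whose score / min(self_i, self_j) exceeds
#' \code{ratio_threshold} is a merge candidate; the highest-ratio pair is
#' merged by profile-profile alignment of the two cluster alignments, and
#' scores are recomputed. Terminates in at most (initial clusters - 1)
#' merges.
#'
#' @param alignments named list of \code{msa} objects, one per cluster.
#' @param ratio_threshold merge when score/self-score ratio exceeds this
#'   (default 0.1).
#' @return list with \code{alignments} (merged clusters), \code{scores}
#'   (symmetric profile score matrix), \code{self_scores}, \code{ratios},
#'   and \code{log} (data frame step, cluster_i, cluster_j, ratio).
#' @export
iterative_merge <- function(alignments, ratio_threshold = 0.1) {
  if (length(alignments) < 1) stop("need at least one cluster")
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("C%03d", seq_along(alignments))
  profs <- lapply(alignments, build_profile)
  log <- data.frame(step = integer(), cluster_i = character(),
                    cluster_j = character(), ratio = numeric(),
                    stringsAsFactors = FALSE)
  score_mat <- function(profs) {
    n <- length(profs)
    S <- matrix(0, n, n, dimnames = list(names(profs), names(profs)))
    selfs <- vapply(profs, profile_self_score, numeric(1))
    if (n >= 2)
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
        S[i, j] <- S[j, i] <- profile_score(profs[[i]], profs[[j]])
    list(S = S, selfs = selfs)
  }
  sm <- score_mat(profs)
  step <- 0L
  repeat {
    n <- length(profs)
    if (n == 1) break
    R <- sm$S / outer(sm$selfs, sm$selfs, pmin)
    diag(R) <- 0
    best <- max(R)
    if (best <= ratio_threshold) break
    idx <- which(R == best, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- min(idx[1, ]); j <- max(idx[1, ])
    step <- step + 1L
    log <- rbind(log, data.frame(step = step,
                                 cluster_i = names(profs)[i],
                                 cluster_j = names(profs)[j],
                                 ratio = best, stringsAsFactors = FALSE))
    ai <- alignments[[i]]; aj <- alignments[[j]]
    merged_rows <- merge_alignments(ai$seqs, aj$seqs, ai$kind)
    merged <- msa(c(ai$ids, aj$ids), c(ai$genome_ids, aj$genome_ids),
                  merged_rows, ai$kind)
    alignments[[i]] <- merged
    alignments[[j]] <- NULL
    profs <- lapply(alignments, build_profile)
    sm <- score_mat(profs)
  }
  ratios <- sm$S / outer(sm$selfs, sm$selfs, pmin)
  diag(ratios) <- 1
  list(alignments = alignments, scores = sm$S, self_scores = sm$selfs,
       ratios = ratios, log = log)
}

#' Convert a similarity matrix to distances via self-score normalization
#'
#' d(i,j) = 1 - score(i,j) / min(self_i, self_j), floored at 0.
#'
#' @param scores symmetric similarity matrix.
#' @param self_scores per-item self-similarities (> 0).
#' @return symmetric distance matrix with zero diagonal.
#' @export
similarity_to_distance <- function(scores, self_scores) {
  d <- 1 - scores / outer(self_scores, self_scores, pmin)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' UPGMA (average-linkage) dendrogram from a distance matrix
#'
#' @param d symmetric distance matrix (n >= 2) with dimnames, or a
#'   \code{dist}.
#' @return a rooted ultrametric \code{phylo} tree.
#' @export
upgma_tree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) < 2) stop("need at least 2 items")
    if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance matrix not symmetric")
    d <- as.dist(d)
  }
  hc <- hclust(d, method = "average")
  tr <- ape::as.phylo(hc)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Corrected pairwise distances from kept alignment columns.
# protein: scoredist-style d = -ln(1 - p - 0.2 p^2); nucleotide: JC
# d = -(3/4) ln(1 - 4p/3). Saturated or incomparable pairs capped at 12.
#' @noRd
aln_distances <- function(aln, model) {
  m <- seq_char_matrix(aln$seqs)[, aln$column_mask, drop = FALSE]
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) { D[i, j] <- D[j, i] <- SATURATION_CAP; next }
    p <- mean(m[i, ok] != m[j, ok])
    d <- if (model == "protein") {
      arg <- 1 - p - 0.2 * p^2
      if (arg <= 0) SATURATION_CAP else min(-log(arg), SATURATION_CAP)
    } else {
      if (p >= 0.75) SATURATION_CAP else min(-0.75 * log(1 - 4 * p / 3),
                                             SATURATION_CAP)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree with bootstrap support from an alignment
#'
#' Distances are maximum-likelihood-style corrections of the p-distance on
#' kept columns (protein: d = -ln(1 - p - 0.2p^2); nucleotide: Jukes-Cantor
#' d = -(3/4)ln(1 - 4p/3)); saturated pairs are capped at 12, matching the
#' coherence sentinel. Support values are bipartition frequencies over
#' bootstrap resamplings of kept columns (0..bootstrap). Output is unrooted;
#' negative NJ branch lengths are clamped to 0.
#'
#' @param aln an \code{msa} with >= 3 rows and >= 1 kept column.
#' @param model \code{"protein"} or \code{"nucleotide"}.
#' @param bootstrap number of resamplings (0 disables support).
#' @param seed optional RNG seed for the bootstrap.
#' @return unrooted \code{phylo}; node labels carry support counts.
#' @export
nj_tree <- function(aln, model = c("protein", "nucleotide"), bootstrap = 100,
                    seed = NULL) {
  model <- match.arg(model)
  if (length(aln$seqs) < 3) stop("need at least 3 sequences for NJ")
  if (!any(aln$column_mask)) stop("no kept columns")
  D <- aln_distances(aln, model)
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (bootstrap > 0) {
    keep <- which(aln$column_mask)
    boot <- with_stream(seed %||% 0L, "nj_bootstrap", {
      lapply(seq_len(bootstrap), function(b) {
        cols <- sample(keep, length(keep), replace = TRUE)
        a2 <- aln
        a2$column_mask <- rep(FALSE, length(aln$column_mask))
        bm <- seq_char_matrix(aln$seqs)[, cols, drop = FALSE]
        a2$seqs <- collapse_rows(bm)
        a2$column_mask <- rep(TRUE, length(cols))
        t2 <- ape::nj(aln_distances(a2, model))
        t2$edge.length[t2$edge.length < 0] <- 0
        t2
      })
    })
    cnt <- ape::prop.clades(tr, boot, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tr$node.label <- as.character(cnt)
  }
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path,
#' preserving patristic distances.
#'
#' @param tree a \code{phylo} with >= 2 leaves and branch lengths.
#' @return a rooted \code{phylo}.
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) == 2) {
    total <- sum(tree$edge.length)
    out <- tree
    out$edge.length <- rep(total / 2, nrow(out$edge))
    return(out)
  }
  phangorn::midpoint(tree)
}

#' Graft per-cluster trees onto a cluster dendrogram
#'
#' Every dendrogram tip is replaced by the corresponding (midpoint-rooted)
#' cluster subtree; singleton clusters may be given as a bare leaf id.
#' Within-subtree patristic distances and dendrogram-level distances between
#' cluster roots are preserved. Dendrogram-internal nodes get support "0"
#' (never-aligned attachment points).
#'
#' @param dendrogram \code{phylo} over cluster ids (a 1-tip tree is allowed).
#' @param subtrees named list mapping every dendrogram tip to a \code{phylo}
#'   or, for singleton clusters, a single leaf id (character).
#' @return a \code{phylo} whose leaf set is the disjoint union of the
#'   subtree leaf sets.
#' @export
graft <- function(dendrogram, subtrees) {
  tips <- dendrogram$tip.label
  missing <- setdiff(tips, names(subtrees))
  if (length(missing))
    stop("missing subtree for dendrogram tip: ", missing[1])
  if (ape::Ntip(dendrogram) == 1) {
    st <- subtrees[[tips]]
    if (is.character(st)) { dendrogram$tip.label <- st; return(dendrogram) }
    return(st)
  }
  out <- dendrogram
  out$node.label <- rep("0", out$Nnode)
  for (lab in tips) {
    st <- subtrees[[lab]]
    w <- match(lab, out$tip.label)
    if (is.character(st)) {
      out$tip.label[w] <- st
    } else if (ape::Ntip(st) == 1) {
      out$tip.label[w] <- st$tip.label
    } else {
      if (is.null(st$node.label)) st$node.label <- rep("", st$Nnode)
      out <- ape::bind.tree(out, st, where = w)
    }
  }
  out
}
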