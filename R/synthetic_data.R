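# Synthetic-data generator with known ground truth: Yule species trees, a
# gene family evolving with horizontal transfer (SPR at random times),
# duplication and loss, codon sequences under a Muse-Gaut/HKY model with a
# tunable dN/dS, a slowly-evolving 16S-like marker, and annotated genome
# feature tables with CRISPR adaptation-module operons, solo genes and
# MGE-resident copies.

#' Simulation configuration
#'
#' Defaults describe a desk-scale but realistic world: 50 genomes, species
#' tree rescaled to height 1 (expected amino-acid substitutions per site
#' root-to-tip for the family protein clock), 16S-like marker at 0.1x that
#' rate, 200 codons, omega 0.1 (moderate purifying selection, matching
#' genome-wide medians of ~0.1), kappa 2, and a locus mix following the
#' family's observed category proportions (~0.85 CRISPR-associated, ~0.11
#' solo, ~0.04 MGE).
#'
#' @param n_genomes number of genomes (>= 2).
#' @param birth_rate Yule per-lineage speciation rate.
#' @param hgt_rate expected transfers per gene lineage per unit tree height.
#' @param dup_rate per-branch duplication probability.
#' @param loss_rate per-branch loss probability.
#' @param omega target dN/dS for the codon simulation (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @param seq_len_codons protein length in codons.
#' @param rrna_len length of the 16S-like marker.
#' @param rrna_rate rRNA clock relative to the protein clock.
#' @param tree_height species-tree height after rescaling (NULL keeps the
#'   raw Yule height).
#' @param locus_mix named proportions of cas_operon / solo / mge placements
#'   (sum to 1).
#' @param seed master seed; all stages draw from labeled substreams of it.
#' @return a validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_genomes = 50, birth_rate = 1, hgt_rate = 0,
                              dup_rate = 0, loss_rate = 0, omega = 0.1,
                              kappa = 2, seq_len_codons = 200,
                              rrna_len = 1500, rrna_rate = 0.1,
                              tree_height = 1,
                              locus_mix = c(cas_operon = 0.85, solo = 0.11,
                                            mge = 0.04),
                              seed = 1) {
  stopifnot(n_genomes >= 2, birth_rate > 0, hgt_rate >= 0, dup_rate >= 0,
            loss_rate >= 0, omega >= 0, kappa > 0, seq_len_codons >= 1,
            rrna_len >= 1)
  if (length(locus_mix) != 3 || any(locus_mix < 0) || any(locus_mix > 1) ||
      abs(sum(locus_mix) - 1) > 1e-9)
    stop("locus_mix must be 3 proportions in [0,1] summing to 1")
  names(locus_mix) <- c("cas_operon", "solo", "mge")
  structure(list(n_genomes = n_genomes, birth_rate = birth_rate,
                 hgt_rate = hgt_rate, dup_rate = dup_rate,
                 loss_rate = loss_rate, omega = omega, kappa = kappa,
                 seq_len_codons = seq_len_codons, rrna_len = rrna_len,
                 rrna_rate = rrna_rate, tree_height = tree_height,
                 locus_mix = locus_mix, seed = seed),
            class = "sim_config")
}

#' Simulate an ultrametric Yule species tree
#'
#' @param n_genomes number of leaves (>= 2); leaf labels are genome ids
#'   \code{g001..}.
#' @param birth_rate per-lineage speciation rate.
#' @param seed RNG seed (labeled substream).
#' @param height if non-NULL, rescale the tree to this root-to-tip height.
#' @return an ultrametric \code{phylo}.
#' @export
simulate_species_tree <- function(n_genomes, birth_rate = 1, seed = NULL,
                                  height = NULL) {
  if (n_genomes < 2) stop("n_genomes must be >= 2")
  tr <- with_stream(seed %||% 0L, "species_tree",
                    ape::rphylo(n_genomes, birth_rate, 0))
  tr$tip.label <- sprintf("g%03d", seq_len(n_genomes))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (height / h)
  }
  tr
}

# ---- timed-tree machinery (internal) ---------------------------------------
# Nodes are rows of parallel vectors: parent (NA for root), time (depth from
# the original root), label (tips only), alive flag. All gene-family events
# (SPR transfers, duplications, losses) are edits of this structure.

#' @noRd
phylo_to_timed <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  label <- rep(NA_character_, n)
  label[seq_len(ape::Ntip(tree))] <- tree$tip.label
  list(parent = parent, time = depth, label = label,
       alive = rep(TRUE, n))
}

#' @noRd
timed_children <- function(tt, v) {
  which(tt$alive & !is.na(tt$parent) & tt$parent == v)
}

#' @noRd
timed_root <- function(tt) which(tt$alive & is.na(tt$parent))

# splice out a node that has exactly one live child
#' @noRd
timed_suppress <- function(tt, v) {
  ch <- timed_children(tt, v)
  if (length(ch) != 1) return(tt)
  tt$parent[ch] <- tt$parent[v]
  tt$alive[v] <- FALSE
  tt
}

#' @noRd
timed_add_node <- function(tt, parent, time, label = NA_character_) {
  tt$parent <- c(tt$parent, parent)
  tt$time <- c(tt$time, time)
  tt$label <- c(tt$label, label)
  tt$alive <- c(tt$alive, TRUE)
  list(tt = tt, id = length(tt$parent))
}

# edges (identified by child node) whose span strictly contains time t
#' @noRd
timed_alive_edges <- function(tt, t) {
  v <- which(tt$alive & !is.na(tt$parent))
  v[tt$time[tt$parent[v]] <= t & tt$time[v] > t]
}

# replacement transfer: re-attach the subtree hanging below the recipient
# edge at time t as sister to the donor lineage at time t
#' @noRd
timed_transfer <- function(tt, recipient, donor, t) {
  pr <- tt$parent[recipient]
  res <- timed_add_node(tt, tt$parent[donor], t)
  tt <- res$tt; r <- res$id
  tt$parent[donor] <- r
  tt$parent[recipient] <- r
  if (sum(tt$alive & !is.na(tt$parent) & tt$parent == pr) <= 1)
    tt <- timed_suppress(tt, pr)
  tt
}

# duplicate the lineage below time tm on edge (parent[v] -> v)
#' @noRd
timed_duplicate <- function(tt, v, tm, suffix) {
  res <- timed_add_node(tt, tt$parent[v], tm)
  tt <- res$tt; d <- res$id
  tt$parent[v] <- d
  copy <- function(tt, src, new_parent) {
    lab <- if (!is.na(tt$label[src])) paste0(tt$label[src], suffix) else NA_character_
    res <- timed_add_node(tt, new_parent, tt$time[src], lab)
    tt <- res$tt; dst <- res$id
    for (ch in timed_children(tt, src)) {
      if (ch == dst) next
      tt <- copy(tt, ch, dst)
    }
    tt
  }
  copy(tt, v, d)
}

# delete the subtree below edge v
#' @noRd
timed_lose <- function(tt, v) {
  kill <- function(tt, x) {
    for (ch in timed_children(tt, x)) tt <- kill(tt, ch)
    tt$alive[x] <- FALSE
    tt
  }
  p <- tt$parent[v]
  tt <- kill(tt, v)
  while (!is.na(p)) {
    ch <- timed_children(tt, p)
    if (length(ch) >= 2) break
    if (length(ch) == 1) { tt <- timed_suppress(tt, p); break }
    np <- tt$parent[p]
    tt$alive[p] <- FALSE
    p <- np
  }
  tt
}

#' @noRd
timed_to_phylo <- function(tt) {
  root <- timed_root(tt)
  if (length(root) != 1) stop("timed tree has no unique root")
  build <- function(v) {
    ch <- timed_children(tt, v)
    if (length(ch) == 0) return(tt$label[v])
    paste0("(", paste(vapply(ch, function(c2) {
      paste0(build(c2), ":", format(tt$time[c2] - tt$time[v], digits = 12))
    }, character(1)), collapse = ","), ")")
  }
  nw <- paste0(build(root), ";")
  ape::read.tree(text = nw)
}

# ---- gene family evolution -------------------------------------------------

#' Evolve a gene family on a species tree
#'
#' The gene tree starts as a copy of the species tree. Transfers occur at
#' Poisson(hgt_rate x height) uniformly random times: the subtree below a
#' random recipient lineage is re-attached as sister to a random
#' contemporaneous donor lineage (replacement transfer, i.e. subtree
#' prune-regraft). Each branch then independently duplicates (probability
#' \code{dup_rate}, copy attached at the branch midpoint) and each branch
#' is lost with probability \code{loss_rate}.
#'
#' @param species_tree ultrametric \code{phylo} with genome-id tip labels.
#' @param hgt_rate,dup_rate,loss_rate event rates (see above).
#' @param seed RNG seed (labeled substream).
#' @return list of class \code{gene_family}: \code{gene_tree} (phylo, tips
#'   are gene ids \code{<genome>.<copy>}), \code{gene_map} (data frame
#'   gene_id, genome_id), \code{transfer_events} (data frame donor_node,
#'   recipient_node, time).
#' @export
evolve_gene_family <- function(species_tree, hgt_rate = 0, dup_rate = 0,
                               loss_rate = 0, seed = NULL) {
  height <- max(ape::node.depth.edgelength(species_tree))
  with_stream(seed %||% 0L, "gene_family", {
    tt <- phylo_to_timed(species_tree)
    events <- data.frame(donor_node = integer(), recipient_node = integer(),
                         time = numeric())
    n_ev <- rpois(1, hgt_rate * height)
    if (n_ev > 0) {
      times <- sort(runif(n_ev, 0, height))
      for (t in times) {
        edges <- timed_alive_edges(tt, t)
        if (length(edges) < 2) next
        pick <- sample(edges, 2)
        recipient <- pick[1]; donor <- pick[2]
        tt <- timed_transfer(tt, recipient, donor, t)
        events <- rbind(events, data.frame(donor_node = donor,
                                           recipient_node = recipient,
                                           time = t))
      }
    }
    if (dup_rate > 0) {
      cand <- which(tt$alive & !is.na(tt$parent))
      hit <- cand[runif(length(cand)) < dup_rate]
      k <- 0L
      for (v in hit) {
        if (!tt$alive[v]) next
        k <- k + 1L
        tm <- (tt$time[tt$parent[v]] + tt$time[v]) / 2
        tt <- timed_duplicate(tt, v, tm, sprintf("~d%d", k))
      }
    }
    if (loss_rate > 0) {
      cand <- which(tt$alive & !is.na(tt$parent))
      hit <- cand[runif(length(cand)) < loss_rate]
      for (v in hit) {
        if (!tt$alive[v]) next
        tt <- timed_lose(tt, v)
      }
    }
    tips <- which(tt$alive & vapply(seq_along(tt$alive), function(v)
      tt$alive[v] && length(timed_children(tt, v)) == 0, logical(1)))
    tips <- tips[!is.na(tt$label[tips])]
    if (length(tips) == 0) stop("empty family: all gene copies lost")
    genome <- sub("~d.*$", "", tt$label[tips])
    gene_id <- character(length(tips))
    for (g in unique(genome)) {
      idx <- which(genome == g)
      idx <- idx[order(tt$label[tips][idx])]
      gene_id[idx] <- sprintf("%s.%d", g, seq_along(idx))
    }
    tt$label[tips] <- gene_id
    gene_tree <- timed_to_phylo(tt)
    structure(list(gene_tree = gene_tree,
                   gene_map = data.frame(gene_id = sort(gene_id),
                                         genome_id = genome[order(gene_id)],
                                         stringsAsFactors = FALSE),
                   transfer_events = events),
              class = "gene_family")
  })
}

# ---- codon and marker simulation -------------------------------------------

# Muse-Gaut style codon rate matrix over the 61 sense codons with HKY
# nucleotide exchange (uniform codon frequencies). Scaled so that one unit
# of branch length equals one expected nucleotide substitution per site at
# omega = 1; omega rescales nonsynonymous rates only.
#' @noRd
codon_rate_matrix <- function(omega, kappa) {
  codons <- sense_codons()
  gc <- genetic_code()
  K <- length(codons)
  is_transition <- function(x, y)
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  base <- matrix(0, K, K, dimnames = list(codons, codons))
  nonsyn <- matrix(FALSE, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    ci <- chars(codons[i]); cj <- chars(codons[j])
    diff <- which(ci != cj)
    if (length(diff) != 1) next
    base[i, j] <- if (is_transition(ci[diff], cj[diff])) kappa else 1
    nonsyn[i, j] <- gc[codons[i]] != gc[codons[j]]
  }
  r1 <- mean(rowSums(base))            # per-codon rate at omega = 1
  Q <- base * ifelse(nonsyn, omega, 1) * (3 / r1)
  diag(Q) <- -rowSums(Q)
  Q
}

#' @noRd
codon_transition_probs <- function(eig, t) {
  P <- eig$vectors %*% (t(eig$vectors) * exp(eig$values * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate codon sequences along a tree
#'
#' Site-independent Muse-Gaut/HKY codon model with nonsynonymous rates
#' scaled by omega; uniform codon frequencies; stop codons are never
#' generated. Branch lengths are expected nucleotide substitutions per site
#' at omega = 1.
#'
#' @param tree \code{phylo} with branch lengths; tip labels become record
#'   ids.
#' @param omega dN/dS (>= 0).
#' @param kappa transition/transversion ratio.
#' @param seq_len_codons number of codons.
#' @param seed RNG seed (labeled substream).
#' @param genome_of optional named map tip label -> genome id (default:
#'   genome = label up to the first ".").
#' @return list with \code{cds} and \code{protein} \code{seq_records}.
#' @export
simulate_codon_sequences <- function(tree, omega, kappa = 2,
                                     seq_len_codons = 200, seed = NULL,
                                     genome_of = NULL) {
  if (omega < 0) stop("omega must be >= 0")
  if (seq_len_codons < 1) stop("seq_len_codons must be >= 1")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  codons <- sense_codons()
  Q <- codon_rate_matrix(omega, kappa)
  eig <- eigen(Q, symmetric = TRUE)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  with_stream(seed %||% 0L, "codon_sim", {
    states <- matrix(NA_integer_, nnode, seq_len_codons)
    root <- ntip + 1L
    states[root, ] <- sample.int(61L, seq_len_codons, replace = TRUE)
    eo <- reorder(tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      p <- eo$edge[k, 1]; v <- eo$edge[k, 2]; t <- eo$edge.length[k]
      if (t <= 0) { states[v, ] <- states[p, ]; next }
      P <- codon_transition_probs(eig, t)
      out <- integer(seq_len_codons)
      ps <- states[p, ]
      for (s in unique(ps)) {
        idx <- which(ps == s)
        out[idx] <- sample.int(61L, length(idx), replace = TRUE,
                               prob = P[s, ])
      }
      states[v, ] <- out
    }
    cds <- vapply(seq_len(ntip), function(i)
      paste(codons[states[i, ]], collapse = ""), character(1))
    ids <- tree$tip.label
    genome <- if (is.null(genome_of)) sub("\\..*$", "", ids) else
      unname(genome_of[ids])
    list(cds = sequence_records(ids, genome, cds, "cds"),
         protein = sequence_records(ids, genome, translate_cds(cds),
                                    "protein"))
  })
}

#' Simulate a 16S-like marker along the species tree
#'
#' Jukes-Cantor evolution at \code{rate} times the protein clock (default
#' 0.1x, mimicking rRNA conservation).
#'
#' @param species_tree \code{phylo} with genome-id tips.
#' @param rrna_len sequence length.
#' @param rate clock multiplier relative to branch-length units.
#' @param seed RNG seed (labeled substream).
#' @return a \code{seq_records} set of kind \code{"rrna"} (ids
#'   \code{<genome>_16S}).
#' @export
simulate_marker <- function(species_tree, rrna_len = 1500, rate = 0.1,
                            seed = NULL) {
  ntip <- ape::Ntip(species_tree)
  nnode <- ntip + species_tree$Nnode
  with_stream(seed %||% 0L, "rrna_sim", {
    states <- matrix(NA_integer_, nnode, rrna_len)
    root <- ntip + 1L
    states[root, ] <- sample.int(4L, rrna_len, replace = TRUE)
    eo <- reorder(species_tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      p <- eo$edge[k, 1]; v <- eo$edge[k, 2]; t <- eo$edge.length[k] * rate
      p_stay <- 0.25 + 0.75 * exp(-4 * t / 3)
      s <- states[p, ]
      change <- runif(rrna_len) > p_stay
      s[change] <- ((s[change] - 1L + sample.int(3L, sum(change),
                                                 replace = TRUE)) %% 4L) + 1L
      states[v, ] <- s
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste(NUC4[states[i, ]], collapse = ""), character(1))
    sequence_records(paste0(species_tree$tip.label, "_16S"),
                     species_tree$tip.label, seqs, "rrna")
  })
}

# ---- genome feature tables -------------------------------------------------

CAS_ARRANGEMENTS <- c("cas4-cas1-cas2", "fusion-cas2", "cas4-cas1-cas2-cas6",
                      "two-cas4")

# effector subtypes plausibly co-occurring with each arrangement
#' @noRd
arrangement_subtypes <- function(arr) {
  switch(arr,
         "cas4-cas1-cas2" = c("I-B", "I-C", "II-B"),
         "fusion-cas2" = c("I-U", "V-A", "V-B"),
         "cas4-cas1-cas2-cas6" = c("I-B", "I-D"),
         "two-cas4" = "I-A")
}

#' Emit annotated genome feature tables for a simulated family
#'
#' Each gene copy is placed on its own synthetic contig. CRISPR-operon
#' placements get one of the typical adaptation-module arrangements
#' (cas4-cas1-cas2, cas4/cas1 fusion-cas2, cas4-cas1-cas2-cas6, or the
#' two-cas4 I-A-like form), optionally followed by an effector-subtype gene
#' and a CRISPR array; MGE placements sit on viral or plasmid replicons
#' with flanking MGE markers; solo placements get neutral neighbors on the
#' chromosome.
#'
#' @param gene_map data frame gene_id, genome_id (from
#'   [evolve_gene_family()]).
#' @param locus_mix named proportions (cas_operon, solo, mge) summing to 1.
#' @param seed RNG seed (labeled substream).
#' @return list with \code{features} (a \code{gene_features} data frame)
#'   and \code{true_labels} (named map gene_id -> cas_operon/solo/mge).
#' @export
emit_genome_tables <- function(gene_map, locus_mix = c(cas_operon = 0.85,
                                                       solo = 0.11,
                                                       mge = 0.04),
                               seed = NULL) {
  if (abs(sum(locus_mix) - 1) > 1e-9) stop("locus_mix must sum to 1")
  n <- nrow(gene_map)
  with_stream(seed %||% 0L, "genome_tables", {
    lab <- sample(c("cas_operon", "solo", "mge"), n, replace = TRUE,
                  prob = locus_mix)
    rows <- list()
    for (i in seq_len(n)) {
      gid <- gene_map$gene_id[i]; gen <- gene_map$genome_id[i]
      ann <- character(); ids <- character(); strands <- character()
      replicon <- "chromosome"; contig <- paste0("ctg_", gid)
      if (lab[i] == "cas_operon") {
        arr <- sample(CAS_ARRANGEMENTS, 1)
        if (arr == "cas4-cas1-cas2") {
          ann <- c("cas4", "cas1", "cas2"); ids <- c(gid, NA, NA)
        } else if (arr == "fusion-cas2") {
          ann <- c("cas4/cas1 fusion", "cas2"); ids <- c(gid, NA)
        } else if (arr == "cas4-cas1-cas2-cas6") {
          ann <- c("cas4", "cas1", "cas2", "cas6"); ids <- c(gid, NA, NA, NA)
        } else {
          ann <- c("cas4", "cas4", "cas1", "cas2"); ids <- c(gid, NA, NA, NA)
        }
        if (runif(1) < 0.7) {
          st <- sample(arrangement_subtypes(arr), 1)
          ann <- c(ann, paste0("effector_", st)); ids <- c(ids, NA)
        }
        if (runif(1) < 0.5) { ann <- c(ann, "crispr_array"); ids <- c(ids, NA) }
        strands <- rep("+", length(ann))
      } else if (lab[i] == "solo") {
        ann <- c("other", "other", "cas4", "other", "other")
        ids <- c(NA, NA, gid, NA, NA)
        strands <- sample(c("+", "-"), length(ann), replace = TRUE)
      } else {
        replicon <- sample(c("viral", "plasmid"), 1, prob = c(0.7, 0.3))
        ann <- c("mge_marker", "other", "cas4", "mge_marker")
        ids <- c(NA, NA, gid, NA)
        strands <- sample(c("+", "-"), length(ann), replace = TRUE)
      }
      k <- seq_along(ann)
      ids[is.na(ids)] <- sprintf("%s_n%d", gid, which(is.na(ids)))
      rows[[i]] <- data.frame(
        genome_id = gen, contig_id = contig, gene_id = ids,
        start = (k - 1L) * 1000L + 1L, end = (k - 1L) * 1000L + 900L,
        strand = strands, annotation = ann, replicon_class = replicon,
        stringsAsFactors = FALSE)
    }
    features <- gene_features(do.call(rbind, rows))
    list(features = features,
         true_labels = setNames(lab, gene_map$gene_id))
  })
}

#' Run the full synthetic generator for one configuration
#'
#' Species tree, gene family (transfers/duplications/losses), codon and
#' protein sequences, 16S-like marker and genome feature tables, with the
#' ground truth needed for parameter-recovery tests. Same config + seed
#' reproduces identical output.
#'
#' @param config a \code{sim_config} from [simulation_config()].
#' @return list of class \code{family_simulation}: species_tree, gene_tree,
#'   gene_map, transfer_events, sequences (protein/cds/rrna), features,
#'   true_labels, config.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- simulate_species_tree(config$n_genomes, config$birth_rate,
                              seed = config$seed,
                              height = config$tree_height)
  fam <- evolve_gene_family(sp, config$hgt_rate, config$dup_rate,
                            config$loss_rate, seed = config$seed)
  seqs <- simulate_codon_sequences(fam$gene_tree, config$omega, config$kappa,
                                   config$seq_len_codons, seed = config$seed)
  rrna <- simulate_marker(sp, config$rrna_len, config$rrna_rate,
                          seed = config$seed)
  tabs <- emit_genome_tables(fam$gene_map, config$locus_mix,
                             seed = config$seed)
  structure(list(species_tree = sp, gene_tree = fam$gene_tree,
                 gene_map = fam$gene_map,
                 transfer_events = fam$transfer_events,
                 sequences = list(protein = seqs$protein, cds = seqs$cds,
                                  rrna = rrna),
                 features = tabs$features, true_labels = tabs$true_labels,
                 config = config),
            class = "family_simulation")
}
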