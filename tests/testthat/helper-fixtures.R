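# Shared fixtures: random sequence generators and small simulated families.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")
NT <- c("A","C","G","T")

rand_protein <- function(len) paste(sample(AA, len, replace = TRUE),
                                    collapse = "")
rand_nucleotide <- function(len) paste(sample(NT, len, replace = TRUE),
                                       collapse = "")

# substitute k positions with conservative (positive-BLOSUM) partners so
# the optimal global alignment stays gapless and identity is exact
CONSERVATIVE <- c(A = "S", R = "K", N = "H", D = "E", C = "A", Q = "E",
                  E = "D", G = "A", H = "N", I = "V", L = "I", K = "R",
                  M = "L", F = "Y", P = "A", S = "T", T = "S", W = "Y",
                  Y = "F", V = "I")

mutate_conservative <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  ch[positions] <- CONSERVATIVE[ch[positions]]
  paste(ch, collapse = "")
}

# a protein seq_records set of n mutated copies of one random base
random_family <- function(n, len = 60, sub_rate = 0.2, prefix = "s") {
  base <- strsplit(rand_protein(len), "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    ch <- base
    k <- rbinom(1, len, sub_rate)
    if (k > 0) {
      pos <- sample(len, k)
      ch[pos] <- sample(AA, k, replace = TRUE)
    }
    paste(ch, collapse = "")
  }, character(1))
  sequence_records(sprintf("%s%02d", prefix, seq_len(n)), "g", seqs,
                   "protein")
}

# small simulated family for round-trip tests
small_simulation <- function(seed = 11, n_genomes = 20,
                             locus_mix = c(cas_operon = 0.4, solo = 0.3,
                                           mge = 0.3)) {
  cfg <- simulation_config(n_genomes = n_genomes, hgt_rate = 0.5,
                           dup_rate = 0.05, seq_len_codons = 80,
                           rrna_len = 400, locus_mix = locus_mix,
                           seed = seed)
  simulate_family(cfg)
}

expect_isomorphic_trees <- function(t1, t2, tol = 1e-9) {
  expect_setequal(t1$tip.label, t2$tip.label)
  c1 <- stats::cophenetic(t1)
  c2 <- stats::cophenetic(t2)[rownames(c1), colnames(c1)]
  expect_lt(max(abs(c1 - c2)), tol)
}
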