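test_that("pairwise identity matches definitions on exact cases", {
  p <- pairwise_identity("MKVLWAALLG", "MKVLWAALLG")
  expect_equal(p$identity, 1.0)
  expect_equal(p$coverage_a, 1.0)
  expect_equal(p$coverage_b, 1.0)

  pn <- pairwise_identity("AAAA", "AAAT", kind = "nucleotide")
  expect_equal(pn$identity, 0.75)

  expect_error(pairwise_identity("", "MK"), "empty")
})

test_that("pairwise identity is symmetric and scores match the Biostrings oracle", {
  set.seed(11)
  for (k in 1:20) {
    a <- rand_protein(sample(30:80, 1))
    b <- rand_protein(sample(30:80, 1))
    p <- pairwise_identity(a, b)
    q <- pairwise_identity(b, a)
    expect_equal(p$identity, q$identity)
    expect_equal(p$coverage_a, q$coverage_b)
    expect_equal(p$coverage_b, q$coverage_a)
    # independent Needleman-Wunsch oracle (same gap convention:
    # length-k gap costs 11 + (k-1))
    ora <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global")
    expect_equal(p$score, Biostrings::score(ora))
  }
})

test_that("greedy clustering gives single-linkage components with exact thresholds", {
  # all identical -> one cluster
  rec <- sequence_records(c("a", "b", "c"), "g",
                          rep("MKVLWAALLGMKVLWAALLG", 3), "protein")
  cs <- greedy_cluster(rec, 0.5, 0.8)
  expect_length(cs$clusters, 1)

  # chain A-B, B-C linked but A-C below threshold -> one cluster of 3
  set.seed(4)
  base <- rand_protein(100)
  b <- mutate_conservative(base, 1:30)       # 0.70 to A
  c2 <- mutate_conservative(b, 41:80)        # 0.60 to B, 0.30 to A
  rec <- sequence_records(c("A", "B", "C"), "g", c(base, b, c2), "protein")
  ids <- identity_mat <- outer(1:3, 1:3, Vectorize(function(i, j)
    pairwise_identity(rec$residues[i], rec$residues[j])$identity))
  expect_lt(identity_mat[1, 3], 0.5)
  expect_gte(identity_mat[1, 2], 0.5)
  expect_gte(identity_mat[2, 3], 0.5)
  cs <- greedy_cluster(rec, 0.5, 0.8)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]], c("A", "B", "C"))

  # identity exactly 0.49 splits at the 50% threshold
  set.seed(5)
  a <- rand_protein(100)
  b49 <- mutate_conservative(a, 1:51)
  expect_equal(pairwise_identity(a, b49)$identity, 0.49)
  rec <- sequence_records(c("a", "b"), "g", c(a, b49), "protein")
  expect_length(greedy_cluster(rec, 0.5, 0.8)$clusters, 2)
  expect_length(greedy_cluster(rec, 0.49, 0.8)$clusters, 1)
})

test_that("clustering is invariant to input order", {
  set.seed(6)
  rec <- random_family(12, len = 50, sub_rate = 0.35)
  cs1 <- greedy_cluster(rec, 0.5, 0.8)
  perm <- sample(nrow(rec))
  cs2 <- greedy_cluster(rec[perm, ], 0.5, 0.8)
  expect_identical(cs1$clusters, cs2$clusters)
})

test_that("progressive alignment satisfies its contracts", {
  # single sequence: unchanged, no gaps
  one <- sequence_records("a", "g", "MKVLW", "protein")
  a1 <- progressive_align(one)
  expect_equal(a1$seqs, "MKVLW")

  # two identical sequences: zero gap characters
  two <- sequence_records(c("a", "b"), "g", rep("MKVLWAALLG", 2), "protein")
  a2 <- progressive_align(two)
  expect_false(any(grepl("-", a2$seqs, fixed = TRUE)))

  # a single internal 3-residue deletion aligns as one 3-column gap block
  set.seed(8)
  base <- rand_protein(60)
  del <- paste0(substr(base, 1, 30), substr(base, 34, 60))
  three <- sequence_records(c("full1", "full2", "del"), "g",
                            c(base, mutate_conservative(base, c(5, 15, 25)),
                              del), "protein")
  a3 <- progressive_align(three)
  gaps <- gregexpr("-+", a3$seqs[3])[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3)
  expect_false(any(grepl("-", a3$seqs[1:2], fixed = TRUE)))

  # ungapping any row reproduces its input (property, random families)
  for (k in 1:5) {
    rec <- random_family(sample(3:8, 1), len = 40, sub_rate = 0.3)
    aln <- progressive_align(rec)
    expect_equal(gsub("-", "", aln$seqs, fixed = TRUE),
                 rec$residues[match(aln$ids, rec$id)])
  }
})

test_that("two-sequence progressive alignment reproduces the pairwise NW optimum", {
  set.seed(9)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  for (k in 1:5) {
    a <- rand_protein(50)
    b <- rand_protein(55)
    aln <- progressive_align(sequence_records(c("a", "b"), "g", c(a, b),
                                              "protein"))
    # recompute the affine sum score of the emitted alignment
    ca <- strsplit(aln$seqs[1], "")[[1]]
    cb <- strsplit(aln$seqs[2], "")[[1]]
    sc <- 0; run <- 0
    for (i in seq_along(ca)) {
      if (ca[i] == "-" || cb[i] == "-") {
        run <- run + 1
        sc <- sc - (if (run == 1) 11 else 1)
      } else {
        run <- 0
        sc <- sc + BLOSUM62[ca[i], cb[i]]
      }
    }
    direct <- pairwise_identity(a, b)$score
    expect_equal(sc, direct)
  }
})

test_that("column filter applies the gap and homogeneity rules and is idempotent", {
  aln <- msa(c("r1", "r2", "r3", "r4"), "g",
             c("AKAAC", "A-AAC", "G-ARC", "T-AVC"), "protein")
  f <- filter_columns(aln)
  st <- f$column_stats
  # column 1 "AAGT": no gaps, homogeneity 1/6 -> kept
  expect_true(st$kept[1])
  expect_equal(st$homogeneity[1], 1 / 6)
  # column 2 "K---": gap fraction 0.75 > 0.5 -> removed
  expect_false(st$kept[2])
  expect_equal(st$gap_fraction[2], 0.75)
  # column 3 "AAAA": kept, homogeneity 1
  expect_true(st$kept[3])
  expect_equal(st$homogeneity[3], 1)
  # column 4 "AARV": 4 distinct of 4 -> homogeneity 0 < 0.1 -> removed
  aln2 <- msa(paste0("q", 1:5), "g",
              c("A", "R", "N", "D", "C"), "protein")
  f2 <- filter_columns(aln2)
  expect_false(f2$column_mask[1])
  expect_equal(f2$column_stats$homogeneity[1], 0)
  # idempotent
  expect_identical(filter_columns(f)$column_mask, f$column_mask)

  expect_error(filter_columns(msa(character(), character(), character())),
               "zero columns")
})

test_that("profiles use the stated pseudocount and normalize", {
  aln <- msa(paste0("s", 1:4), "g", c("A", "A", "A", "C"), "protein")
  p <- build_profile(aln)
  expect_equal(unname(p$freq["A", 1]), (3 + 0.05) / 5)
  expect_equal(unname(p$freq["C", 1]), (1 + 0.05) / 5)
  # property: all kept columns sum to 1
  set.seed(12)
  for (k in 1:5) {
    rec <- random_family(sample(2:6, 1), len = 30, sub_rate = 0.3)
    pr <- build_profile(progressive_align(rec))
    expect_true(all(abs(colSums(pr$freq) - 1) < 1e-9))
  }
  # single-sequence profile is ~one-hot
  p1 <- build_profile(msa("a", "g", "MK", "protein"))
  expect_equal(unname(p1$freq["M", 1]), 1.05 / 2)
  expect_equal(unname(p1$freq["K", 2]), 1.05 / 2)

  bad <- msa(c("a", "b"), "g", c("AA", "AA"), "protein",
             column_mask = c(FALSE, FALSE))
  expect_error(build_profile(bad), "empty profile")
})
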