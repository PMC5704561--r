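mk_features <- function(ann, replicon = "chromosome", gene_idx = NULL,
                        contig = "c1", genome = "g1") {
  n <- length(ann)
  ids <- sprintf("f%02d", seq_len(n))
  if (!is.null(gene_idx)) ids[gene_idx] <- "target"
  gene_features(data.frame(
    genome_id = genome, contig_id = contig, gene_id = ids,
    start = (seq_len(n) - 1) * 1000 + 1, end = (seq_len(n) - 1) * 1000 + 900,
    strand = "+", annotation = ann, replicon_class = replicon,
    stringsAsFactors = FALSE))
}

test_that("classification follows the CAS / MGE / solo precedence rules", {
  # cas4 immediately upstream of cas1, cas2 -> CAS with the canonical
  # arrangement
  ft <- mk_features(c("cas4", "cas1", "cas2"), gene_idx = 1)
  cl <- classify_locus("target", ft)
  expect_equal(cl$category, "CAS")
  expect_equal(cl$arrangement, "cas4-cas1-cas2")
  expect_true(cl$standalone_adaptation_module)

  # cas4 on a viral contig with no cas genes -> MGE
  ft2 <- mk_features(c("other", "cas4", "other"), replicon = "viral",
                     gene_idx = 2)
  expect_equal(classify_locus("target", ft2)$category, "MGE")

  # mge_marker proximity on a chromosome also gives MGE
  ft2b <- mk_features(c("mge_marker", "cas4", "other"), gene_idx = 2)
  expect_equal(classify_locus("target", ft2b)$category, "MGE")

  # only "other" neighbors on a chromosome -> solo
  ft3 <- mk_features(c("other", "other", "cas4", "other"), gene_idx = 3)
  expect_equal(classify_locus("target", ft3)$category, "solo")

  # effector within the window suppresses the stand-alone flag and sets
  # the subtype
  ft4 <- mk_features(c("cas4", "cas1", "cas2", "effector_I-B"),
                     gene_idx = 1)
  cl4 <- classify_locus("target", ft4)
  expect_equal(cl4$category, "CAS")
  expect_false(cl4$standalone_adaptation_module)
  expect_equal(cl4$subtype, "I-B")

  # window limit: cas evidence beyond window_genes does not count
  ft5 <- mk_features(c("cas1", rep("other", 11), "cas4"), gene_idx = 13)
  expect_equal(classify_locus("target", ft5, window_genes = 10)$category,
               "solo")
  expect_equal(classify_locus("target", ft5, window_genes = 12)$category,
               "CAS")

  expect_error(classify_locus("absent", ft), "not found")
})

test_that("arrangement typing distinguishes the canonical module layouts", {
  ft <- mk_features(c("cas4", "cas1", "cas2", "cas6"), gene_idx = 1)
  expect_equal(classify_locus("target", ft)$arrangement,
               "cas4-cas1-cas2-cas6")

  ft2 <- mk_features(c("cas4", "cas4", "cas1", "cas2"), gene_idx = 1)
  expect_equal(classify_locus("target", ft2)$arrangement, "two-cas4")

  ft3 <- mk_features(c("cas4/cas1 fusion", "cas2"), gene_idx = 1)
  expect_equal(classify_locus("target", ft3)$arrangement, "fusion-cas2")

  # reversed gene order (minus-strand layout) still matches
  ft4 <- mk_features(c("cas2", "cas1", "cas4"), gene_idx = 3)
  expect_equal(classify_locus("target", ft4)$arrangement, "cas4-cas1-cas2")
})

test_that("fusion genes are CAS regardless of context", {
  expect_true(fusion_detect("cas4/cas1 fusion"))
  expect_false(fusion_detect("cas4"))
  # fusion on a viral contig: fusion precedence wins over MGE evidence
  ft <- mk_features(c("mge_marker", "cas4/cas1 fusion", "other"),
                    replicon = "viral", gene_idx = 2)
  expect_equal(classify_locus("target", ft)$category, "CAS")
})

test_that("classification is total over the three categories", {
  set.seed(61)
  sim <- small_simulation(seed = 62, n_genomes = 12)
  cl <- classify_all(sim$gene_map$gene_id, sim$features)
  expect_equal(nrow(cl), nrow(sim$gene_map))
  expect_true(all(cl$category %in% c("CAS", "solo", "MGE")))
  expect_true(all(cl$arrangement[cl$category != "CAS"] == "none"))
})

test_that("genome weights are inverse species sizes and sum to 1 per species", {
  g <- data.frame(genome_id = c("a1", "a2", "a3", "b1"),
                  species_id = c("spA", "spA", "spA", "spB"))
  w <- genome_weights(g)
  expect_equal(w$weight, c(1/3, 1/3, 1/3, 1))
  expect_equal(as.numeric(tapply(w$weight, w$species_id, sum)), c(1, 1))
})

test_that("presence summary partitions each domain with weights", {
  cls <- data.frame(gene_id = c("x1", "x2"),
                    genome_id = c("a1", "a1"),
                    category = c("CAS", "solo"), stringsAsFactors = FALSE)
  w <- data.frame(genome_id = c("a1", "a2"), weight = c(0.5, 0.5))
  dom <- c(a1 = "archaea", a2 = "archaea")
  ps <- presence_summary(cls, w, dom)
  expect_equal(ps$both, 0.5)
  expect_equal(ps$neither, 0.5)
  expect_equal(ps$cas_only + ps$solo_only + ps$both + ps$neither, 1)

  # all-CAS world
  cls2 <- data.frame(gene_id = "x", genome_id = "a2", category = "CAS")
  ps2 <- presence_summary(cls2, data.frame(genome_id = "a2", weight = 1),
                          c(a2 = "bacteria"))
  expect_equal(ps2$cas_only, 1)

  expect_error(presence_summary(cls, w, c(a1 = "archaea")), "missing domain")
})

test_that("independent placement makes P(both) ~ P(CAS) x P(solo)", {
  set.seed(63)
  n <- 4000
  has_cas <- runif(n) < 0.6
  has_solo <- runif(n) < 0.3
  cls <- rbind(
    data.frame(gene_id = paste0("c", which(has_cas)),
               genome_id = paste0("g", which(has_cas)), category = "CAS"),
    data.frame(gene_id = paste0("s", which(has_solo)),
               genome_id = paste0("g", which(has_solo)), category = "solo"))
  w <- data.frame(genome_id = paste0("g", 1:n), weight = 1 / n)
  dom <- setNames(rep("archaea", n), paste0("g", 1:n))
  ps <- presence_summary(cls, w, dom)
  p_cas <- ps$cas_only + ps$both
  p_solo <- ps$solo_only + ps$both
  expect_lt(abs(ps$both - p_cas * p_solo), 0.03)
})

test_that("one-per-species counts match a brute-force dedup oracle", {
  # 3 strains of one species, all CAS I-B -> count 1
  cls <- data.frame(gene_id = paste0("x", 1:3),
                    genome_id = c("s1a", "s1b", "s1c"),
                    category = "CAS", arrangement = "cas4-cas1-cas2",
                    standalone_adaptation_module = FALSE, subtype = "I-B",
                    stringsAsFactors = FALSE)
  sp <- c(s1a = "sp1", s1b = "sp1", s1c = "sp1")
  cnt <- one_per_species_counts(cls, sp)
  expect_equal(cnt$count[cnt$group == "CAS:I-B"], 1L)

  # random multi-strain fixture vs explicit dedup
  set.seed(64)
  n <- 60
  cls2 <- data.frame(
    gene_id = paste0("y", 1:n),
    genome_id = paste0("g", sample(30, n, TRUE)),
    category = sample(c("CAS", "solo", "MGE"), n, TRUE),
    arrangement = "none", standalone_adaptation_module = FALSE,
    subtype = sample(c("I-A", "I-B", NA), n, TRUE),
    stringsAsFactors = FALSE)
  cls2 <- cls2[!duplicated(cls2$genome_id), ]
  sp2 <- setNames(paste0("sp", (as.integer(sub("g", "",
                                               unique(cls2$genome_id))) %% 7)),
                  unique(cls2$genome_id))
  cnt2 <- one_per_species_counts(cls2, sp2)
  oracle <- local({
    g <- ifelse(cls2$category == "CAS",
                paste0("CAS:", ifelse(is.na(cls2$subtype), "unknown",
                                      cls2$subtype)),
                cls2$category)
    tab <- unique(data.frame(g, sp = sp2[cls2$genome_id]))
    table(tab$g)
  })
  expect_equal(setNames(cnt2$count, cnt2$group),
               setNames(as.integer(oracle), names(oracle)))
})
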