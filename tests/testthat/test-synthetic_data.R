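test_that("species tree simulation is ultrametric, labeled and deterministic", {
  t2 <- simulate_species_tree(2, 1, seed = 1)
  d <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d[1], d[2])

  t50a <- simulate_species_tree(50, 1, seed = 1)
  t50b <- simulate_species_tree(50, 1, seed = 1)
  expect_identical(ape::write.tree(t50a), ape::write.tree(t50b))
  expect_equal(t50a$Nnode, 49)                 # binary: n - 1 internal nodes
  expect_equal(sort(t50a$tip.label), sprintf("g%03d", 1:50))
  expect_true(all(t50a$edge.length > 0))

  th <- simulate_species_tree(10, 1, seed = 2, height = 1)
  expect_equal(max(ape::node.depth.edgelength(th)), 1)

  expect_error(simulate_species_tree(1, 1), ">= 2")
})

test_that("gene family evolution respects its event model", {
  sp <- simulate_species_tree(20, 1, seed = 3)

  # no events: gene tree identical to species tree
  fam0 <- evolve_gene_family(sp, 0, 0, 0, seed = 4)
  expect_equal(nrow(fam0$transfer_events), 0L)
  g0 <- fam0$gene_tree
  g0$tip.label <- sub("\\.1$", "", g0$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(sp), ape::unroot(g0))), 0)
  expect_isomorphic_trees(sp, g0, tol = 1e-6)

  # duplications create multi-copy genomes
  famd <- evolve_gene_family(sp, 0, 0.3, 0, seed = 5)
  expect_gt(max(table(famd$gene_map$genome_id)), 1)

  # losses shrink the family; deterministic under the same seed
  faml <- evolve_gene_family(sp, 0, 0, 0.2, seed = 6)
  expect_lt(nrow(faml$gene_map), 20)
  faml2 <- evolve_gene_family(sp, 0, 0, 0.2, seed = 6)
  expect_identical(ape::write.tree(faml$gene_tree),
                   ape::write.tree(faml2$gene_tree))

  # transfer counts scale with the rate
  n2 <- vapply(1:20, function(s)
    nrow(evolve_gene_family(sp, 2, seed = s)$transfer_events), integer(1))
  n0 <- vapply(1:20, function(s)
    nrow(evolve_gene_family(sp, 0, seed = s)$transfer_events), integer(1))
  expect_gt(mean(n2), mean(n0))
  expect_equal(mean(n0), 0)
})

test_that("transfers reshape the gene tree away from the species tree", {
  sp <- simulate_species_tree(30, 1, seed = 7)
  rf <- vapply(1:10, function(s) {
    fam <- evolve_gene_family(sp, 3, seed = s)
    g <- fam$gene_tree
    g$tip.label <- sub("\\.1$", "", g$tip.label)
    as.numeric(ape::dist.topo(ape::unroot(sp), ape::unroot(g)))
  }, numeric(1))
  expect_gt(mean(rf), 0)
})

test_that("codon simulation honors the model constraints", {
  tr <- ape::read.tree(text = "((x.1:0.2,y.1:0.2):0.1,z.1:0.3);")

  # zero branch lengths: all sequences equal the root sequence
  t0 <- tr; t0$edge.length <- rep(0, nrow(t0$edge))
  s0 <- simulate_codon_sequences(t0, 0.5, 2, 40, seed = 8)
  expect_length(unique(s0$cds$residues), 1)

  # in-frame, stop-free output; proteins are exact translations
  sq <- simulate_codon_sequences(tr, 0.5, 2, 100, seed = 9)
  expect_true(all(nchar(sq$cds$residues) %% 3 == 0))
  expect_false(any(grepl("\\*", translate_cds(sq$cds$residues))))
  expect_equal(translate_cds(sq$cds$residues), sq$protein$residues)

  # omega = 0 with long branches: proteins identical, nucleotides differ
  tl <- tr; tl$edge.length <- tl$edge.length * 10
  sz <- simulate_codon_sequences(tl, 0, 2, 150, seed = 10)
  expect_length(unique(sz$protein$residues), 1)
  expect_gt(length(unique(sz$cds$residues)), 1)

  expect_error(simulate_codon_sequences(tr, -0.1, 2, 10), "omega")

  # nonsynonymous divergence increases with omega
  tp <- ape::read.tree(text = "(x.1:0.4,y.1:0.4);")
  aa_div <- vapply(c(0.05, 0.5, 1.0), function(om) {
    mean(vapply(1:10, function(s) {
      sq <- simulate_codon_sequences(tp, om, 2, 100, seed = s)
      p <- strsplit(sq$protein$residues, "")
      mean(p[[1]] != p[[2]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aa_div) > 0))
})

test_that("the 16S-like marker evolves slowly and deterministically", {
  sp <- simulate_species_tree(10, 1, seed = 11, height = 1)
  r1 <- simulate_marker(sp, 500, 0.1, seed = 12)
  r2 <- simulate_marker(sp, 500, 0.1, seed = 12)
  expect_identical(r1$residues, r2$residues)
  expect_equal(r1$genome_id, sp$tip.label)
  m <- do.call(rbind, strsplit(r1$residues, ""))
  pmax_ <- max(vapply(2:10, function(i) mean(m[1, ] != m[i, ]), numeric(1)))
  expect_lt(pmax_, 0.3)  # far from saturation at 0.1x clock
})

test_that("genome tables encode the locus architecture and recover labels", {
  sp <- simulate_species_tree(15, 1, seed = 13)
  fam <- evolve_gene_family(sp, 0, 0.1, 0, seed = 14)

  # pure operon mix: cas1 within two features of every family gene
  tab1 <- emit_genome_tables(fam$gene_map, c(cas_operon = 1, solo = 0,
                                             mge = 0), seed = 15)
  for (gid in fam$gene_map$gene_id) {
    ft <- tab1$features
    k <- match(gid, ft$gene_id)
    nb <- ft[ft$contig_id == ft$contig_id[k], ]
    nb <- nb[order(nb$start), ]
    i <- match(gid, nb$gene_id)
    near <- nb[max(1, i - 2):min(nrow(nb), i + 2), ]
    expect_true(any(near$annotation %in% c("cas1", "cas4/cas1 fusion")))
    expect_true(all(near$strand[near$annotation %in%
                                  c("cas1", "cas2")] == "+"))
  }

  # pure MGE mix: every family gene off the chromosome
  tab3 <- emit_genome_tables(fam$gene_map, c(cas_operon = 0, solo = 0,
                                             mge = 1), seed = 16)
  k <- match(fam$gene_map$gene_id, tab3$features$gene_id)
  expect_true(all(tab3$features$replicon_class[k] != "chromosome"))

  # every gene labeled exactly once
  expect_setequal(names(tab1$true_labels), fam$gene_map$gene_id)
})

test_that("same config and seed reproduce byte-identical outputs", {
  cfg <- simulation_config(n_genomes = 8, hgt_rate = 1, dup_rate = 0.1,
                           seq_len_codons = 30, rrna_len = 120, seed = 99)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fasta(s1$sequences$protein, file.path(d1, "p.faa"))
  write_fasta(s2$sequences$protein, file.path(d2, "p.faa"))
  write_feature_table(s1$features, file.path(d1, "f.tsv"))
  write_feature_table(s2$features, file.path(d2, "f.tsv"))
  expect_identical(readLines(file.path(d1, "p.faa")),
                   readLines(file.path(d2, "p.faa")))
  expect_identical(readLines(file.path(d1, "f.tsv")),
                   readLines(file.path(d2, "f.tsv")))
  expect_identical(ape::write.tree(s1$gene_tree),
                   ape::write.tree(s2$gene_tree))
})

test_that("config validation rejects malformed worlds", {
  expect_error(simulation_config(locus_mix = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(simulation_config(n_genomes = 1), "n_genomes")
  expect_error(simulation_config(omega = -1), "omega")
})
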