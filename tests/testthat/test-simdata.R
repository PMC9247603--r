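test_that("configuration invariants are enforced", {
  expect_error(sim_config(chimera_rate = 1), "chimera_rate")
  expect_error(sim_config(polyploid_events = list(
    ppevent("P1", c("spA", "spB"), 5.0))), "crown age")
  expect_error(ppevent("P1", c("spA", "spA"), 1.0, ploidy = 4), "distinct")
  expect_error(ppevent("P1", c("spA", "spB", "spC"), 1.0, ploidy = 4),
               "one parent per subgenome")
  ev <- ppevent("P1", "spA", 1.0)
  expect_equal(ev$type, "auto")
  expect_equal(ev$ploidy, 4L)
})

test_that("a history without polyploids is an ordinary species tree", {
  cfg <- preset_config("diploids_only", rng_seed = 1)
  h <- simulate_history(cfg)
  expect_equal(sort(h$mul_tree$tip.label), paste0("sp", LETTERS[1:4]))
  expect_equal(nrow(h$network$reticulations), 0)
  expect_equal(igraph::gsize(h$network$graph), nrow(h$mul_tree$edge))
})

test_that("planted polyploids satisfy the MUL-tree invariants", {
  h_auto <- simulate_history(preset_config("autotetraploid", rng_seed = 2))
  expect_true(ape::is.monophyletic(h_auto$mul_tree, c("P1.sg1", "P1.sg2")))
  # leaf count = sum of ploidy/2 over lineages
  expect_equal(length(h_auto$mul_tree$tip.label),
               sum(h_auto$samples$ploidy / 2))
  expect_equal(h_auto$network$reticulations$in_degree, 1)

  h_hex <- simulate_history(preset_config("allohexaploid", rng_seed = 2))
  expect_equal(length(h_hex$mul_tree$tip.label), 4 + 3)
  expect_equal(h_hex$network$reticulations$in_degree, 3)
  expect_setequal(h_hex$subgenomes$parent, c("spA", "spC", "spD"))
  expect_equal(unname(h_hex$maternal["P1"]), "spA")

  # subgenome leaves attach at the origin time on each parent branch
  hgt <- polycoal:::node_heights(h_hex$mul_tree)
  parent <- rep(NA_integer_, length(hgt))
  parent[h_hex$mul_tree$edge[, 2]] <- h_hex$mul_tree$edge[, 1]
  for (leaf in h_hex$subgenomes$leaf) {
    v <- which(h_hex$mul_tree$tip.label == leaf)
    expect_equal(hgt[parent[v]], 1.5, tolerance = 1e-8)
  }
})

test_that("default crown age is honoured and origins after lineage merging are rejected", {
  cfg <- sim_config(n_diploid_lineages = 4, rng_seed = 3)
  h <- simulate_history(cfg)
  expect_equal(max(polycoal:::node_heights(h$mul_tree)), 4.39,
               tolerance = 1e-8)
  # spA and spB coalesce at 3.5 Ma on the preset tree: a 4 Ma hybrid of the
  # two names a single ancestral branch twice
  cfg_bad <- preset_config("diploids_only")
  cfg_bad$polyploid_events <- list(ppevent("P1", c("spA", "spB"), 4.0))
  expect_error(simulate_history(cfg_bad), "not distinct")
})

test_that("seeded simulations are bit-reproducible", {
  run <- function() {
    gt <- simulate_gene_trees(
      simulate_history(preset_config("allotetraploid", rng_seed = 31)),
      n_trees = 5)
    list(trees = lapply(gt$samples$L1$trees, ape::write.tree),
         reg = gt$registry)
  }
  expect_identical(run(), run())
})

test_that("gene-tree concordance matches the three-taxon coalescent probability", {
  # species tree ((A,B),C) with an internal branch of exactly 1 coalescent
  # unit (1.5 Ma at N = 2.5e5, 3-year generations); single allele per
  # species so the closed form 1 - (2/3) exp(-T) applies
  cfg <- sim_config(n_diploid_lineages = 3,
                    species_tree = "((spA:1.5,spB:1.5):1.5,spC:3);",
                    rng_seed = 17)
  h <- simulate_history(cfg)
  set.seed(17)
  entering <- list(spA = "a", spB = "b", spC = "c")
  n <- 1500
  conc <- 0
  for (i in seq_len(n)) {
    tr <- polycoal:::msc_tree(h$pop_table, entering, cfg)
    conc <- conc + ape::is.monophyletic(tr, c("a", "b"))
  }
  p_hat <- conc / n
  p_true <- 1 - (2 / 3) * exp(-1)   # 0.7547
  expect_lt(abs(p_hat - p_true), 0.035)
})

test_that("truth assignment is a perfect partition of each polyploid's alleles", {
  gt <- simulate_gene_trees(
    simulate_history(preset_config("allohexaploid", rng_seed = 5)),
    n_trees = 2)
  reg <- gt$registry
  poly <- reg[reg$sample == "P1" & reg$locus != "pt", ]
  for (l in unique(poly$locus)) {
    d <- poly[poly$locus == l, ]
    expect_equal(nrow(d), 6)
    expect_equal(sort(as.integer(table(d$subgenome))), c(2L, 2L, 2L))
    expect_false(any(is.na(d$subgenome)))
  }
  # every gene tree carries exactly the registered alleles
  for (l in paste0("L", 1:5)) {
    for (tr in gt$samples[[l]]$trees) {
      expect_setequal(tr$tip.label, reg$allele[reg$locus == l])
    }
  }
})

test_that("plastid lineages are maternally inherited", {
  gt <- simulate_gene_trees(
    simulate_history(preset_config("allotetraploid", rng_seed = 19)),
    n_trees = 2, n_trees_plastid = 25)
  reg <- gt$registry
  expect_equal(sum(reg$locus == "pt"), 5)          # one per sample
  # maternal parent is spA: P1's plastid should coalesce with spA's more
  # often than with spC's (they share the branch from 1.5 Ma upward)
  with_mat <- vapply(gt$samples$pt$trees, function(tr) {
    m_a <- ape::getMRCA(tr, c("P1.pt.a1", "spA.pt.a1"))
    m_c <- ape::getMRCA(tr, c("P1.pt.a1", "spC.pt.a1"))
    length(ape::extract.clade(tr, m_a)$tip.label) <
      length(ape::extract.clade(tr, m_c)$tip.label)
  }, logical(1))
  expect_gt(mean(with_mat), 0.5)
})

test_that("read simulation honours depth, error and chimera settings", {
  set.seed(21)
  al <- synth_alleles(2, 200, 0.03)
  clean <- simulate_reads(al, depth = 50, error_rate = 0, chimera_rate = 0,
                          lowq_read_frac = 0)
  expect_true(all(clean$seq %in% unname(al)))

  rs <- simulate_reads(al, depth = 600, error_rate = 0, chimera_rate = 0,
                       lowq_read_frac = 0)
  counts <- table(rs$truth$allele)
  # binomial(600, 1/2): 4 sd ~ 49
  expect_true(all(abs(counts - 300) < 50))

  ch <- simulate_reads(al, depth = 600, error_rate = 0, chimera_rate = 0.1,
                       lowq_read_frac = 0)
  expect_lt(abs(mean(ch$truth$chimera) - 0.1), 0.04)
})

test_that("simulated data sets round-trip through plain-text files", {
  cfg <- preset_config("allotetraploid", rng_seed = 41, n_loci = 1,
                       read_depth = 30, seq_length = 120)
  ds <- simulate_dataset(cfg, n_trees = 2)
  dir <- withr::local_tempdir()
  write_simdata(ds, dir)
  expect_true(file.exists(file.path(dir, "spA_L1.fastq")))
  back <- read_fastq(file.path(dir, "spA_L1.fastq"))
  expect_identical(back$seq, ds$reads$spA$L1$seq)
  expect_identical(back$qual, ds$reads$spA$L1$qual)
  fa <- read_fasta(file.path(dir, "true_alleles.fasta"))
  expect_identical(unname(fa[ds$alleles$allele[1]]), ds$alleles$seq[1])
  nwk <- ape::read.tree(file.path(dir, "genetrees_L1.nwk"))
  expect_length(nwk, 2)
  expect_match(readLines(file.path(dir, "true_network.enwk")), "#H1")
})
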