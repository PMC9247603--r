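test_that("haplotype collapsing merges identical sequences and flags long deletions", {
  aln <- c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGA")
  ht <- collapse_haplotypes(aln)
  expect_equal(nrow(ht$table), 2)
  expect_equal(sum(ht$table$count), 3)
  expect_equal(ht$table$count[ht$table$sequence == "ACGTACGT"], 2)

  one <- collapse_haplotypes(c(a = "AAAA", b = "AAAA"))
  expect_equal(nrow(one$table), 1)
  expect_equal(one$table$count, 2)

  del <- c(x = paste0(paste0(rep("-", 25), collapse = ""), "ACGT"),
           y = paste0(paste0(rep("A", 25), collapse = ""), "ACGT"))
  expect_identical(collapse_haplotypes(del, long_del = 20)$flagged, "x")

  # gap-column exclusion mode drops gapped columns before collapsing
  g <- c(p = "A-GT", q = "ACGT")
  hg <- collapse_haplotypes(g, indel_mode = "ignore-gap-columns")
  expect_equal(nrow(hg$table), 1)
})

test_that("step distances count substitutions plus one step per indel run", {
  expect_equal(haplotype_steps("ACGT", "ACGA"), 1)
  expect_equal(haplotype_steps("AC--T", "ACGGT"), 1)   # one 2-bp indel
  expect_equal(haplotype_steps("AC--T", "ACGGA"), 2)
  expect_equal(haplotype_steps("ACGT", "ACGT"), 0)
})

test_that("the parsimony limit behaves like the published calculation", {
  expect_gte(parsimony_limit(600), parsimony_limit(300))
  expect_gte(parsimony_limit(300), parsimony_limit(100))
  expect_lte(parsimony_limit(600, alpha = 0.999), 2)
  expect_gte(parsimony_limit(600, alpha = 0.95), 1)

  # Monte-Carlo oracle of the same series: draw the true mutation count H
  # from the geometric prior (theta = j), scatter hits over m sites, and
  # estimate P(H = j | exactly j sites hit)
  set.seed(91)
  mc_parsimony <- function(j, m, nrep = 40000) {
    h <- rgeom(nrep, prob = 1 / (1 + j))
    keep <- h >= j
    h <- h[keep]
    distinct <- vapply(h, function(hh)
      length(unique(sample.int(m, hh, replace = TRUE))), integer(1))
    mean(h[distinct == j] == j)
  }
  for (j in c(2, 5, 8)) {
    p_pkg <- polycoal:::parsimony_prob(j, 600)
    p_mc <- mc_parsimony(j, 600)
    expect_lt(abs(p_pkg - p_mc), 0.02)
  }
})

test_that("network construction follows distance order with intermediates", {
  # chain A-B-C: the 2-step A-C pair is already connected within its length
  tab <- data.frame(haplotype = c("H1", "H2", "H3"),
                    sequence = c("AAAA", "AAAT", "AATT"),
                    count = c(3L, 1L, 2L),
                    samples = c("a,b,c", "d", "e,f"))
  net <- build_network(tab, limit = 5)
  el <- igraph::as_data_frame(net$graph)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el$from, el$to), c("H1 H2", "H2 H3"))

  # beyond the limit: two components
  far <- data.frame(haplotype = c("H1", "H2"),
                    sequence = c("AAAAAAAA", "TTTTTTTT"),
                    count = c(1L, 1L), samples = c("a", "b"))
  net2 <- build_network(far, limit = 3)
  expect_equal(igraph::components(net2$graph)$no, 2)
  expect_equal(igraph::gsize(net2$graph), 0)

  # a single haplotype is a single node without edges
  net3 <- build_network(tab[1, ], limit = 3)
  expect_equal(igraph::gorder(net3$graph), 1)
  expect_equal(igraph::gsize(net3$graph), 0)

  # multi-step connections insert degree->=2 hypothetical intermediates and
  # graph distance equals mutational distance on tree-like data
  tab4 <- data.frame(haplotype = c("H1", "H2"),
                     sequence = c("AAAAAA", "AATTTA"),
                     count = c(1L, 1L), samples = c("a", "b"))
  net4 <- build_network(tab4, limit = 5)
  g4 <- net4$graph
  hypo <- igraph::V(g4)[!igraph::V(g4)$observed]
  expect_length(hypo, 2)
  expect_true(all(igraph::degree(g4, hypo) >= 2))
  expect_equal(unname(igraph::distances(g4, "H1", "H2")[1, 1]), 3)
})

test_that("graph distances never exceed mutational distances within components", {
  set.seed(14)
  seqs <- synth_alleles(6, 40, 0.05)
  tab <- collapse_haplotypes(setNames(unname(seqs), paste0("s", 1:6)))
  net <- build_network(tab, limit = 12)
  g <- net$graph
  for (i in 1:5) for (j in (i + 1):6) {
    hi <- tab$table$haplotype[tab$table$sequence == unname(seqs)[i]]
    hj <- tab$table$haplotype[tab$table$sequence == unname(seqs)[j]]
    d_mut <- haplotype_steps(unname(seqs)[i], unname(seqs)[j])
    d_graph <- igraph::distances(g, hi, hj)[1, 1]
    if (is.finite(d_graph)) expect_lte(d_graph, d_mut)
  }
})

test_that("plastid haplotypes of an allopolyploid travel with the maternal lineage", {
  cfg <- preset_config("allotetraploid", rng_seed = 71)
  gt <- simulate_gene_trees(simulate_history(cfg), n_trees = 1,
                            n_trees_plastid = 30)
  # across sampled plastid genealogies, P1 shares its most recent common
  # ancestor with maternal spA more often than with paternal spC
  closer_mat <- vapply(gt$samples$pt$trees, function(tr) {
    ca <- length(ape::extract.clade(
      tr, ape::getMRCA(tr, c("P1.pt.a1", "spA.pt.a1")))$tip.label)
    cc <- length(ape::extract.clade(
      tr, ape::getMRCA(tr, c("P1.pt.a1", "spC.pt.a1")))$tip.label)
    ca < cc
  }, logical(1))
  expect_gt(mean(closer_mat), 0.6)
})
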