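mk_mul <- function() {
  # ((X1:1,A:1)0.9:1,(X2:1.5,B:1.5)0.95:0.5); with supports as node labels
  tr <- ape::read.tree(text = "((X1:1,A:1):1,(X2:1.5,B:1.5):0.5);")
  tr$node.label <- c("", "0.9", "0.95")
  tr
}

test_that("support collapsing is strict at the threshold and keeps heights", {
  tr <- mk_mul()
  full <- collapse_low_support(tr, 0.7)
  expect_equal(full$Nnode, tr$Nnode)        # all supports >= 0.7: identity

  tr69 <- tr; tr69$node.label <- c("", "0.69", "0.95")
  col <- collapse_low_support(tr69, 0.7)
  expect_equal(col$Nnode, 2)                # one branch contracted
  h <- polycoal:::node_heights(col)
  expect_equal(max(h), 2, tolerance = 1e-9) # root height unchanged
  expect_true(all(c("X1", "A") %in% col$tip.label))

  tr70 <- tr; tr70$node.label <- c("", "0.70", "0.95")
  expect_equal(collapse_low_support(tr70, 0.7)$Nnode, 3)   # exactly 0.70 kept
})

test_that("folding a MUL-tree joins subgenome leaves into reticulations", {
  net <- join_subgenome_leaves(mk_mul(), list(X = c("X1", "X2")),
                               maternal = c(X = "X1"))
  expect_equal(net$reticulations$in_degree, 2)
  expect_equal(net$reticulations$type, "reticulate")
  # leaf count: MUL leaves minus (subgenomes - 1)
  expect_length(net$leaves, 4 - 1)
  el <- igraph::as_data_frame(net$graph)
  expect_true(el$maternal[el$to == "X" & el$via_leaf == "X1"])
  expect_false(el$maternal[el$to == "X" & el$via_leaf == "X2"])
  expect_match(write_enewick(net), "#H1")

  # autopolyploid cherry collapses to a single annotated edge
  auto <- ape::read.tree(text = "(((X1:1,X2:1):1,A:2):1,B:3);")
  auto$node.label <- rep("1", 3)
  net2 <- join_subgenome_leaves(auto, list(X = c("X1", "X2")))
  expect_equal(net2$reticulations$in_degree, 1)
  expect_equal(net2$reticulations$type, "autopolyploid")
  el2 <- igraph::as_data_frame(net2$graph)
  expect_equal(el2$n_merged[el2$to == "X"], 2)

  # no polyploids: the network is the tree
  net3 <- join_subgenome_leaves(mk_mul(), list())
  expect_equal(igraph::gsize(net3$graph), nrow(mk_mul()$edge))
  expect_error(join_subgenome_leaves(mk_mul(), list(X = c("X1", "X9"))),
               "missing")
})

test_that("collapsing and folding commute away from the reticulation", {
  tr <- ape::read.tree(
    text = "(((X1:1,A:1):1,B:2):1,((X2:1,C:1):1,D:2):1);")
  tr$node.label <- c("", "0.5", "1", "0.5", "1")
  poly <- list(X = c("X1", "X2"))
  a <- join_subgenome_leaves(collapse_low_support(tr, 0.7), poly)
  b <- join_subgenome_leaves(tr, poly)   # collapse has no counterpart after
  expect_equal(sort(a$leaves), sort(b$leaves))
  expect_equal(a$reticulations$in_degree, b$reticulations$in_degree)
})

test_that("HPD merging returns the covering interval", {
  expect_equal(merge_hpd(list(c(0.5, 1.5))), c(0.5, 1.5))
  expect_equal(merge_hpd(list(c(0.59, 1.8), c(1.2, 2.87))), c(0.59, 2.87))
  expect_equal(merge_hpd(list(c(0.2, 0.5), c(1.0, 4.54))), c(0.2, 4.54))
  m <- rbind(c(0.59, 1.8), c(1.2, 2.87), c(0.9, 1.1))
  out <- merge_hpd(m)
  for (i in seq_len(nrow(m))) {
    expect_lte(out[1], m[i, 1]); expect_gte(out[2], m[i, 2])
  }
  expect_error(merge_hpd(list()), "no intervals")
  expect_error(merge_hpd(list(c(2, 1))), "lower")
})

test_that("annotated trees round-trip supports, heights and HPDs", {
  txt <- paste0("((X1[&height_95%_HPD={0.0,0.0}]:1.2,",
                "A:1.2)[&posterior=0.97,height_95%_HPD={0.59,1.8}]:1.0,",
                "(X2:1.7,B:1.7)[&posterior=0.88,height_95%_HPD={1.2,2.87}]",
                ":0.5)[&posterior=1.0];")
  tr <- read_annotated_tree(txt)
  expect_setequal(tr$tip.label, c("X1", "A", "X2", "B"))
  expect_setequal(as.numeric(tr$node.label), c(1.0, 0.97, 0.88))
  hpd <- attr(tr, "hpd")
  expect_true(all(c("A|X1", "B|X2") %in% hpd$clade))
  expect_equal(hpd[hpd$clade == "A|X1", c("lower", "upper")],
               data.frame(lower = 0.59, upper = 1.8),
               ignore_attr = TRUE)

  # polyploid age = covering interval of its subgenome divergence HPDs
  expect_equal(polyploid_age(tr, c("X1", "X2")), c(0.59, 2.87))
})

test_that("scenario ranking separates planted single and double origins", {
  cfg <- preset_config("two_origins", rng_seed = 55, n_loci = 4)
  gt <- simulate_gene_trees(simulate_history(cfg), n_trees = 40,
                            plastid = NULL)
  nuc <- paste0("L", 1:4)
  alleles <- gt$registry[gt$registry$locus %in% nuc,
                         c("allele", "locus", "sample", "lineage", "ploidy")]
  scen <- list(
    two_lineages = list(T1 = "P1", T2 = "P2"),
    one_lineage  = list(T1 = c("P1", "P2")))
  rk <- rank_scenarios(gt$samples[nuc], alleles, scen,
                       iterations = 200, restarts = 4, seed = 8)
  expect_identical(rk$scenario[1], "two_lineages")
  expect_lt(rk$score[1], rk$score[2])
  # deterministic given the seed
  rk2 <- rank_scenarios(gt$samples[nuc], alleles, scen,
                        iterations = 200, restarts = 4, seed = 8)
  expect_identical(rk, rk2)
})
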