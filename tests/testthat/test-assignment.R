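# Fixture: one tetraploid P with two diploid parents A and B, two loci,
# gene trees in which P's alleles split cleanly into an A-like and a B-like
# pair (p1,p2 ~ A; p3,p4 ~ B at L1; p1,p3 ~ A at L2).
fix_alleles <- function() {
  rbind(
    data.frame(allele = c("a1", "a2", "b1", "b2", "p1", "p2", "p3", "p4"),
               locus = "L1", sample = c("A", "A", "B", "B", rep("P", 4)),
               lineage = c("A", "A", "B", "B", NA, NA, NA, NA), ploidy = c(2, 2, 2, 2, 4, 4, 4, 4)),
    data.frame(allele = c("a3", "a4", "b3", "b4", "q1", "q2", "q3", "q4"),
               locus = "L2", sample = c("A", "A", "B", "B", rep("P", 4)),
               lineage = c("A", "A", "B", "B", NA, NA, NA, NA), ploidy = c(2, 2, 2, 2, 4, 4, 4, 4)))
}

fix_samples <- function() {
  list(
    tiny_sample(rep("(((a1,a2),(p1,p2)),((b1,b2),(p3,p4)));", 3), "L1"),
    tiny_sample(rep("(((a3,a4),(q1,q3)),((b3,b4),(q2,q4)));", 3), "L2"))
}

truth_bins <- function() {
  list(P = list(L1 = c(p1 = 1L, p2 = 1L, p3 = 2L, p4 = 2L),
                L2 = c(q1 = 1L, q2 = 2L, q3 = 1L, q4 = 2L)))
}

test_that("the truth assignment of a clean allotetraploid scores zero and wrong bins score worse", {
  map <- lineage_map(fix_alleles())
  sc <- score_assignment(fix_samples(), map, truth_bins())
  expect_equal(as.numeric(sc), 0)
  st <- attr(sc, "species_tree")
  expect_true(ape::is.monophyletic(st, c("A", "P.sg1")) ||
              ape::is.monophyletic(st, c("A", "P.sg2")))
  wrong <- truth_bins()
  wrong$P$L1 <- c(p1 = 1L, p2 = 2L, p3 = 1L, p4 = 2L)  # mixes parents
  expect_gt(as.numeric(score_assignment(fix_samples(), map, wrong)), 0)
})

test_that("scores are invariant under wholesale bin relabeling", {
  map <- lineage_map(fix_alleles())
  sc1 <- as.numeric(score_assignment(fix_samples(), map, truth_bins()))
  flipped <- truth_bins()
  flipped$P <- lapply(flipped$P, function(b) setNames(3L - b, names(b)))
  sc2 <- as.numeric(score_assignment(fix_samples(), map, flipped))
  expect_equal(sc1, sc2)
  # relabeling only one locus breaks cross-locus coherence and must not
  # score better than the coherent labeling
  one <- truth_bins()
  one$P$L2 <- setNames(3L - one$P$L2, names(one$P$L2))
  expect_gte(as.numeric(score_assignment(fix_samples(), map, one)), sc1)
})

test_that("overfull bins are rejected", {
  map <- lineage_map(fix_alleles())
  bad <- truth_bins()
  bad$P$L1 <- c(p1 = 1L, p2 = 1L, p3 = 1L, p4 = 2L)
  expect_error(score_assignment(fix_samples(), map, bad), "more than 2")
})

test_that("hill climbing equals the brute-force assignment oracle and is seed-deterministic", {
  map <- lineage_map(fix_alleles())
  fit1 <- hill_climb_assignment(fix_samples(), map, iterations = 50,
                                restarts = 3, seed = 9)
  fit2 <- hill_climb_assignment(fix_samples(), map, iterations = 50,
                                restarts = 3, seed = 9)
  expect_identical(fit1$table, fit2$table)
  expect_identical(fit1$score, fit2$score)

  all_scores <- vapply(oracle_assignments(map, "P"), function(a)
    as.numeric(score_assignment(fix_samples(), map, a)), numeric(1))
  expect_equal(fit1$score, min(all_scores))
  expect_equal(fit1$score, 0)

  # the best-so-far trajectory over runs never increases
  expect_true(all(diff(fit1$log$best_score) <= 1e-12))
})

test_that("hill climbing matches the exhaustive oracle on random small instances", {
  set.seed(23)
  hits <- 0L
  for (rep in 1:6) {
    alle <- fix_alleles()
    trees <- list(
      tiny_sample(vapply(1:3, function(i) {
        labs <- sample(c("a1", "a2", "b1", "b2", "p1", "p2", "p3", "p4"))
        ape::write.tree(ape::rtree(8, tip.label = labs))
      }, character(1)), "L1"),
      tiny_sample(vapply(1:3, function(i) {
        labs <- sample(c("a3", "a4", "b3", "b4", "q1", "q2", "q3", "q4"))
        ape::write.tree(ape::rtree(8, tip.label = labs))
      }, character(1)), "L2"))
    map <- lineage_map(alle)
    fit <- hill_climb_assignment(trees, map, iterations = 100, restarts = 5)
    best <- min(vapply(oracle_assignments(map, "P"), function(a)
      as.numeric(score_assignment(trees, map, a)), numeric(1)))
    if (abs(fit$score - best) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 5L)   # >= 95% of small instances in expectation
})

test_that("planted allotetraploid truth is recovered from simulated gene trees", {
  cfg <- preset_config("allotetraploid", rng_seed = 77)
  gt <- simulate_gene_trees(simulate_history(cfg), n_trees = 60,
                            plastid = NULL)
  nuc <- paste0("L", 1:5)
  map <- truth_lineage_map(gt, nuc)
  fit <- hill_climb_assignment(gt$samples[nuc], map, iterations = 300,
                               restarts = 5, seed = 3)
  expect_gte(assignment_accuracy(fit, gt$registry), 0.95)
  tsc <- as.numeric(score_assignment(gt$samples[nuc], map,
                                     truth_assignment(gt, nuc)))
  expect_lte(fit$score, tsc + 1e-9)
})

test_that("accuracy metric is permutation-aware", {
  truth <- data.frame(allele = c("p1", "p2", "p3", "p4"), sample = "P",
                      subgenome = c(1L, 1L, 2L, 2L))
  tab <- data.frame(sample = "P", locus = "L1",
                    allele = c("p1", "p2", "p3", "p4"),
                    subgenome = c(2L, 2L, 1L, 1L))   # flipped labels
  expect_equal(assignment_accuracy(tab, truth), 1)
  tab$subgenome <- c(2L, 1L, 1L, 2L)
  expect_equal(assignment_accuracy(tab, truth), 0.5)
})
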