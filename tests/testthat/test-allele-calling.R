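mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(L)
    rep(35L, L))
  read_set(paste0("r", seq_along(seqs)), seqs, quals)
}

test_that("quality filtering applies the more-than-10% rule exactly", {
  L <- 100
  q_11 <- c(rep(10L, 11), rep(35L, L - 11))   # 11% below 20: discarded
  q_10 <- c(rep(10L, 10), rep(35L, L - 10))   # exactly 10%: retained
  q_hi <- rep(20L, L)                         # Q20 is not below 20
  seqs <- rep(paste0(rep("A", L), collapse = ""), 3)
  rs <- read_set(c("a", "b", "c"), seqs, list(q_11, q_10, q_hi))
  kept <- qc_filter(rs)
  expect_setequal(kept$id, c("b", "c"))
  expect_warning(qc_filter(read_set(character(0), character(0), list())),
                 "empty")
})

test_that("minimum read cutoffs follow the ploidy-aware rule", {
  expect_identical(min_reads_cutoff(600, 6), 50L)
  expect_identical(min_reads_cutoff(600, 2), 150L)
  expect_identical(min_reads_cutoff(600, 4, qc_params(min_read_factor = 1)),
                   150L)
  expect_error(min_reads_cutoff(600, 3), "ploidy")
})

test_that("IUPAC consensus applies the 20% wobble threshold at the boundary", {
  col80 <- c(rep("A", 80), rep("C", 20))   # 20% reaches the threshold -> M
  col81 <- c(rep("A", 81), rep("C", 19))   # 19% stays below -> A
  seqs80 <- paste0(col80, "G")
  seqs81 <- paste0(col81, "G")
  expect_identical(consensus_iupac(seqs80), "MG")
  expect_identical(consensus_iupac(seqs81), "AG")
  expect_identical(consensus_iupac(rep("ACGT", 7)), "ACGT")
  # 50/50 tie with threshold above 50%: IUPAC over the tied bases
  expect_identical(
    consensus_iupac(c("A", "G"), qc_params(wobble_threshold = 0.6)), "R")
  expect_error(consensus_iupac(character(0)), "empty")
})

test_that("chimera detection flags recombinants but not erroneous reads", {
  set.seed(8)
  al <- synth_alleles(2, 120, 0.05)
  a <- al[[1]]; b <- al[[2]]
  k <- 60
  rec <- paste0(substr(a, 1, k), substr(b, k + 1, 120))
  a_err <- a
  substr(a_err, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                   substr(a, 30, 30))[1]
  rs <- mk_reads(c(rec, a_err, a))
  flagged <- detect_chimeras(rs, unname(al))
  expect_identical(flagged, "r1")
  # fewer than two candidates: no-op
  expect_identical(detect_chimeras(rs, unname(al[1])), character(0))
})

test_that("read clustering separates alleles and isolates junk", {
  set.seed(12)
  al <- synth_alleles(2, 300, 0.05)
  pure <- simulate_reads(al[1], depth = 40, error_rate = 0,
                         chimera_rate = 0, lowq_read_frac = 0)
  cl <- cluster_reads(pure)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 40)

  rs <- simulate_reads(al, depth = 300, error_rate = 0.01,
                       chimera_rate = 0, lowq_read_frac = 0)
  cl2 <- cluster_reads(rs)
  big <- cl2[vapply(cl2, `[[`, integer(1), "size") >= 50]
  expect_length(big, 2)
  cons <- vapply(big, function(c_) consensus_iupac(rs$seq[c_$members]),
                 character(1))
  expect_setequal(cons, unname(al))

  junk <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rs3 <- read_set(c(rs$id, "junk"), c(rs$seq, junk),
                  c(rs$qual, list(rep(35L, 300))))
  cl3 <- cluster_reads(rs3)
  sizes <- vapply(cl3, `[[`, integer(1), "size")
  expect_true(any(sizes == 1 &
                  vapply(cl3, function(c_) "junk" %in% c_$ids, logical(1))))
  # partition invariants
  expect_equal(sum(sizes), length(rs3))
  expect_false(anyDuplicated(unlist(lapply(cl3, `[[`, "ids"))) > 0)
})

test_that("called allele sets export to FASTA with support-annotated headers", {
  set.seed(44)
  al <- synth_alleles(2, 120, 0.05)
  rs <- simulate_reads(al, depth = 60, error_rate = 0, chimera_rate = 0,
                       lowq_read_frac = 0)
  out <- call_alleles(rs, 2, sample_id = "s1", locus_id = "L1")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(out, path)
  back <- read_fasta(path)
  expect_length(back, length(out$alleles))
  expect_match(names(back)[1], "^s1\\|L1\\|allele_1\\|reads=\\d+$")
  expect_setequal(unname(back), out$alleles)
})

test_that("clone-recovery probability follows inclusion-exclusion", {
  # printed design: 27 clones give >= 0.95 for six alleles, 26 do not
  expect_gte(prob_all_alleles(27, 6), 0.95)
  expect_lt(prob_all_alleles(26, 6), 0.95)
  expect_identical(clones_needed(6, 0.95), 27L)
  # tiny case against exhaustive enumeration: 2 clones, 2 alleles
  draws <- expand.grid(1:2, 1:2)
  expect_equal(prob_all_alleles(2, 2),
               mean(apply(draws, 1, function(d) length(unique(d)) == 2)))
  expect_identical(prob_all_alleles(5, 6), 0)
  expect_identical(prob_all_alleles(10, 1), 1)
  # nondecreasing in clone number, approaching one
  p <- vapply(6:80, prob_all_alleles, numeric(1), n_alleles = 6)
  expect_true(all(diff(p) >= -1e-12))
  expect_gt(p[length(p)], 0.9999)
})

test_that("fluorescence ratios classify to the published ploidy levels", {
  expect_identical(classify_ploidy(3.278), 2L)
  expect_identical(classify_ploidy(5.804), 4L)
  expect_identical(classify_ploidy(7.431), 6L)
  expect_warning(out <- classify_ploidy(4.5), "nearest")
  expect_identical(out, 2L)
  bad <- data.frame(ploidy = c(2L, 4L), lower = c(3, 3.5), upper = c(4, 6))
  expect_error(classify_ploidy(3.6, bad), "overlap")
})

test_that("the calling pipeline reproduces truth alleles and reports chimeras", {
  set.seed(33)
  ok <- 0L; flag_all <- 0L; chim_all <- 0L
  for (ploidy in c(2L, 4L, 6L)) {
    al <- synth_alleles(ploidy, 300, 0.02)
    rs <- simulate_reads(al, depth = 300, error_rate = 0.01,
                         chimera_rate = 0.1)
    out <- call_alleles(rs, ploidy)
    if (setequal(out$alleles, unique(unname(al)))) ok <- ok + 1L
    kept <- setdiff(rs$truth$id, out$discarded_qc)
    chim <- rs$truth$id[rs$truth$chimera & rs$truth$id %in% kept]
    chim_all <- chim_all + length(chim)
    flag_all <- flag_all + sum(chim %in% out$flagged_chimeras)
    expect_false(out$warning)
  }
  expect_identical(ok, 3L)
  expect_gte(flag_all / chim_all, 0.9)
})
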