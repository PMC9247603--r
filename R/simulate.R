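# Multispecies-coalescent simulation within a planted polyploid history,
# HKY sequence evolution along the simulated genealogies, and amplicon read
# simulation with errors and PCR chimeras.

# One allele row per sampled gene copy per locus.  Polyploid allele ids are
# numbered in a random order so the identifier carries no hint of the true
# subgenome; the truth lives in the `subgenome` column only.
allele_registry <- function(history, loci, plastid = "pt") {
  reg <- NULL
  for (i in seq_len(nrow(history$samples))) {
    s <- history$samples$sample[i]
    kind <- history$samples$kind[i]
    p <- history$samples$ploidy[i]
    nb <- p %/% 2L
    for (l in loci) {
      if (kind == "diploid") {
        reg <- rbind(reg, data.frame(
          allele = paste0(s, ".", l, ".a", 1:2), locus = l, sample = s,
          tip = s, subgenome = NA_integer_, lineage = s, ploidy = 2L))
      } else {
        sg <- sample(rep(seq_len(nb), each = 2L))
        tip <- if (kind == "auto") rep(s, p) else paste0(s, ".sg", sg)
        reg <- rbind(reg, data.frame(
          allele = paste0(s, ".", l, ".a", seq_len(p)), locus = l,
          sample = s, tip = tip, subgenome = sg,
          lineage = NA_character_, ploidy = p))
      }
    }
    if (!is.null(plastid)) {
      d <- history$subgenomes[history$subgenomes$sample == s, ]
      tip <- if (kind == "diploid") s else if (kind == "auto") s else
        history$maternal_leaf[s]
      sg <- if (kind == "diploid") NA_integer_ else
        d$subgenome[match(history$maternal[s], d$parent)]
      reg <- rbind(reg, data.frame(
        allele = paste0(s, ".", plastid, ".a1"), locus = plastid, sample = s,
        tip = tip, subgenome = sg,
        lineage = if (kind == "diploid") s else NA_character_, ploidy = p))
    }
  }
  reg
}

# One coalescent genealogy for the lineages in `entering` (named list:
# population-tree tip label -> allele ids), run within the population tree.
# Branch lengths of the returned phylo are expected substitutions per site.
msc_tree <- function(tab, entering, config, ploidy_scale = 1) {
  kids <- split(tab$id, factor(tab$parent, levels = tab$id))
  root <- tab$id[is.na(tab$parent)]
  gen <- config$generation_time
  sim <- function(v) {
    ch <- kids[[as.character(v)]]
    lin <- list()
    if (length(ch) == 0) {
      al <- entering[[tab$label[v]]]
      lin <- lapply(al, function(a) list(nwk = a, h = tab$height[v] * 1e6))
    } else {
      for (c_ in ch) lin <- c(lin, sim(c_))
    }
    t1 <- if (is.na(tab$parent[v])) Inf else tab$height[tab$parent[v]] * 1e6
    copies <- 2 * config$pop_size * tab$pop_factor[v] * ploidy_scale
    cur <- tab$height[v] * 1e6
    while (length(lin) >= 2) {
      k <- length(lin)
      wait <- rexp(1, rate = k * (k - 1) / 2 / (copies * gen))
      if (cur + wait > t1) break
      cur <- cur + wait
      pick <- sample.int(k, 2)
      a <- lin[[pick[1]]]; b <- lin[[pick[2]]]
      merged <- list(nwk = sprintf("(%s:%.10g,%s:%.10g)",
                                   a$nwk, (cur - a$h) * config$subst_rate,
                                   b$nwk, (cur - b$h) * config$subst_rate),
                     h = cur)
      lin <- c(lin[-pick], list(merged))
    }
    lin
  }
  res <- sim(root)
  stopifnot(length(res) == 1L)
  ape::read.tree(text = paste0(res[[1]]$nwk, ";"))
}

#' Simulate per-locus gene-tree samples under the multispecies coalescent
#'
#' Every nuclear locus receives `n_trees` independent coalescent genealogies
#' run within the planted population history: diploid individuals contribute
#' two allele lineages, each allopolyploid subgenome two lineages in its own
#' disomic population, and an autopolyploid's copies share one tetrasomic
#' population of proportionally larger size.  The plastid locus traces a
#' single lineage per sample through the maternal parent only, at half the
#' nuclear effective size.  The first genealogy of each locus is the "true"
#' allele genealogy used for sequence simulation; the remaining draws stand
#' in for the topological spread of a posterior gene-tree sample.
#'
#' @param history a [simulate_history()] result.
#' @param n_trees genealogies per nuclear locus.
#' @param plastid name of the plastid locus, or `NULL` to skip it.
#' @param n_trees_plastid genealogies for the plastid locus.
#' @return object of class `sim_gene_trees`: list of [gene_tree_sample()]
#'   per locus (`$samples`), the allele registry with truth columns
#'   (`$registry`), and the history.
#' @export
simulate_gene_trees <- function(history, n_trees = 500,
                                plastid = "pt", n_trees_plastid = n_trees) {
  config <- history$config
  loci <- paste0("L", seq_len(config$n_loci))
  reg <- allele_registry(history, loci, plastid)
  samples <- list()
  for (l in c(loci, if (!is.null(plastid)) plastid)) {
    d <- reg[reg$locus == l, ]
    entering <- split(d$allele, d$tip)
    scale <- if (!is.null(plastid) && l == plastid) 0.5 else 1
    nt <- if (!is.null(plastid) && l == plastid) n_trees_plastid else n_trees
    trees <- lapply(seq_len(nt), function(i) {
      msc_tree(history$pop_table, entering, config, ploidy_scale = scale)
    })
    samples[[l]] <- gene_tree_sample(l, trees)
  }
  structure(list(samples = samples, registry = reg, history = history),
            class = "sim_gene_trees")
}

#' Lineage map holding the planted truth labels
#'
#' @param sim a [simulate_gene_trees()] result.
#' @param loci which loci to include (default: all).
#' @param groups optional scenario grouping, as in [lineage_map()].
#' @return a [lineage_map()] covering the simulated alleles.
#' @export
truth_lineage_map <- function(sim, loci = NULL, groups = NULL) {
  reg <- sim$registry
  if (!is.null(loci)) reg <- reg[reg$locus %in% loci, ]
  lineage_map(reg[, c("allele", "locus", "sample", "lineage", "ploidy")],
              groups = groups)
}

#' Planted allele-to-subgenome assignment
#'
#' @param sim a [simulate_gene_trees()] result.
#' @param loci which loci to include (default: all).
#' @return nested bin list, as consumed by [score_assignment()].
#' @export
truth_assignment <- function(sim, loci = NULL) {
  reg <- sim$registry
  if (!is.null(loci)) reg <- reg[reg$locus %in% loci, ]
  reg <- reg[!is.na(reg$subgenome) & reg$ploidy > 2L, ]
  out <- list()
  for (s in unique(reg$sample)) {
    out[[s]] <- list()
    for (l in unique(reg$locus[reg$sample == s])) {
      d <- reg[reg$sample == s & reg$locus == l, ]
      out[[s]][[l]] <- setNames(d$subgenome, d$allele)
    }
  }
  out
}

#' Simulate true allele sequences along the simulated genealogies
#'
#' HKY sequence evolution (phangorn's simulator) along the first genealogy
#' of every locus; branch lengths are expected substitutions per site.
#'
#' @param sim a [simulate_gene_trees()] result.
#' @return data.frame with columns `allele`, `locus`, `sample`, `seq`.
#' @export
simulate_alleles <- function(sim) {
  config <- sim$history$config
  Q <- c(1, config$kappa, 1, 1, config$kappa, 1)
  bf <- c(0.3, 0.2, 0.2, 0.3)
  out <- NULL
  for (l in names(sim$samples)) {
    tr <- sim$samples[[l]]$trees[[1]]
    dat <- phangorn::simSeq(tr, l = config$seq_length, Q = Q, bf = bf,
                            type = "DNA")
    m <- toupper(as.character(dat))
    seqs <- apply(m, 1, paste0, collapse = "")
    d <- sim$registry[sim$registry$locus == l, ]
    out <- rbind(out, data.frame(allele = d$allele, locus = l,
                                 sample = d$sample,
                                 seq = unname(seqs[d$allele])))
  }
  out
}

#' Synthetic allele sets with controlled divergence
#'
#' Generates `n` allele sequences in which every pair differs at exactly
#' `round(divergence * length)` positions from a common reference (distinct
#' positions per allele), guaranteeing a minimum pairwise divergence.  Used
#' to exercise allele calling under stated divergence conditions without a
#' full coalescent simulation.
#'
#' @param n number of alleles.
#' @param length sequence length in bp.
#' @param divergence per-allele fraction of sites mutated away from the
#'   shared reference.
#' @return named character vector of allele sequences.
#' @export
synth_alleles <- function(n, length = 300, divergence = 0.02) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length, replace = TRUE)
  k <- max(1L, round(divergence * length))
  pos_all <- sample.int(length, n * k)   # disjoint mutated positions
  out <- character(n)
  for (i in seq_len(n)) {
    s <- ref
    pos <- pos_all[((i - 1L) * k + 1L):(i * k)]
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    out[i] <- paste0(s, collapse = "")
  }
  names(out) <- paste0("allele", seq_len(n))
  out
}

#' Simulate amplicon reads from an allele set
#'
#' Reads are drawn uniformly from the sample's alleles with per-base errors
#' and Phred-like quality strings; a `chimera_rate` fraction are PCR
#' recombinants (prefix of one allele, suffix of another, uniform
#' breakpoint).  A recombinant whose sequence coincides with an existing
#' allele is emitted as an ordinary read of that allele — nothing in the
#' data could distinguish it — so only recombinants distinct from every
#' input allele carry the chimera truth label.  A `lowq_read_frac` fraction
#' of reads is emitted with uniformly low qualities to exercise quality
#' control.
#'
#' @param alleles named character vector of allele sequences (equal length).
#' @param depth number of reads.
#' @param error_rate per-base error probability.
#' @param chimera_rate fraction of reads built as recombinants.
#' @param lowq_read_frac fraction of uniformly low-quality reads.
#' @param prefix read-id prefix.
#' @return a [read_set()] whose `truth` table records the source allele and
#'   chimera status of every read.
#' @export
simulate_reads <- function(alleles, depth = 300, error_rate = 0.01,
                           chimera_rate = 0.1, lowq_read_frac = 0.05,
                           prefix = "read") {
  stopifnot(length(unique(nchar(alleles))) == 1L)
  L <- nchar(alleles[1])
  bases <- c("A", "C", "G", "T")
  amat <- do.call(rbind, strsplit(unname(alleles), ""))
  ids <- character(depth); seqs <- character(depth)
  quals <- vector("list", depth)
  src <- character(depth); chim <- logical(depth)
  for (i in seq_len(depth)) {
    is_chim <- length(alleles) >= 2 && runif(1) < chimera_rate
    if (is_chim) {
      pair <- sample(length(alleles), 2)
      k <- sample.int(L - 1L, 1)
      tmpl <- c(amat[pair[1], 1:k], amat[pair[2], (k + 1L):L])
      hit <- which(apply(amat, 1, function(r) all(r == tmpl)))
      if (length(hit) > 0) {          # indistinguishable from a real allele
        is_chim <- FALSE
        src[i] <- names(alleles)[hit[1]]
      } else {
        src[i] <- NA_character_
      }
    } else {
      a <- sample(length(alleles), 1)
      tmpl <- amat[a, ]
      src[i] <- names(alleles)[a]
    }
    chim[i] <- is_chim
    # quality-first error model: per-base Phred scores are drawn and bases
    # err with the probability the score implies, so qualities are
    # calibrated estimates of the error process (as on a real instrument).
    # Error mass is carried by a low-quality base fraction tuned so the
    # mean per-base error equals error_rate.
    if (runif(1) < lowq_read_frac) {
      q <- sample(5:15, L, replace = TRUE)   # junk read: QC should drop it
    } else if (error_rate == 0) {
      q <- sample(30:40, L, replace = TRUE)
    } else {
      f <- min(error_rate / 0.162, 0.099)    # 0.162 = mean error at Q 5..12
      low <- runif(L) < f
      q <- ifelse(low, sample(5:12, L, replace = TRUE),
                  sample(30:40, L, replace = TRUE))
    }
    err <- if (error_rate == 0) rep(FALSE, L) else runif(L) < 10^(-q / 10)
    read <- tmpl
    if (any(err)) {
      read[err] <- vapply(read[err], function(b) sample(setdiff(bases, b), 1),
                          character(1))
    }
    seqs[i] <- paste0(read, collapse = "")
    quals[[i]] <- q
    ids[i] <- sprintf("%s%04d|allele=%s|chimera=%d", prefix, i,
                      ifelse(is.na(src[i]), "NA", src[i]), as.integer(chim[i]))
  }
  read_set(ids, seqs, quals,
           truth = data.frame(id = ids, allele = src, chimera = chim,
                              stringsAsFactors = FALSE))
}

#' Simulate a complete data set
#'
#' Convenience wrapper: planted history, gene-tree samples, true allele
#' sequences, and amplicon reads per sample and nuclear locus.
#'
#' @param config a [sim_config()].
#' @param n_trees genealogies per locus.
#' @return list with `history`, `gene_trees`, `alleles` (truth sequences),
#'   `reads` (nested list sample -> locus -> [read_set()]), and `plastid`
#'   (named vector of plastid haplotype sequences per sample).
#' @export
simulate_dataset <- function(config, n_trees = 500) {
  history <- simulate_history(config)
  gt <- simulate_gene_trees(history, n_trees = n_trees)
  alleles <- simulate_alleles(gt)
  loci <- paste0("L", seq_len(config$n_loci))
  reads <- list()
  for (s in history$samples$sample) {
    reads[[s]] <- list()
    for (l in loci) {
      d <- alleles[alleles$sample == s & alleles$locus == l, ]
      reads[[s]][[l]] <- simulate_reads(
        setNames(d$seq, d$allele), depth = config$read_depth,
        error_rate = config$error_rate, chimera_rate = config$chimera_rate,
        lowq_read_frac = config$lowq_read_frac,
        prefix = paste0(s, ".", l, ".r"))
    }
  }
  pt <- alleles[alleles$locus == "pt", ]
  plastid <- setNames(pt$seq, pt$sample)
  list(history = history, gene_trees = gt, alleles = alleles,
       reads = reads, plastid = plastid)
}
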