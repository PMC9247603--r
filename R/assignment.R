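#' Lineage map for allele co-ancestry analyses
#'
#' Declares, for every allele at every locus, the sample it was called from
#' and — for diploid samples — the species (progenitor lineage) it belongs
#' to.  Alleles of polyploid samples carry no lineage: assigning them to
#' `ploidy/2` diploid subgenome bins is exactly what the search estimates.
#'
#' Polyploid samples may be grouped into putative lineages (species
#' delimitation scenarios): samples of one group share their subgenome
#' labels, i.e. the search treats them as conspecific accessions.
#'
#' @param alleles data.frame with columns `allele`, `locus`, `sample`,
#'   `lineage` (`NA` for polyploid samples) and `ploidy`.
#' @param groups optional named list of character vectors partitioning the
#'   polyploid samples into putative lineages; defaults to one group per
#'   sample, named after it.
#' @return an object of class `lineage_map`.
#' @export
lineage_map <- function(alleles, groups = NULL) {
  need <- c("allele", "locus", "sample", "lineage", "ploidy")
  if (!all(need %in% names(alleles))) {
    stop("alleles must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(alleles$allele)) stop("allele ids must be unique")
  ip <- is.na(alleles$lineage)
  poly_samples <- unique(alleles$sample[ip])
  dip <- alleles[!ip, ]
  if (any(alleles$ploidy[ip] %% 2 != 0)) stop("polyploid ploidy must be even")
  if (is.null(groups)) {
    groups <- as.list(poly_samples)
    names(groups) <- poly_samples
  }
  gs <- unlist(groups, use.names = FALSE)
  if (!setequal(gs, poly_samples) || anyDuplicated(gs)) {
    stop("groups must partition the polyploid samples")
  }
  poly <- unique(alleles[ip, c("sample", "ploidy")])
  poly$group <- vapply(poly$sample, function(s) {
    names(groups)[vapply(groups, function(g) s %in% g, logical(1))][1]
  }, character(1))
  for (g in names(groups)) {
    pl <- unique(poly$ploidy[poly$group == g])
    if (length(pl) > 1) stop("group '", g, "' mixes ploidy levels")
  }
  poly$n_bins <- poly$ploidy %/% 2L
  gtab <- unique(poly[, c("group", "n_bins")])
  sg_labels <- unlist(lapply(seq_len(nrow(gtab)), function(i) {
    paste0(gtab$group[i], ".sg", seq_len(gtab$n_bins[i]))
  }))
  labels <- c(sort(unique(dip$lineage)), sg_labels)
  structure(list(df = alleles, poly = poly, groups = groups,
                 diploid = setNames(dip$lineage, dip$allele),
                 labels = labels),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat("lineage_map:", length(unique(stats::na.omit(x$df$lineage))),
      "diploid lineages,", nrow(x$poly), "polyploid sample(s) in",
      length(x$groups), "group(s),", length(unique(x$df$locus)), "loci\n")
  invisible(x)
}

# Alleles of one polyploid sample at one locus.
poly_alleles <- function(map, sample, locus) {
  d <- map$df
  d$allele[d$sample == sample & d$locus == locus & is.na(d$lineage)]
}

# Random valid assignment: per sample x locus, alleles are dealt into the
# sample's subgenome bins with at most two alleles per bin.
random_assignment <- function(map) {
  loci <- unique(map$df$locus)
  out <- list()
  for (i in seq_len(nrow(map$poly))) {
    s <- map$poly$sample[i]
    nb <- map$poly$n_bins[i]
    out[[s]] <- list()
    for (l in loci) {
      al <- sort(poly_alleles(map, s, l))
      if (length(al) == 0) next
      if (length(al) > 2L * nb) {
        stop("sample ", s, " has ", length(al), " alleles at ", l,
             " but only ", nb, " bins of capacity 2")
      }
      slots <- sample(rep(seq_len(nb), 2L))
      out[[s]][[l]] <- setNames(slots[seq_along(al)], al)
    }
  }
  out
}

check_assignment <- function(map, assignment) {
  for (i in seq_len(nrow(map$poly))) {
    s <- map$poly$sample[i]
    nb <- map$poly$n_bins[i]
    for (l in names(assignment[[s]])) {
      bins <- assignment[[s]][[l]]
      if (!setequal(names(bins), poly_alleles(map, s, l))) {
        stop("assignment for ", s, "/", l, " does not cover its alleles")
      }
      if (any(tabulate(bins, nb) > 2L)) {
        stop("bin with more than 2 alleles for ", s, " at ", l)
      }
    }
  }
  invisible(TRUE)
}

# Label of each allele (0-based index into map$labels) for one engine locus
# under the current assignment.
locus_lineages <- function(engine, map, assignment, i) {
  loc <- engine$loci[[i]]
  lab_idx <- setNames(seq_along(map$labels) - 1L, map$labels)
  lin <- lab_idx[map$diploid[loc$alleles]]
  poly_of <- setNames(map$poly$group, map$poly$sample)
  for (s in names(assignment)) {
    bins <- assignment[[s]][[loc$locus_id]]
    if (is.null(bins)) next
    hit <- match(names(bins), loc$alleles)
    keep <- !is.na(hit)
    lin[hit[keep]] <- lab_idx[paste0(poly_of[s], ".sg", bins[keep])]
  }
  if (anyNA(lin)) {
    stop("alleles without lineage at locus ", loc$locus_id, ": ",
         paste(loc$alleles[is.na(lin)], collapse = ", "))
  }
  unname(lin)
}

assignment_K <- function(engine, map, assignment) {
  lapply(seq_along(engine$loci), function(i) {
    engine_locus_K(engine, i, locus_lineages(engine, map, assignment, i))
  })
}

#' Score an allele-to-subgenome assignment
#'
#' Relabels the polyploid alleles by their subgenome bin and returns the
#' minimum over species trees of the total number of extra lineages, summed
#' over loci and weighted gene trees.  The minimizing species tree (a
#' multi-labeled tree in which every subgenome is a leaf) is attached as
#' attribute `species_tree`.
#'
#' @param samples list of [gene_tree_sample()] objects, one per locus.
#' @param map a [lineage_map()].
#' @param assignment nested list: `assignment[[sample]][[locus]]` is a named
#'   integer vector of bin indices (1..ploidy/2) over the sample's alleles.
#' @return numeric deep-coalescence score with attribute `species_tree`.
#' @export
score_assignment <- function(samples, map, assignment) {
  check_assignment(map, assignment)
  engine <- mdc_engine(samples, map$labels)
  K <- Reduce(`+`, assignment_K(engine, map, assignment))
  res <- engine_score(K, engine)
  structure(res$score, species_tree = res$tree)
}

# All single moves touching one sample at one locus: transfers of one allele
# to a bin with spare capacity, swaps of one allele between two bins, and
# wholesale relabelings of a bin pair.  The relabeling move is the
# composition of two allele swaps; it is included as an atomic move because
# a coherent labeling at one locus that is permuted relative to the other
# loci could otherwise only be repaired through a worse-scoring
# intermediate state, a local optimum a single-swap neighbourhood cannot
# leave.
neighbour_moves <- function(map, assignment) {
  moves <- list()
  for (i in seq_len(nrow(map$poly))) {
    s <- map$poly$sample[i]
    nb <- map$poly$n_bins[i]
    for (l in names(assignment[[s]])) {
      bins <- assignment[[s]][[l]]
      size <- tabulate(bins, nb)
      for (a in names(bins)) {
        for (b2 in seq_len(nb)[-bins[a]]) {
          if (size[b2] < 2L) {
            nb2 <- bins; nb2[a] <- b2
            moves[[length(moves) + 1L]] <- list(sample = s, locus = l, bins = nb2)
          }
          for (b in names(bins)[bins == b2]) {   # swap a <-> b
            if (a < b || bins[a] == bins[b]) next
            nb2 <- bins; nb2[a] <- bins[b]; nb2[b] <- bins[a]
            moves[[length(moves) + 1L]] <- list(sample = s, locus = l, bins = nb2)
          }
        }
      }
      for (b1 in seq_len(nb - 1L)) {             # relabel bin pair b1 <-> b2
        for (b2 in (b1 + 1L):nb) {
          if (size[b1] == 0L && size[b2] == 0L) next
          nb2 <- bins
          nb2[bins == b1] <- b2
          nb2[bins == b2] <- b1
          moves[[length(moves) + 1L]] <- list(sample = s, locus = l, bins = nb2)
        }
      }
    }
  }
  moves
}

#' Assign polyploid alleles to subgenomes by hill climbing
#'
#' Starts from a random valid assignment and repeatedly applies the first
#' score-improving single move (moving one allele to another bin, or swapping
#' two alleles between bins, within one sample at one locus), scanning the
#' neighbourhood in random order.  When no move improves the score the
#' search has reached a local optimum and is reinitialized from a fresh
#' random assignment; one run spends `iterations` hill-climbing steps
#' (accepted moves and reinitializations).  `restarts` independent runs are
#' performed and the best assignment overall is returned.  Deterministic for
#' a fixed `seed`.
#'
#' @param samples list of [gene_tree_sample()] objects, one per locus.
#' @param map a [lineage_map()].
#' @param iterations hill-climbing steps per run (default 1000).
#' @param restarts number of independent runs (default 10).
#' @param seed optional RNG seed.
#' @return object of class `subgenome_assignment`: list with `assignment`,
#'   `score`, `species_tree`, `table` (tidy sample/locus/allele/subgenome
#'   rows) and `log` (best score after each run).
#' @export
hill_climb_assignment <- function(samples, map, iterations = 1000L,
                                  restarts = 10L, seed = NULL) {
  if (nrow(map$poly) == 0) stop("no polyploid samples in the lineage map")
  if (!is.null(seed)) set.seed(seed)
  engine <- mdc_engine(samples, map$labels)
  poly_samples <- map$poly$sample

  # the K vector of a locus depends only on that locus' bin configuration;
  # configurations recur constantly across climbs, so cache them (bins are
  # kept in sorted-allele order, so the bare values identify the config)
  Kcache <- new.env(parent = emptyenv())
  K_of <- function(i, assignment) {
    l <- names(engine$loci)[i]
    key <- paste0(i, "|", paste(vapply(poly_samples, function(s) {
      b <- assignment[[s]][[l]]
      if (is.null(b)) "" else paste0(b, collapse = "")
    }, character(1)), collapse = "/"))
    hit <- Kcache[[key]]
    if (!is.null(hit)) return(hit)
    K <- engine_locus_K(engine, i, locus_lineages(engine, map, assignment, i))
    Kcache[[key]] <- K
    K
  }

  # neighbourhoods likewise depend only on one sample's bins at one locus
  Mcache <- new.env(parent = emptyenv())
  moves_of <- function(assignment) {
    out <- list()
    for (ii in seq_len(nrow(map$poly))) {
      s <- map$poly$sample[ii]
      for (l in names(assignment[[s]])) {
        key <- paste0(s, "|", l, "|",
                      paste0(assignment[[s]][[l]], collapse = ""))
        hit <- Mcache[[key]]
        if (is.null(hit)) {
          sub <- map$poly[ii, , drop = FALSE]
          one <- list()
          one[[s]] <- assignment[[s]][l]
          m1 <- neighbour_moves(list(poly = sub), one)
          Mcache[[key]] <- m1
          hit <- m1
        }
        out <- c(out, hit)
      }
    }
    out
  }

  best <- NULL
  log <- numeric(0)
  for (r in seq_len(restarts)) {
    cur <- random_assignment(map)
    K_loc <- lapply(seq_along(engine$loci), K_of, assignment = cur)
    K_tot <- Reduce(`+`, K_loc)
    cur_sc <- engine_score_value(K_tot)
    steps <- 0L
    while (steps < iterations) {
      moves <- moves_of(cur)
      improved <- FALSE
      for (m in moves[sample.int(length(moves))]) {
        i <- match(m$locus, names(engine$loci))
        cand <- cur
        cand[[m$sample]][[m$locus]] <- m$bins
        K_new <- K_of(i, cand)
        sc <- engine_score_value(K_tot - K_loc[[i]] + K_new)
        if (sc < cur_sc - 1e-9) {
          cur <- cand
          K_tot <- K_tot - K_loc[[i]] + K_new
          K_loc[[i]] <- K_new
          cur_sc <- sc
          improved <- TRUE
          break
        }
      }
      steps <- steps + 1L
      if (!improved) {                      # local optimum -> reinitialize
        if (is.null(best) || cur_sc < best$score - 1e-9) {
          best <- list(assignment = cur, score = cur_sc, K = K_tot)
        }
        cur <- random_assignment(map)
        K_loc <- lapply(seq_along(engine$loci), K_of, assignment = cur)
        K_tot <- Reduce(`+`, K_loc)
        cur_sc <- engine_score_value(K_tot)
      }
    }
    if (is.null(best) || cur_sc < best$score - 1e-9) {
      best <- list(assignment = cur, score = cur_sc, K = K_tot)
    }
    log <- c(log, best$score)
  }
  best$tree <- engine_score(best$K, engine)$tree
  tab <- do.call(rbind, lapply(names(best$assignment), function(s) {
    do.call(rbind, lapply(names(best$assignment[[s]]), function(l) {
      bins <- best$assignment[[s]][[l]]
      data.frame(sample = s, locus = l, allele = names(bins),
                 subgenome = unname(bins))
    }))
  }))
  structure(list(assignment = best$assignment, score = best$score,
                 species_tree = best$tree, table = tab,
                 log = data.frame(run = seq_along(log), best_score = log)),
            class = "subgenome_assignment")
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("subgenome_assignment: score =", x$score, "extra lineages\n")
  cat("species tree:", ape::write.tree(x$species_tree), "\n")
  invisible(x)
}

#' Allele-level accuracy of an assignment against a planted truth
#'
#' Bin indices are arbitrary labels, so for every sample the inferred bins
#' are matched to the true subgenomes by the permutation maximizing
#' agreement (consistently across loci), and the fraction of alleles placed
#' with their true subgenome is returned.
#'
#' @param assignment a `subgenome_assignment` (or its `table`).
#' @param truth data.frame with columns `allele`, `sample`, `subgenome`.
#' @return fraction in `[0, 1]` of polyploid alleles correctly assigned.
#' @export
assignment_accuracy <- function(assignment, truth) {
  tab <- if (inherits(assignment, "subgenome_assignment")) assignment$table
         else assignment
  tab <- merge(tab, truth[, c("allele", "subgenome")],
               by = "allele", suffixes = c("", ".true"))
  hits <- 0L
  for (s in unique(tab$sample)) {
    d <- tab[tab$sample == s, ]
    bins <- sort(unique(d$subgenome))
    perms <- perms_of(sort(unique(d$subgenome.true)))
    best <- 0L
    for (p in perms) {
      if (length(p) < length(bins)) next
      best <- max(best, sum(d$subgenome.true == p[match(d$subgenome, bins)]))
    }
    hits <- hits + best
  }
  hits / nrow(tab)
}

perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}
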