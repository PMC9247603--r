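# Statistical-parsimony (TCS-style) haplotype networks from aligned plastid
# sequences: haplotype collapsing with indel handling, the 95% parsimony
# connection limit, and distance-ordered network construction with
# hypothetical intermediate haplotypes.

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences are merged into one haplotype.  Indel handling:
#' `"single-step"` keeps gap columns (a contiguous gap run later counts as
#' one mutational step), `"ignore-gap-columns"` removes every column
#' containing a gap before collapsing.  Samples with a deletion longer than
#' `long_del` columns are flagged: their haplotype identity is considered
#' ambiguous and they are candidates for exclusion.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (one per sample).
#' @param indel_mode `"single-step"` (default) or `"ignore-gap-columns"`.
#' @param long_del flag threshold for long deletions (columns, default 20).
#' @return object of class `haplotype_table`: data.frame `table`
#'   (haplotype, sequence, count, samples) and `flagged` sample names.
#' @export
collapse_haplotypes <- function(aln,
                                indel_mode = c("single-step",
                                               "ignore-gap-columns"),
                                long_del = 20L) {
  indel_mode <- match.arg(indel_mode)
  stopifnot(length(unique(nchar(aln))) == 1L)
  flagged <- names(aln)[vapply(aln, function(s) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    any(r$values & r$lengths > long_del)
  }, logical(1))]
  seqs <- aln
  if (indel_mode == "ignore-gap-columns") {
    m <- do.call(rbind, strsplit(aln, ""))
    keep <- colSums(m == "-") == 0
    seqs <- setNames(apply(m[, keep, drop = FALSE], 1, paste0,
                           collapse = ""), names(aln))
  }
  uniq <- unique(unname(seqs))
  tab <- data.frame(
    haplotype = paste0("H", seq_along(uniq)),
    sequence = uniq,
    count = vapply(uniq, function(u) sum(seqs == u), integer(1)),
    samples = vapply(uniq, function(u)
      paste(names(seqs)[seqs == u], collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, flagged = flagged, indel_mode = indel_mode),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$table), "haplotypes from",
      sum(x$table$count), "samples\n")
  if (length(x$flagged)) {
    cat("  flagged (long deletion):", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mutational steps between two aligned haplotypes
#'
#' Substitution differences plus, under single-step indel handling, one
#' step per contiguous alignment run in which exactly one of the two
#' sequences is gapped.
#'
#' @param a,b aligned sequences of equal length.
#' @return integer number of steps.
#' @export
haplotype_steps <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  gap_x <- x == "-"; gap_y <- y == "-"
  subs <- sum(x != y & !gap_x & !gap_y)
  r <- rle(gap_x != gap_y)
  indels <- sum(r$values)
  subs + indels
}

# Probability that two haplotypes showing j differing sites over m sites
# are separated by exactly j mutations (a parsimonious connection).  The
# unknown true mutation count H is given the coalescent (geometric) prior
# with the moment estimate theta = j, and multiple hits are uniform over
# sites: P(j observed | H = h) is the classical occupancy probability of h
# draws filling exactly j of m cells.
parsimony_prob <- function(j, m, h_extra = 80L) {
  if (j == 0L) return(1)
  theta <- j
  hs <- j:(j + h_extra)
  log_prior <- hs * log(theta) - (hs + 1) * log(1 + theta)
  ls2 <- log_stirling2_column(max(hs), j)           # log S2(h, j)
  log_occ <- lchoose(m, j) + lfactorial(j) + ls2[hs] - hs * log(m)
  log_terms <- log_prior + log_occ
  mx <- max(log_terms)
  w <- exp(log_terms - mx)
  w[1] / sum(w)
}

# log S2(h, j) for fixed j and h = 1..hmax via the triangular recurrence in
# log space.
log_stirling2_column <- function(hmax, j) {
  prev <- c(0, rep(-Inf, hmax - 1))                 # j = 1: S2(h,1) = 1
  if (j == 1L) return(prev)
  for (jj in 2:j) {
    cur <- rep(-Inf, hmax)
    for (h in jj:hmax) {
      a <- log(jj) + (if (h - 1 >= 1) cur[h - 1] else -Inf)
      b <- prev[h - 1]
      cur[h] <- if (is.infinite(a)) b else if (is.infinite(b)) a else
        max(a, b) + log1p(exp(-abs(a - b)))
    }
    prev <- cur
  }
  prev
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` for which the probability of
#' a parsimonious connection (no superimposed mutations hidden in the `j`
#' observed differences) still reaches `alpha`.  Haplotype pairs further
#' apart than the limit are left in separate network components.
#'
#' @param seq_length alignment length in sites.
#' @param alpha required parsimony probability (default 0.95).
#' @return integer connection limit (>= 0).
#' @export
parsimony_limit <- function(seq_length, alpha = 0.95) {
  stopifnot(seq_length > 0)
  j <- 0L
  while (j < seq_length && parsimony_prob(j + 1L, seq_length) >= alpha) {
    j <- j + 1L
  }
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are processed in increasing step distance up to the
#' connection limit, round by round: a pair at distance `d` is connected
#' unless the network built from strictly closer pairs (and earlier rounds)
#' already joins them within `d` steps.  Multi-step connections insert
#' hypothetical intermediate haplotypes (one node per step); all
#' alternative connections of equal cost qualify in the same round, so
#' reticulations are retained.  Pairs beyond the limit stay unconnected.
#'
#' @param table a [collapse_haplotypes()] result (or its `table`).
#' @param limit connection limit in steps; default computed from the
#'   alignment length via [parsimony_limit()].
#' @param alpha parsimony probability used when `limit` is computed.
#' @return object of class `haplotype_network`: `graph` (undirected
#'   `igraph`; vertex attributes `observed`, `count`), `limit`, `table`.
#' @export
build_network <- function(table, limit = NULL, alpha = 0.95) {
  tab <- if (inherits(table, "haplotype_table")) table$table else table
  if (is.null(limit)) {
    limit <- parsimony_limit(nchar(tab$sequence[1]), alpha)
  }
  nh <- nrow(tab)
  g <- igraph::make_empty_graph(n = nh, directed = FALSE)
  igraph::V(g)$name <- tab$haplotype
  igraph::V(g)$observed <- TRUE
  igraph::V(g)$count <- tab$count
  if (nh >= 2) {
    pairs <- utils::combn(nh, 2)
    d <- apply(pairs, 2, function(p)
      haplotype_steps(tab$sequence[p[1]], tab$sequence[p[2]]))
    o <- order(d, tab$haplotype[pairs[1, ]], tab$haplotype[pairs[2, ]])
    hyp <- 0L
    for (dist_round in sort(unique(d[d <= limit]))) {
      g_before <- g
      for (ci in o[d[o] == dist_round]) {
        i <- pairs[1, ci]; j <- pairs[2, ci]
        dd <- suppressWarnings(igraph::distances(
          g_before, tab$haplotype[i], tab$haplotype[j]))[1, 1]
        if (is.finite(dd) && dd <= dist_round) next
        if (dist_round == 1L) {
          g <- igraph::add_edges(g, c(tab$haplotype[i], tab$haplotype[j]))
        } else {
          mids <- paste0("hyp", hyp + seq_len(dist_round - 1L))
          hyp <- hyp + dist_round - 1L
          g <- igraph::add_vertices(g, length(mids), name = mids,
                                    observed = FALSE, count = 0)
          chain <- c(tab$haplotype[i], mids, tab$haplotype[j])
          for (k in seq_len(length(chain) - 1L)) {
            g <- igraph::add_edges(g, c(chain[k], chain[k + 1L]))
          }
        }
      }
    }
  }
  structure(list(graph = g, limit = limit, table = tab),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  memb <- igraph::components(x$graph)$membership
  obs <- igraph::V(x$graph)$observed
  cat("haplotype_network:", sum(obs), "observed +", sum(!obs),
      "hypothetical haplotypes,",
      length(unique(memb[obs])), "component(s), limit", x$limit, "steps\n")
  invisible(x)
}

#' Haplotype group membership table
#'
#' @param net a [build_network()] result.
#' @return data.frame mapping each observed haplotype (and its samples) to
#'   a network component.
#' @export
haplotype_groups <- function(net) {
  memb <- igraph::components(net$graph)$membership
  obs <- igraph::V(net$graph)$observed
  nm <- igraph::V(net$graph)$name[obs]
  data.frame(haplotype = nm,
             component = unname(memb[obs]),
             samples = net$table$samples[match(nm, net$table$haplotype)],
             stringsAsFactors = FALSE)
}
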