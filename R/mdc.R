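#' Gene-tree samples per locus
#'
#' Container for a per-locus sample of rooted gene trees (typically drawn
#' from a Bayesian posterior, or simulated).  Each tree receives equal weight
#' `1/n` so that deep-coalescence scores are comparable across loci with
#' different sample sizes.
#'
#' @param locus_id single character locus name.
#' @param trees a `multiPhylo` (or list of `phylo`) of rooted trees whose tip
#'   labels are allele identifiers.
#' @return an object of class `gene_tree_sample`.
#' @export
gene_tree_sample <- function(locus_id, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    if (!inherits(tr, "phylo")) stop("trees must be phylo objects")
    tr
  })
  class(trees) <- "multiPhylo"
  structure(list(locus_id = locus_id, trees = trees,
                 weight = 1 / length(trees)),
            class = "gene_tree_sample")
}

#' @export
print.gene_tree_sample <- function(x, ...) {
  cat("gene_tree_sample:", x$locus_id, "-", length(x$trees),
      "rooted trees, weight", signif(x$weight, 4), "\n")
  invisible(x)
}

#' Subsample gene trees from a posterior sample
#'
#' Removes a burn-in prefix, draws a uniform subsample without replacement,
#' and optionally roots every tree on a declared outgroup which is then
#' pruned (the outgroup carries no information for downstream
#' deep-coalescence counting and would otherwise inflate lineage counts).
#'
#' @param posterior list or `multiPhylo` of trees in sampling order.
#' @param n number of trees to keep.
#' @param burnin number of leading trees to discard.
#' @param outgroup optional tip label used to root each tree before pruning.
#' @param locus_id locus name attached to the result.
#' @return a [gene_tree_sample()].
#' @export
subsample_gene_trees <- function(posterior, n, burnin = 0, outgroup = NULL,
                                 locus_id = "locus") {
  m <- length(posterior)
  if (m - burnin < n) {
    stop("posterior holds ", m, " trees; cannot draw ", n,
         " after a burn-in of ", burnin)
  }
  keep <- posterior[(burnin + 1L):m]
  keep <- keep[sort(sample.int(length(keep), n))]
  if (!is.null(outgroup)) {
    keep <- lapply(keep, function(tr) {
      tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
      ape::drop.tip(tr, outgroup)
    })
  }
  gene_tree_sample(locus_id, keep)
}

#' Count deep coalescences of a gene tree against a species tree
#'
#' The classical cluster formulation: for every cluster (branch) of the
#' species tree, the minimum number of gene lineages exiting that cluster is
#' the number of maximal gene-tree clades whose leaves all map inside the
#' cluster; extra lineages are that number minus one, summed over clusters.
#' The count is zero exactly when the gene tree can be embedded in the
#' species tree without any lineage failing to coalesce in its branch.
#'
#' @param gene_tree rooted `phylo`; tips are allele ids.
#' @param species_tree rooted `phylo`; tips are lineage labels.
#' @param map named character vector, allele id -> lineage label.
#' @return non-negative integer count of extra lineages.
#' @export
count_extra_lineages <- function(gene_tree, species_tree, map) {
  if (!all(gene_tree$tip.label %in% names(map))) {
    stop("unmapped gene-tree leaves: ",
         paste(setdiff(gene_tree$tip.label, names(map)), collapse = ", "))
  }
  labels <- species_tree$tip.label
  if (!all(map[gene_tree$tip.label] %in% labels)) {
    stop("map points to lineages absent from the species tree")
  }
  L <- length(labels)
  if (L > 30L) stop("more than 30 lineages not supported")
  bit <- setNames(bitwShiftL(1L, seq_len(L) - 1L), labels)

  alleles <- gene_tree$tip.label
  aidx <- setNames(seq_along(alleles) - 1L, alleles)
  arr <- tree_arrays(gene_tree, aidx)
  lin <- as.integer(log2(bit[map[alleles]]))

  smask <- cluster_masks(species_tree, labels)
  total <- 0L
  for (A in smask) {
    k <- .tree_cluster_k(arr$po, arr$parent, arr$leaf, lin, L, A)
    if (k > 1L) total <- total + (k - 1L)
  }
  total
}

# --- deep-coalescence engine -------------------------------------------------
#
# Preprocesses gene-tree samples once so that scoring an allele-to-lineage
# labeling costs one small matrix pass per locus.  For every locus the
# sampled topologies are deduplicated (weights summed); each unique tree is
# flattened to postorder arrays.  Scoring computes, per locus, the weighted
# extra-lineage vector K over all 2^L lineage subsets, then finds the exact
# minimum-deep-coalescence species tree by dynamic programming over subsets.

mdc_engine <- function(samples, labels) {
  if (inherits(samples, "gene_tree_sample")) samples <- list(samples)
  L <- length(labels)
  if (L > 14L) stop("subset engine supports at most 14 lineage labels")
  loci <- lapply(samples, function(s) {
    trees <- s$trees
    keys <- vapply(trees, canonical_topology, character(1))
    uk <- unique(keys)
    w <- as.numeric(table(keys)[uk]) * s$weight
    utrees <- trees[match(uk, keys)]
    alleles <- sort(unique(unlist(lapply(utrees, function(tr) tr$tip.label))))
    aidx <- setNames(seq_along(alleles) - 1L, alleles)
    arr <- lapply(utrees, tree_arrays, allele_index = aidx)
    list(locus_id = s$locus_id, alleles = alleles,
         po = lapply(arr, `[[`, "po"),
         parent = lapply(arr, `[[`, "parent"),
         leaf = lapply(arr, `[[`, "leaf"),
         w = w)
  })
  names(loci) <- vapply(samples, `[[`, character(1), "locus_id")
  list(loci = loci, labels = labels, L = L)
}

# lineage assignment: list per locus of integer vectors (0-based label index)
# aligned with engine$loci[[i]]$alleles.
engine_locus_K <- function(engine, i, lineage) {
  loc <- engine$loci[[i]]
  .locus_K(loc$po, loc$parent, loc$leaf, loc$w, as.integer(lineage), engine$L)
}

engine_score <- function(K_total, engine) {
  dp <- .dp_min_tree(K_total)
  list(score = dp$score,
       tree = tree_from_choice(dp$choice, engine$labels))
}

# score only (the optimal tree is rebuilt lazily after the search)
engine_score_value <- function(K_total) {
  .dp_min_tree(K_total)$score
}

#' Minimize-deep-coalescence species tree
#'
#' Finds the rooted species tree minimizing the total number of extra
#' lineages summed over all gene trees and loci.  Up to 12 lineages the
#' optimum is exact (dynamic programming over lineage subsets visits every
#' cluster of every rooted binary tree once); beyond that a rooted-NNI hill
#' climb from a greedy start is used.
#'
#' @param samples a [gene_tree_sample()] or list of them (one per locus).
#' @param map named character vector, allele id -> lineage label.
#' @param labels optional character vector fixing the lineage set and its
#'   order; defaults to the sorted unique labels of `map`.
#' @return list with `tree` (rooted `phylo`) and `score` (weighted extra
#'   lineages; an integer when each locus holds a single tree).
#' @export
mdc_species_tree <- function(samples, map, labels = sort(unique(map))) {
  engine <- mdc_engine(samples, labels)
  bit <- setNames(seq_along(labels) - 1L, labels)
  K <- 0
  for (i in seq_along(engine$loci)) {
    lin <- bit[map[engine$loci[[i]]$alleles]]
    if (anyNA(lin)) stop("unmapped alleles at locus ", engine$loci[[i]]$locus_id)
    K <- K + engine_locus_K(engine, i, lin)
  }
  if (length(labels) <= 12L) {
    engine_score(K, engine)
  } else {
    nni_search(K, labels)
  }
}

# Rooted NNI hill climb used above the exact-DP size limit.
nni_search <- function(K, labels, max_sweeps = 50L) {
  cur <- ape::as.phylo(stats::as.hclust(stats::hclust(
    stats::dist(seq_along(labels)), "average")))  # arbitrary resolved start
  cur$tip.label <- labels
  cur_s <- score_topology(cur, K, labels)
  for (s in seq_len(max_sweeps)) {
    improved <- FALSE
    for (nb in rooted_nni(cur)) {
      sc <- score_topology(nb, K, labels)
      if (sc < cur_s) {
        cur <- nb; cur_s <- sc; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(score = cur_s, tree = cur)
}

# All rooted NNI neighbours: for each internal non-root node v with parent u,
# exchange one child of v with v's sibling.
rooted_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- children_list(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  out <- list()
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    if (v == root) next
    u <- parent[v]
    sib <- setdiff(kids[[u]], v)
    if (length(sib) != 1L) next
    for (ci in seq_along(kids[[v]])) {
      e <- tree$edge
      e[e[, 1L] == u & e[, 2L] == sib, 2L] <- kids[[v]][ci]
      e[e[, 1L] == v & e[, 2L] == kids[[v]][ci], 2L] <- sib
      nb <- tree
      nb$edge <- e
      nb$edge.length <- NULL
      out[[length(out) + 1L]] <- ape::read.tree(text = ape::write.tree(nb))
    }
  }
  out
}
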