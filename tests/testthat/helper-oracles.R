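# Independent oracles used across the suite.  These deliberately avoid the
# package's bitmask/kernel code paths: tip sets are plain character vectors
# and species-tree topologies come from phangorn's enumerator.

# Tip labels below every node of a tree, as a list indexed by node id.
oracle_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- rep(list(character(0)), ntip + tree$Nnode)
  for (v in seq_len(ntip)) sets[[v]] <- tree$tip.label[v]
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; c_ <- tree$edge[i, 2]
      if (length(sets[[c_]]) > 0 && !all(sets[[c_]] %in% sets[[p]])) {
        sets[[p]] <- union(sets[[p]], sets[[c_]])
        done <- FALSE
      }
    }
    if (done) break
  }
  sets
}

# Brute-force deep-coalescence count: for every species-tree cluster, count
# maximal gene-tree clades mapping inside it by direct set comparison.
oracle_extra_lineages <- function(gene_tree, species_tree, map) {
  gsets <- oracle_tipsets(gene_tree)
  ssets <- oracle_tipsets(species_tree)
  ntipg <- length(gene_tree$tip.label)
  parent <- rep(NA_integer_, ntipg + gene_tree$Nnode)
  parent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]
  total <- 0L
  for (cl in ssets) {
    k <- 0L
    for (v in seq_along(gsets)) {
      inside <- all(map[gsets[[v]]] %in% cl)
      if (!inside) next
      p <- parent[v]
      if (is.na(p) || !all(map[gsets[[p]]] %in% cl)) k <- k + 1L
    }
    if (k > 1L) total <- total + (k - 1L)
  }
  total
}

# Exhaustive minimum-deep-coalescence species tree over all rooted
# topologies enumerated by phangorn.
oracle_mdc <- function(samples, map, labels) {
  if (inherits(samples, "gene_tree_sample")) samples <- list(samples)
  topos <- phangorn::allTrees(length(labels), rooted = TRUE,
                              tip.label = labels)
  scores <- vapply(topos, function(st) {
    tot <- 0
    for (s in samples) {
      for (tr in s$trees) {
        tot <- tot + s$weight * oracle_extra_lineages(tr, st, map)
      }
    }
    tot
  }, numeric(1))
  list(score = min(scores), tree = topos[[which.min(scores)]])
}

# All assignments of one polyploid sample's alleles to bins (capacity 2),
# enumerated per locus and combined; used as a brute-force search oracle.
oracle_assignments <- function(map, sample) {
  nb <- map$poly$n_bins[map$poly$sample == sample]
  loci <- unique(map$df$locus)
  per_locus <- lapply(loci, function(l) {
    al <- sort(map$df$allele[map$df$sample == sample & map$df$locus == l &
                               is.na(map$df$lineage)])
    if (length(al) == 0) return(list(NULL))
    grid <- expand.grid(rep(list(seq_len(nb)), length(al)))
    keep <- apply(grid, 1, function(b) all(tabulate(b, nb) <= 2L))
    lapply(which(keep), function(r)
      stats::setNames(as.integer(grid[r, ]), al))
  })
  names(per_locus) <- loci
  combos <- expand.grid(lapply(per_locus, seq_along))
  lapply(seq_len(nrow(combos)), function(r) {
    bins <- lapply(loci, function(l) per_locus[[l]][[combos[r, l]]])
    names(bins) <- loci
    out <- list()
    out[[sample]] <- bins[!vapply(bins, is.null, logical(1))]
    out
  })
}

# Small fixed gene-tree sample sets for deterministic tests.
tiny_sample <- function(newicks, locus = "L1") {
  gene_tree_sample(locus, lapply(newicks, function(s)
    ape::read.tree(text = s)))
}
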