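# Internal tree helpers shared by the deep-coalescence engine and the
# simulator.  Gene trees are ape "phylo" objects; the compiled kernel takes
# flat postorder arrays (see src/mdc.cpp).

# Flatten a rooted phylo into 0-based postorder arrays for the kernel.
# allele_index: named integer vector (0-based) mapping tip labels to allele
# slots of the locus allele table.
tree_arrays <- function(tree, allele_index) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  re <- stats::reorder(tree, "postorder")
  po <- c(re$edge[, 2L], ntip + 1L)
  parent <- rep(-1L, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  leaf <- rep(-1L, nn)
  idx <- allele_index[tree$tip.label]
  if (anyNA(idx)) {
    stop("gene-tree leaves not in the allele table: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  leaf[seq_len(ntip)] <- idx
  list(po = po - 1L, parent = parent - 1L, leaf = as.integer(leaf))
}

# Canonical topology string (ignores branch lengths and node rotation); used
# to collapse duplicate sampled topologies into weighted unique trees.
canonical_topology <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- children_list(tree)
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    parts <- sort(vapply(kids[[v]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(ntip + 1L)
}

children_list <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# Node heights of an ultrametric tree (0 at tips, root tallest).
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

# Rebuild the optimal species tree from the subset-DP backtracking vector.
tree_from_choice <- function(choice, labels) {
  L <- length(labels)
  rec <- function(A) {
    if (bitwAnd(A, A - 1L) == 0L) {               # singleton
      return(labels[which(bitwAnd(A, bitwShiftL(1L, seq_len(L) - 1L)) != 0L)])
    }
    sub <- choice[A + 1L]
    paste0("(", rec(sub), ",", rec(bitwXor(A, sub)), ")")
  }
  ape::read.tree(text = paste0(rec(bitwShiftL(1L, L) - 1L), ";"))
}

# All cluster bitmasks of a rooted tree whose tips are lineage labels.
cluster_masks <- function(tree, labels) {
  bit <- stats::setNames(bitwShiftL(1L, seq_along(labels) - 1L), labels)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  mask <- integer(nn)
  mask[seq_len(ntip)] <- bit[tree$tip.label]
  re <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(re$edge))) {
    mask[re$edge[i, 1L]] <- bitwOr(mask[re$edge[i, 1L]], mask[re$edge[i, 2L]])
  }
  mask
}

# Score a fixed species-tree topology against an extra-lineage vector K
# (indexed by lineage subset + 1).
score_topology <- function(tree, K, labels) {
  sum(K[cluster_masks(tree, labels) + 1L])
}
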