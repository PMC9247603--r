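# Probability of a rooted gene-tree topology under the multispecies
# coalescent, by enumeration of coalescent histories: every assignment of the
# gene tree's coalescent events to species-tree branches (respecting ancestry)
# contributes prod_b (w_b / d_b) g_{u_b, v_b}(T_b), where u_b / v_b are the
# numbers of lineages entering / leaving branch b, d_b counts all coalescent
# sequences from u_b to v_b lineages, w_b counts the orderings of the assigned
# events compatible with the gene tree, and g is Tavare's pure-death
# probability.  Exact for small trees; used only to break ties between
# equally scored allele assignments.

# Tavare (1984): probability that i lineages are reduced to j after t
# coalescent units.
tavare_gij <- function(i, j, t) {
  if (!is.finite(t)) return(as.numeric(j == 1L))
  if (j > i) return(0)
  s <- 0
  for (k in j:i) {
    term <- exp(-k * (k - 1) * t / 2) * (2 * k - 1) * (-1)^(k - j) /
      (factorial(j) * factorial(k - j) * (j + k - 1))
    y <- seq_len(k) - 1
    term <- term * prod((j + y) * (i - y) / (i + y))
    s <- s + term
  }
  max(s, 0)
}

# Number of sequences of coalescences taking u lineages down to v.
coal_seq_count <- function(u, v) {
  factorial(u) * factorial(u - 1) /
    (factorial(v) * factorial(v - 1) * 2^(u - v))
}

# Linear extensions of the event forest induced inside one branch: events
# must respect gene-tree ancestry (descendants first).  Hook-length formula
# for forests: n! / prod(subtree sizes).
linear_extensions <- function(events, anc_gt) {
  n <- length(events)
  if (n <= 1L) return(1)
  sz <- vapply(events, function(e) {
    sum(vapply(events, function(f) e == f || e %in% anc_gt[[f]], logical(1)))
  }, numeric(1))   # descendants-within-branch count, inclusive of self
  factorial(n) / prod(sz)
}

#' Probability of a gene-tree topology under the multispecies coalescent
#'
#' @param gene_tree rooted `phylo`, tips are alleles.
#' @param species_tree rooted `phylo`, tips are lineage labels; branch
#'   lengths in coalescent units (the root branch is infinite).
#' @param map named character vector allele -> lineage label.
#' @return probability of the (unranked, leaf-labeled) gene-tree topology.
#' @export
gene_tree_probability <- function(gene_tree, species_tree, map) {
  st <- species_tree
  gt <- gene_tree
  ntipS <- length(st$tip.label)
  nS <- ntipS + st$Nnode
  parS <- rep(NA_integer_, nS)
  parS[st$edge[, 2L]] <- st$edge[, 1L]
  lenS <- rep(Inf, nS)
  lenS[st$edge[, 2L]] <- st$edge.length
  rootS <- ntipS + 1L
  maskS <- cluster_masks(st, st$tip.label)
  ancS <- lapply(seq_len(nS), function(m) {
    path <- m
    while (!is.na(parS[m])) { m <- parS[m]; path <- c(path, m) }
    path
  })

  ntipG <- length(gt$tip.label)
  nG <- ntipG + gt$Nnode
  parG <- rep(NA_integer_, nG)
  parG[gt$edge[, 2L]] <- gt$edge[, 1L]
  bit <- setNames(bitwShiftL(1L, seq_len(ntipS) - 1L), st$tip.label)
  maskG <- integer(nG)
  maskG[seq_len(ntipG)] <- bit[map[gt$tip.label]]
  reG <- stats::reorder(gt, "postorder")
  for (i in seq_len(nrow(reG$edge))) {
    maskG[reG$edge[i, 1L]] <- bitwOr(maskG[reG$edge[i, 1L]],
                                     maskG[reG$edge[i, 2L]])
  }
  events <- unique(reG$edge[reG$edge[, 1L] > ntipG, 1L])  # postorder internals
  events <- events[order(match(events, c(reG$edge[, 2L], ntipG + 1L)))]
  ancG <- lapply(seq_len(nG), function(u) {
    path <- integer(0)
    while (!is.na(parG[u])) { u <- parG[u]; path <- c(path, u) }
    path
  })
  # lowest species-tree node whose cluster contains the event's species set
  mrcaS <- vapply(events, function(u) {
    ok <- which(vapply(seq_len(nS), function(m) {
      bitwAnd(maskG[u], bitwNot(maskS[m])) == 0L
    }, logical(1)))
    ok[which.min(vapply(ok, function(m) sum(bitwAnd(maskS[m],
      bitwShiftL(1L, seq_len(ntipS) - 1L)) != 0L), numeric(1)))]
  }, integer(1))

  # lineages entering each species branch at its bottom, before any events
  tipcount <- integer(nS)
  for (sp in seq_len(ntipS)) {
    tipcount[sp] <- sum(map[gt$tip.label] == st$tip.label[sp])
  }

  assign_branch <- integer(nG)   # species node per gene event
  total <- 0
  recurse <- function(ei) {
    if (ei > length(events)) {
      total <<- total + history_probability(
        events, assign_branch, ancG, parS, lenS, rootS, ntipS, nS, tipcount)
      return(invisible())
    }
    u <- events[ei]
    # children events of u constrain the branch from below
    low <- mrcaS[ei]
    kids <- which(events %in% setdiff(which(parG == u), seq_len(ntipG)))
    for (b in ancS[[low]]) {
      ok <- all(vapply(kids, function(k) b %in% ancS[[assign_branch[events[k]]]],
                       logical(1)))
      if (!ok) next
      assign_branch[u] <<- b
      recurse(ei + 1L)
    }
    invisible()
  }
  recurse(1L)
  total
}

history_probability <- function(events, assign_branch, ancG, parS, lenS,
                                rootS, ntipS, nS, tipcount) {
  e_b <- lapply(seq_len(nS), function(b) events[assign_branch[events] == b])
  # lineages entering each branch, processed tips-to-root
  ord <- order(vapply(seq_len(nS), function(m) length_path(m, parS), numeric(1)),
               decreasing = TRUE)
  u_b <- integer(nS); v_b <- integer(nS)
  for (m in ord) {
    kidsS <- which(!is.na(parS) & parS == m)
    u_b[m] <- if (m <= ntipS) tipcount[m] else sum(v_b[kidsS])
    v_b[m] <- u_b[m] - length(e_b[[m]])
    if (u_b[m] > 0 && v_b[m] < 1L) return(0)
  }
  p <- 1
  for (m in seq_len(nS)) {
    if (u_b[m] == 0L) next
    g <- tavare_gij(u_b[m], v_b[m], lenS[m])
    if (g == 0) return(0)
    if (length(e_b[[m]]) > 0) {
      w <- linear_extensions(e_b[[m]], ancG)
      d <- coal_seq_count(u_b[m], v_b[m])
      p <- p * (w / d)
    }
    p <- p * g
  }
  p
}

length_path <- function(m, parS) {
  d <- 0
  while (!is.na(parS[m])) { m <- parS[m]; d <- d + 1 }
  d
}

#' Estimate coalescent branch lengths from gene-tree concordance
#'
#' For every internal non-root branch of the species tree the frequency of
#' concordant triplets (one allele from each child clade, one from outside)
#' across the sampled gene trees estimates the branch length via the
#' three-taxon identity `P(concordant) = 1 - (2/3) exp(-T)`.  Terminal
#' branches are estimated from the monophyly frequency of each lineage's
#' alleles.  A documented approximation: lengths are clamped to
#' `[0.02, 8]` coalescent units.
#'
#' @param species_tree rooted `phylo` on lineage labels.
#' @param samples list of [gene_tree_sample()] objects.
#' @param maps list (per locus) of named allele -> lineage vectors.
#' @return `species_tree` with `edge.length` in coalescent units.
#' @export
estimate_coal_lengths <- function(species_tree, samples, maps) {
  st <- species_tree
  ntip <- length(st$tip.label)
  kids <- children_list(st)
  st$edge.length <- rep(1, nrow(st$edge))
  masks <- cluster_masks(st, st$tip.label)
  bit <- setNames(bitwShiftL(1L, seq_len(ntip) - 1L), st$tip.label)

  species_of <- function(mask) st$tip.label[bitwAnd(mask, bit) != 0L]
  conc <- function(pickA, pickB, pickC) {
    num <- 0; den <- 0
    for (li in seq_along(samples)) {
      mp <- maps[[li]]
      for (tr in samples[[li]]$trees) {
        labs <- tr$tip.label
        a <- labs[mp[labs] %in% pickA]; b <- labs[mp[labs] %in% pickB]
        c_ <- labs[mp[labs] %in% pickC]
        if (!length(a) || !length(b) || !length(c_)) next
        x <- a[1]; y <- b[1]; z <- c_[1]
        mm <- ape::getMRCA(tr, c(x, y))
        den <- den + 1
        if (!z %in% ape::extract.clade(tr, mm)$tip.label) num <- num + 1
      }
    }
    if (den == 0) return(NA_real_)
    num / den
  }

  for (i in seq_len(nrow(st$edge))) {
    v <- st$edge[i, 2L]
    if (v <= ntip) {                       # terminal: monophyly frequency
      sp <- st$tip.label[v]
      num <- 0; den <- 0
      for (li in seq_along(samples)) {
        mp <- maps[[li]]
        for (tr in samples[[li]]$trees) {
          al <- tr$tip.label[mp[tr$tip.label] == sp]
          if (length(al) < 2) next
          den <- den + 1
          if (ape::is.monophyletic(tr, al)) num <- num + 1
        }
      }
      p <- if (den > 0) num / den else NA_real_
      st$edge.length[i] <- clamp_cu(if (is.na(p)) 1 else -log(max(1 - p, 1e-4)))
    } else {                               # internal: triplet concordance
      ch <- kids[[v]]
      inside <- species_of(masks[v])
      outside <- setdiff(st$tip.label, inside)
      if (length(ch) < 2 || !length(outside)) next
      p <- conc(species_of(masks[ch[1]]), species_of(masks[ch[2]]), outside)
      t_hat <- if (is.na(p) || p <= 1 / 3) 0.02 else -log(1.5 * (1 - p))
      st$edge.length[i] <- clamp_cu(t_hat)
    }
  }
  st
}

clamp_cu <- function(x) min(max(x, 0.02), 8)

#' Break a tie between two equally scored allele assignments
#'
#' Mirrors the published protocol for replicate searches that agree on the
#' number of extra lineages but differ in the allele partition: the
#' multispecies-coalescent probability of the sampled gene-tree topologies is
#' computed under each assignment's species tree (branch lengths estimated
#' from concordance frequencies) and the assignment with the higher summed
#' log-probability wins.  Outside the enumeration regime (more than 8
#' lineages or gene trees larger than 12 leaves) the lexicographically
#' smaller assignment is returned with a warning.
#'
#' @param samples list of [gene_tree_sample()] objects.
#' @param map a [lineage_map()].
#' @param assignA,assignB two assignments (nested bin lists, as in
#'   [score_assignment()]) with equal deep-coalescence scores.
#' @return the chosen assignment, with attribute `logprob` (named numeric of
#'   both summed log-probabilities) when enumeration was used.
#' @export
gene_tree_prob_tiebreak <- function(samples, map, assignA, assignB) {
  sa <- score_assignment(samples, map, assignA)
  sb <- score_assignment(samples, map, assignB)
  if (abs(as.numeric(sa) - as.numeric(sb)) > 1e-9) {
    stop("assignments are not tied: scores ", as.numeric(sa), " vs ",
         as.numeric(sb))
  }
  maxleaf <- max(vapply(samples, function(s)
    max(vapply(s$trees, function(tr) length(tr$tip.label), integer(1))),
    integer(1)))
  if (length(map$labels) > 8L || maxleaf > 12L) {
    warning("outside the enumeration regime; falling back to lexicographic order")
    ka <- assignment_key(assignA); kb <- assignment_key(assignB)
    return(if (ka <= kb) assignA else assignB)
  }
  lp <- vapply(list(assignA, assignB), function(asg) {
    st <- attr(score_assignment(samples, map, asg), "species_tree")
    maps <- lapply(seq_along(samples), function(i) {
      full_allele_map(samples[[i]], map, asg)
    })
    st_cu <- estimate_coal_lengths(st, samples, maps)
    tot <- 0
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      keys <- vapply(s$trees, canonical_topology, character(1))
      uk <- unique(keys)
      w <- as.numeric(table(keys)[uk]) * s$weight
      ut <- s$trees[match(uk, keys)]
      for (j in seq_along(ut)) {
        pr <- gene_tree_probability(ut[[j]], st_cu, maps[[i]])
        tot <- tot + w[j] * log(max(pr, 1e-300))
      }
    }
    tot
  }, numeric(1))
  chosen <- if (lp[1] >= lp[2]) assignA else assignB
  structure(chosen, logprob = setNames(lp, c("A", "B")))
}

full_allele_map <- function(sample_obj, map, assignment) {
  alleles <- sort(unique(unlist(lapply(sample_obj$trees, function(tr)
    tr$tip.label))))
  out <- map$diploid[alleles]
  names(out) <- alleles
  poly_of <- setNames(map$poly$group, map$poly$sample)
  for (s in names(assignment)) {
    bins <- assignment[[s]][[sample_obj$locus_id]]
    if (is.null(bins)) next
    hit <- intersect(names(bins), alleles)
    out[hit] <- paste0(poly_of[s], ".sg", bins[hit])
  }
  out
}

assignment_key <- function(asg) {
  paste(vapply(sort(names(asg)), function(s) {
    paste(vapply(sort(names(asg[[s]])), function(l) {
      b <- asg[[s]][[l]]
      paste(names(b)[order(names(b))], b[order(names(b))], collapse = ";")
    }, character(1)), collapse = "|")
  }, character(1)), collapse = "||")
}
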