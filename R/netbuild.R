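# Folding multi-labeled species trees into reticulate species networks,
# support-based collapsing, merged age intervals for polyploids, and
# MDC-based ranking of species-delimitation scenarios.

clade_key <- function(tips) paste(sort(tips), collapse = "|")

# per-node clade keys (tips + internals), indexed by node id
clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- children_list(tree)
  keys <- character(ntip + tree$Nnode)
  rec <- function(v) {
    if (v <= ntip) {
      keys[v] <<- tree$tip.label[v]
      return(tree$tip.label[v])
    }
    tips <- unlist(lapply(kids[[v]], rec))
    keys[v] <<- clade_key(tips)
    tips
  }
  rec(ntip + 1L)
  keys
}

#' Collapse poorly supported branches of a multi-labeled tree
#'
#' Internal branches whose posterior support is strictly lower than the
#' threshold are contracted into polytomies; node heights of surviving
#' nodes (and their age intervals, if attached as attribute `hpd`) are
#' unchanged.  A branch with support exactly at the threshold is retained.
#'
#' @param tree ultrametric `phylo` with `node.label` support values.
#' @param threshold support below which a branch is collapsed (default 0.7).
#' @return the collapsed `phylo` (possibly multifurcating).
#' @export
collapse_low_support <- function(tree, threshold = 0.7) {
  if (is.null(tree$node.label)) stop("tree has no support values")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  support <- suppressWarnings(as.numeric(tree$node.label))
  h <- node_heights(tree)
  kids <- children_list(tree)
  drop <- function(v) {
    v > ntip && v != root && !is.na(support[v - ntip]) &&
      support[v - ntip] < threshold
  }
  eff_kids <- function(v) {
    out <- integer(0)
    for (c_ in kids[[v]]) {
      if (drop(c_)) out <- c(out, eff_kids(c_)) else out <- c(out, c_)
    }
    out
  }
  emit <- function(v, parent_h) {
    if (v <= ntip) {
      return(paste0(tree$tip.label[v], ":", format(parent_h - h[v],
                                                   digits = 10)))
    }
    parts <- vapply(eff_kids(v), emit, character(1), parent_h = h[v])
    lab <- if (v == root) "" else tree$node.label[v - ntip]
    paste0("(", paste(parts, collapse = ","), ")", lab,
           if (v == root) "" else paste0(":", format(parent_h - h[v],
                                                     digits = 10)))
  }
  out <- ape::read.tree(text = paste0(emit(root, h[root]), ";"))
  hpd <- attr(tree, "hpd")
  if (!is.null(hpd)) {
    keys <- clade_keys(out)
    attr(out, "hpd") <- hpd[hpd$clade %in% keys, , drop = FALSE]
  }
  out
}

#' Fold a MUL-tree into a species network
#'
#' The subgenome leaves of each polyploid are merged into a single leaf
#' that keeps one incoming edge per former leaf position — a reticulation
#' node of in-degree 2 (tetraploids) or 3 (hexaploids).  When all of a
#' polyploid's subgenome leaves are sisters (autopolyploidy) their edges
#' fall on the same parent node and collapse to a single annotated edge.
#' Diploid leaves are untouched.
#'
#' @param tree `phylo` MUL-tree; subgenome leaves named per `polyploids`.
#' @param polyploids named list: sample -> character vector of its
#'   subgenome leaf labels.
#' @param maternal optional named character vector: sample -> subgenome
#'   leaf carrying the plastid; flags the maternal edge.
#' @return object of class `species_network`: `graph` (directed `igraph`,
#'   edges parent to child with `length` and `maternal` attributes),
#'   `reticulations` (per-sample summary), `leaves`.
#' @export
join_subgenome_leaves <- function(tree, polyploids, maternal = NULL) {
  ntip <- length(tree$tip.label)
  leaf_owner <- setNames(rep(NA_character_, ntip), tree$tip.label)
  for (s in names(polyploids)) {
    miss <- setdiff(polyploids[[s]], tree$tip.label)
    if (length(miss) > 0) {
      stop("missing subgenome leaves for ", s, ": ",
           paste(miss, collapse = ", "))
    }
    leaf_owner[polyploids[[s]]] <- s
  }
  h <- node_heights(tree)
  vname <- function(v) {
    if (v <= ntip) {
      lab <- tree$tip.label[v]
      if (!is.na(leaf_owner[lab])) leaf_owner[lab] else lab
    } else paste0("n", v)
  }
  edges <- NULL
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c_ <- tree$edge[i, 2L]
    lab <- if (c_ <= ntip) tree$tip.label[c_] else NA_character_
    mat <- !is.na(lab) && !is.null(maternal) && lab %in% maternal
    edges <- rbind(edges, data.frame(
      from = vname(p), to = vname(c_),
      length = if (is.null(tree$edge.length)) NA_real_ else
        tree$edge.length[i],
      via_leaf = if (is.na(lab)) NA_character_ else lab,
      maternal = mat, n_merged = 1L, stringsAsFactors = FALSE))
  }
  # sister subgenome edges of one polyploid collapse into one (autopolyploid)
  key <- paste(edges$from, edges$to)
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      ix <- which(key == k)
      edges$n_merged[ix[1]] <- length(ix)
      edges$maternal[ix[1]] <- any(edges$maternal[ix])
      edges <- edges[-ix[-1], ]
      key <- paste(edges$from, edges$to)
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  hgt <- setNames(h, vapply(seq_len(ntip + tree$Nnode), vname, character(1)))
  igraph::V(g)$height <- unname(hgt[igraph::V(g)$name])
  indeg <- igraph::degree(g, mode = "in")
  ret <- data.frame(sample = names(polyploids),
                    in_degree = indeg[names(polyploids)],
                    type = ifelse(indeg[names(polyploids)] > 1,
                                  "reticulate", "autopolyploid"),
                    row.names = NULL, stringsAsFactors = FALSE)
  leaves <- names(which(igraph::degree(g, mode = "out") == 0))
  structure(list(graph = g, reticulations = ret, leaves = leaves),
            class = "species_network")
}

#' @export
print.species_network <- function(x, ...) {
  cat("species_network:", length(x$leaves), "leaves,",
      sum(x$reticulations$in_degree > 1), "reticulation(s)\n")
  if (nrow(x$reticulations)) print(x$reticulations)
  invisible(x)
}

#' Merge highest-posterior-density age intervals
#'
#' The age interval of a polyploid is the covering interval of the 95% HPD
#' intervals of the divergence times of the subgenomes involved in its
#' formation: (min of lower bounds, max of upper bounds).
#'
#' @param intervals list of numeric `c(lower, upper)` pairs, or a 2-column
#'   matrix (Ma).
#' @return numeric `c(lower, upper)`.
#' @export
merge_hpd <- function(intervals) {
  if (is.matrix(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  }
  if (length(intervals) == 0) stop("no intervals to merge")
  lo <- vapply(intervals, `[`, numeric(1), 1)
  hi <- vapply(intervals, `[`, numeric(1), 2)
  if (any(lo > hi)) stop("interval with lower > upper")
  c(min(lo), max(hi))
}

#' Age interval of a polyploid from its subgenome divergence nodes
#'
#' Looks up the 95% HPD interval of each subgenome leaf's parent node
#' (attribute `hpd` of the tree, columns `clade`, `lower`, `upper`) and
#' merges them; without HPD annotations the point heights are used as
#' degenerate intervals.
#'
#' @param tree MUL-tree with optional `hpd` attribute.
#' @param subgenome_leaves character vector of the polyploid's leaves.
#' @return numeric `c(lower, upper)` in Ma.
#' @export
polyploid_age <- function(tree, subgenome_leaves) {
  ntip <- length(tree$tip.label)
  h <- node_heights(tree)
  keys <- clade_keys(tree)
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  hpd <- attr(tree, "hpd")
  iv <- lapply(subgenome_leaves, function(lab) {
    v <- which(tree$tip.label == lab)
    if (length(v) != 1L) stop("leaf not found: ", lab)
    p <- parent[v]
    if (!is.null(hpd) && keys[p] %in% hpd$clade) {
      row <- hpd[hpd$clade == keys[p], ]
      c(row$lower[1], row$upper[1])
    } else {
      c(h[p], h[p])
    }
  })
  merge_hpd(iv)
}

#' Rank species-delimitation scenarios by deep-coalescence score
#'
#' For every scenario (a partition of the polyploid samples into putative
#' lineages) the subgenome assignment search is run with samples of one
#' lineage sharing their subgenome labels, and the scenarios are ordered by
#' the best total number of extra lineages found (ascending).  This is a
#' surrogate criterion for the marginal-likelihood model comparison used
#' with full Bayesian machinery; ties are reported as such.
#'
#' @param samples list of [gene_tree_sample()] objects.
#' @param alleles allele table as taken by [lineage_map()].
#' @param scenarios named list of scenarios; each scenario is a named list
#'   of character vectors grouping polyploid samples into lineages.
#' @param iterations,restarts,seed search parameters, see
#'   [hill_climb_assignment()].
#' @return data.frame with one row per scenario, ordered by score;
#'   column `tied` marks scores equal to the best.
#' @export
rank_scenarios <- function(samples, alleles, scenarios, iterations = 1000L,
                           restarts = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(scenarios), function(nm) {
    map <- lineage_map(alleles, groups = scenarios[[nm]])
    fit <- hill_climb_assignment(samples, map, iterations = iterations,
                                 restarts = restarts)
    data.frame(scenario = nm, n_lineages = length(scenarios[[nm]]),
               score = fit$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$n_lineages), ]
  out$tied <- abs(out$score - out$score[1]) < 1e-9
  rownames(out) <- NULL
  attr(out, "criterion") <- "total extra lineages (MDC surrogate)"
  out
}

#' Write a species network as extended newick
#'
#' Reticulation nodes are emitted once in full and referenced as `#H<k>`
#' from their remaining parents.
#'
#' @param net a [join_subgenome_leaves()] result.
#' @return single extended-newick string.
#' @export
write_enewick <- function(net) {
  g <- net$graph
  indeg <- igraph::degree(g, mode = "in")
  roots <- names(which(indeg == 0))
  stopifnot(length(roots) == 1L)
  hy <- names(which(indeg > 1))
  hnum <- setNames(seq_along(hy), hy)
  seen <- character(0)
  el <- igraph::as_data_frame(g, what = "edges")
  emit <- function(v) {
    if (v %in% hy && v %in% seen) return(paste0("#H", hnum[v]))
    seen <<- c(seen, v)
    kids <- el$to[el$from == v]
    inner <- if (length(kids) == 0) "" else {
      parts <- vapply(kids, function(k) {
        len <- el$length[el$from == v & el$to == k][1]
        paste0(emit(k), if (!is.na(len)) paste0(":", format(len, digits = 10)))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    if (v %in% hy) {
      paste0(inner, v, "#H", hnum[v])
    } else if (length(kids) == 0) {
      v
    } else {
      inner
    }
  }
  paste0(emit(roots), ";")
}

#' Read an annotated newick tree (BEAST-style comments)
#'
#' Minimal reader for rooted trees annotated with square-bracket comments
#' of the form `[&posterior=0.97,height_95%_HPD={0.59,1.8}]`.  Posterior
#' values become `node.label`; HPD intervals are attached as attribute
#' `hpd` (data.frame with `clade`, `lower`, `upper`).
#'
#' @param text single newick string (annotations optional).
#' @return `phylo` with support labels and optional `hpd` attribute.
#' @export
read_annotated_tree <- function(text) {
  text <- gsub("\\s", "", text)
  pos <- 1L
  n <- nchar(text)
  peek <- function() substr(text, pos, pos)
  take_while <- function(stop_chars) {
    start <- pos
    while (pos <= n && !substr(text, pos, pos) %in% stop_chars) {
      pos <<- pos + 1L
    }
    substr(text, start, pos - 1L)
  }
  read_comment <- function() {
    if (peek() != "[") return(NULL)
    depth <- 0L; start <- pos
    repeat {
      ch <- substr(text, pos, pos)
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      pos <<- pos + 1L
      if (depth == 0L) break
    }
    substr(text, start + 1L, pos - 2L)
  }
  parse_annot <- function(s) {
    if (is.null(s)) return(list())
    s <- sub("^&", "", s)
    out <- list()
    m <- regmatches(s, gregexpr("[A-Za-z0-9_.%]+=\\{[^}]*\\}|[A-Za-z0-9_.%]+=[^,{]+",
                                s))[[1]]
    for (kv in m) {
      key <- sub("=.*", "", kv)
      val <- sub("^[^=]*=", "", kv)
      if (grepl("^\\{", val)) {
        out[[key]] <- as.numeric(strsplit(gsub("[{}]", "", val), ",")[[1]])
      } else {
        out[[key]] <- suppressWarnings(as.numeric(val))
      }
    }
    out
  }
  nodes <- list()
  parse_node <- function() {
    node <- list(children = integer(0), label = "", annot = list(),
                 length = NA_real_)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        node$children <- c(node$children, parse_node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed newick at position ", pos)
      }
      node$label <- take_while(c("[", ":", ",", ")", ";"))
    } else {
      node$label <- take_while(c("[", ":", ",", ")", ";"))
    }
    node$annot <- parse_annot(read_comment())
    if (peek() == ":") {
      pos <<- pos + 1L
      cm <- read_comment()
      if (!is.null(cm)) node$annot <- utils::modifyList(node$annot,
                                                        parse_annot(cm))
      node$length <- as.numeric(take_while(c(",", ")", ";", "[")))
      cm <- read_comment()
    }
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  root_id <- parse_node()
  # assemble newick without comments, collect annotations per clade
  hpd <- NULL
  build <- function(id) {
    nd <- nodes[[id]]
    if (length(nd$children) == 0) {
      tips <- nd$label
      str <- nd$label
    } else {
      sub <- lapply(nd$children, build)
      tips <- sort(unlist(lapply(sub, `[[`, "tips")))
      lab <- if (!is.null(nd$annot$posterior)) format(nd$annot$posterior) else
        nd$label
      str <- paste0("(", paste(vapply(sub, `[[`, character(1), "str"),
                               collapse = ","), ")", lab)
    }
    iv <- nd$annot[["height_95%_HPD"]]
    if (!is.null(iv) && length(iv) == 2) {
      hpd <<- rbind(hpd, data.frame(clade = clade_key(tips),
                                    lower = iv[1], upper = iv[2]))
    }
    if (!is.na(nd$length)) str <- paste0(str, ":", format(nd$length,
                                                          digits = 10))
    list(str = str, tips = tips)
  }
  res <- build(root_id)
  tr <- ape::read.tree(text = paste0(res$str, ";"))
  if (!is.null(hpd)) attr(tr, "hpd") <- hpd
  tr
}
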