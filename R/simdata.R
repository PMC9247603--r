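#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults emulate the study
#' system: a small genus of diploid mountain plants with a crown age of
#' 4.39 Ma (posterior sd 0.91 Ma), a plant-standard substitution rate of
#' 5e-9 substitutions/site/year, a 3-year generation time, five nuclear
#' amplicon loci plus one plastid locus, and 454-era amplicon depths.
#'
#' @param n_diploid_lineages number of extant diploid species.
#' @param polyploid_events list of events created with [ppevent()].
#' @param crown_age_ma crown age of the diploid species tree (Ma).
#' @param crown_age_sd_ma reported uncertainty of the crown age; carried as
#'   metadata for age intervals, the simulated root height is the mean.
#' @param pop_size diploid effective population size per branch (number of
#'   individuals; each diploid population holds `2 * pop_size` gene copies).
#' @param generation_time years per generation.
#' @param n_loci number of nuclear loci.
#' @param seq_length locus length in bp.
#' @param subst_rate substitutions per site per year.
#' @param kappa HKY transition/transversion rate ratio.
#' @param read_depth reads per sample and locus.
#' @param error_rate per-base sequencing error rate.
#' @param chimera_rate fraction of reads built as PCR recombinants.
#' @param lowq_read_frac fraction of reads emitted with uniformly low
#'   qualities, to exercise quality control.
#' @param species_tree optional ultrametric `phylo` (or newick string) fixing
#'   the diploid species tree; otherwise a random coalescent shape rescaled
#'   to the crown age is drawn.
#' @param rng_seed optional integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_diploid_lineages = 4,
                       polyploid_events = list(),
                       crown_age_ma = 4.39,
                       crown_age_sd_ma = 0.91,
                       pop_size = 2.5e5,
                       generation_time = 3,
                       n_loci = 5,
                       seq_length = 300,
                       subst_rate = 5e-9,
                       kappa = 3,
                       read_depth = 300,
                       error_rate = 0.01,
                       chimera_rate = 0.1,
                       lowq_read_frac = 0.05,
                       species_tree = NULL,
                       rng_seed = NULL) {
  stopifnot(n_diploid_lineages >= 2,
            crown_age_ma > 0, crown_age_sd_ma >= 0,
            pop_size > 0, generation_time > 0,
            n_loci >= 1, seq_length >= 1,
            subst_rate >= 0, error_rate >= 0,
            chimera_rate >= 0, chimera_rate < 1,
            lowq_read_frac >= 0, lowq_read_frac < 1)
  if (inherits(polyploid_events, "ppevent")) {
    polyploid_events <- list(polyploid_events)
  }
  for (ev in polyploid_events) {
    if (!inherits(ev, "ppevent")) stop("polyploid_events must come from ppevent()")
    if (ev$time_ma >= crown_age_ma) {
      stop("polyploid origin time must predate the crown age")
    }
  }
  if (anyDuplicated(vapply(polyploid_events, `[[`, character(1), "sample"))) {
    stop("polyploid sample names must be unique")
  }
  if (is.character(species_tree)) {
    species_tree <- ape::read.tree(text = species_tree)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Declare a polyploidization event
#'
#' An event is autopolyploid when all parents coincide (whole-genome
#' duplication within one lineage: the subgenomes share a single tetrasomic
#' population from the origin to the present) and allopolyploid otherwise
#' (each subgenome is a disomically inherited diploid complement joining its
#' own parent lineage at the origin).
#'
#' @param sample name of the polyploid sample.
#' @param parents character vector of parent diploid lineages: length 1 for
#'   an autopolyploid, one entry per subgenome for an allopolyploid
#'   (2 for tetraploids, 3 for hexaploids).
#' @param time_ma origin time in Ma before present.
#' @param ploidy 4 or 6; defaults to `2 * (length(parents) + 1)` capped
#'   sensibly: autopolyploids must state their ploidy when hexaploid.
#' @param maternal parent lineage carrying the plastid; defaults to the
#'   first parent.
#' @return object of class `ppevent`.
#' @export
ppevent <- function(sample, parents, time_ma,
                    ploidy = if (length(parents) == 1L) 4L else
                      2L * length(parents),
                    maternal = parents[1]) {
  if (!ploidy %in% c(4L, 6L)) stop("ploidy must be 4 or 6")
  type <- if (length(parents) == 1L) "auto" else "allo"
  if (type == "allo") {
    if (anyDuplicated(parents)) {
      stop("allopolyploid parents must be distinct lineages")
    }
    if (length(parents) != ploidy / 2) {
      stop("allopolyploids need one parent per subgenome")
    }
  }
  if (!maternal %in% parents) stop("maternal must be one of the parents")
  structure(list(sample = sample, parents = parents, time_ma = time_ma,
                 ploidy = as.integer(ploidy), type = type,
                 maternal = maternal),
            class = "ppevent")
}

# --- node-table tree surgery -------------------------------------------------

phylo_to_table <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  data.frame(id = seq_len(nn), parent = parent,
             height = node_heights(tree),
             label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
             pop_factor = 1, stringsAsFactors = FALSE)
}

# child-end node of the branch carrying `leaf_label` at height t
branch_at <- function(tab, leaf_label, t) {
  v <- tab$id[!is.na(tab$label) & tab$label == leaf_label]
  if (length(v) != 1L) stop("unknown lineage: ", leaf_label)
  repeat {
    p <- tab$parent[v]
    if (is.na(p)) {
      stop("origin time ", t, " Ma predates the root for lineage ", leaf_label)
    }
    if (tab$height[p] > t) return(v)
    v <- p
  }
}

# split the branch above `child` at height t; returns list(tab, node id)
split_branch <- function(tab, child, t) {
  new_id <- nrow(tab) + 1L
  tab <- rbind(tab, data.frame(id = new_id, parent = tab$parent[child],
                               height = t, label = NA_character_,
                               pop_factor = tab$pop_factor[child]))
  tab$parent[child] <- new_id
  list(tab = tab, node = new_id)
}

add_node <- function(tab, parent, height, label, pop_factor = 1) {
  new_id <- nrow(tab) + 1L
  tab <- rbind(tab, data.frame(id = new_id, parent = parent, height = height,
                               label = label, pop_factor = pop_factor))
  list(tab = tab, node = new_id)
}

table_to_phylo <- function(tab) {
  kids <- split(tab$id, factor(tab$parent, levels = tab$id))
  root <- tab$id[is.na(tab$parent)]
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (length(ch) == 0) return(tab$label[v])
    parts <- vapply(ch, function(c_) {
      paste0(rec(c_), ":", format(tab$height[v] - tab$height[c_], digits = 10))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

#' Simulate a planted polyploid history
#'
#' Draws (or takes) an ultrametric diploid species tree and realizes every
#' polyploidization event: an autopolyploid is attached as a cherry of
#' sister subgenome leaves on its parent's branch at the origin time, an
#' allopolyploid attaches one subgenome leaf to each parent's branch.  The
#' result is a multi-labeled (MUL) species tree, its folded network, the
#' per-subgenome truth table and the maternal parent of every polyploid.
#'
#' @param config a [sim_config()].
#' @return object of class `planted_history` with elements `mul_tree`
#'   (`phylo`), `network` ([join_subgenome_leaves()] result), `pop_table`
#'   (internal population tree used by the coalescent simulator),
#'   `subgenomes`, `samples`, `maternal` and `config`.
#' @export
simulate_history <- function(config) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  n <- config$n_diploid_lineages
  if (is.null(config$species_tree)) {
    sp <- ape::rcoal(n, tip.label = paste0("sp", LETTERS[seq_len(n)]))
    sp$edge.length <- sp$edge.length * config$crown_age_ma /
      max(node_heights(sp))
  } else {
    sp <- config$species_tree
  }
  mul <- phylo_to_table(sp)
  pop <- phylo_to_table(sp)

  subg <- NULL
  samples <- data.frame(sample = sp$tip.label, ploidy = 2L, kind = "diploid",
                        stringsAsFactors = FALSE)
  maternal <- character(0)
  for (ev in config$polyploid_events) {
    nb <- ev$ploidy %/% 2L
    t <- ev$time_ma
    sglab <- paste0(ev$sample, ".sg", seq_len(nb))
    if (ev$type == "auto") {
      # MUL tree: sister subgenome leaves under a zero-stem node at t
      at <- branch_at(mul, ev$parents[1], t)
      s <- split_branch(mul, at, t); mul <- s$tab
      c0 <- add_node(mul, s$node, t, NA_character_); mul <- c0$tab
      for (lab in sglab) mul <- add_node(mul, c0$node, 0, lab)$tab
      # population tree: one tetrasomic population holding all copies
      at <- branch_at(pop, ev$parents[1], t)
      s <- split_branch(pop, at, t); pop <- s$tab
      pop <- add_node(pop, s$node, 0, ev$sample, pop_factor = nb)$tab
      parents <- rep(ev$parents[1], nb)
    } else {
      anchors <- vapply(ev$parents, function(p) branch_at(mul, p, t),
                        integer(1))
      if (anyDuplicated(anchors)) {
        stop("allopolyploid parents of ", ev$sample,
             " are not distinct lineages at ", t, " Ma")
      }
      for (j in seq_len(nb)) {
        at <- branch_at(mul, ev$parents[j], t)
        s <- split_branch(mul, at, t); mul <- s$tab
        mul <- add_node(mul, s$node, 0, sglab[j])$tab
        at <- branch_at(pop, ev$parents[j], t)
        s <- split_branch(pop, at, t); pop <- s$tab
        pop <- add_node(pop, s$node, 0, sglab[j])$tab
      }
      parents <- ev$parents
    }
    subg <- rbind(subg, data.frame(sample = ev$sample,
                                   subgenome = seq_len(nb),
                                   leaf = sglab, parent = parents,
                                   origin_ma = t, stringsAsFactors = FALSE))
    samples <- rbind(samples, data.frame(sample = ev$sample,
                                         ploidy = ev$ploidy, kind = ev$type))
    maternal[ev$sample] <- ev$maternal
  }
  mul_tree <- table_to_phylo(mul)
  mul_tree$node.label <- rep("1", mul_tree$Nnode)
  polyploids <- if (is.null(subg)) list() else split(subg$leaf, subg$sample)
  maternal_leaf <- if (is.null(subg)) character(0) else
    vapply(names(polyploids), function(s) {
      d <- subg[subg$sample == s, ]
      d$leaf[match(maternal[s], d$parent)]
    }, character(1))
  net <- join_subgenome_leaves(mul_tree, polyploids,
                               maternal = maternal_leaf)
  structure(list(mul_tree = mul_tree, network = net, pop_table = pop,
                 subgenomes = subg, samples = samples, maternal = maternal,
                 maternal_leaf = maternal_leaf, config = config),
            class = "planted_history")
}

#' @export
print.planted_history <- function(x, ...) {
  cat("planted_history:", sum(x$samples$kind == "diploid"),
      "diploid lineages,", sum(x$samples$kind != "diploid"),
      "polyploid sample(s)\n")
  cat("MUL tree:", ape::write.tree(x$mul_tree), "\n")
  invisible(x)
}

#' Preset planted histories matching the study conditions
#'
#' Fixed four-species diploid tree
#' `((spA:3.5,spB:3.5):0.89,(spC:3.2,spD:3.2):1.19)` (crown age 4.39 Ma;
#' with the default population size the parent lineages used below are
#' separated by more than 2 coalescent units) and Pleistocene polyploid
#' origins at 1.5 Ma, inside the age interval reported for the study's
#' polyploids.
#'
#' @param type which planted scenario to build.
#' @param rng_seed seed passed to the configuration.
#' @param ... further arguments overriding [sim_config()] defaults.
#' @return a [sim_config()].
#' @export
preset_config <- function(type = c("allotetraploid", "autotetraploid",
                                   "allohexaploid", "two_origins",
                                   "diploids_only"),
                          rng_seed = NULL, ...) {
  type <- match.arg(type)
  tree <- "((spA:3.5,spB:3.5):0.89,(spC:3.2,spD:3.2):1.19);"
  events <- switch(type,
    allotetraploid = list(ppevent("P1", c("spA", "spC"), 1.5)),
    autotetraploid = list(ppevent("P1", "spA", 1.5)),
    allohexaploid  = list(ppevent("P1", c("spA", "spC", "spD"), 1.5,
                                  ploidy = 6)),
    two_origins    = list(ppevent("P1", c("spA", "spC"), 1.5),
                          ppevent("P2", c("spB", "spD"), 1.5)),
    diploids_only  = list())
  sim_config(n_diploid_lineages = 4, polyploid_events = events,
             species_tree = tree, rng_seed = rng_seed, ...)
}
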