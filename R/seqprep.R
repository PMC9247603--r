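# Alignment post-processing shared by all loci: simple indel coding,
# masking of the microsatellite region, and a paralog screen on gene trees.

#' Simple indel coding of alignment gaps
#'
#' One binary character per distinct indel event (identical start and end
#' column across sequences): 1 = gap present, 0 = absent.  A sequence whose
#' own gap strictly contains another sequence's indel is scored as missing
#' (`NA`) for that shorter character, since presence or absence of the
#' shorter indel cannot be assessed inside the longer deletion.
#'
#' @param aln named character vector of equal-length aligned sequences;
#'   gaps are `-`.
#' @return integer matrix (sequences x indel characters, `NA` = missing);
#'   zero columns when the alignment has no gaps.  Column names are
#'   `g<start>_<end>` in 1-based inclusive coordinates.
#' @export
simple_gap_code <- function(aln) {
  stopifnot(length(unique(nchar(aln))) == 1L)
  runs <- lapply(aln, function(s) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  })
  events <- unique(do.call(rbind, runs))
  if (is.null(events) || nrow(events) == 0) {
    return(matrix(integer(0), nrow = length(aln), ncol = 0,
                  dimnames = list(names(aln), NULL)))
  }
  events <- events[order(events[, 1], events[, 2]), , drop = FALSE]
  m <- matrix(0L, nrow = length(aln), ncol = nrow(events),
              dimnames = list(names(aln),
                              paste0("g", events[, 1], "_", events[, 2])))
  for (i in seq_along(aln)) {
    ri <- runs[[i]]
    if (nrow(ri) == 0) next
    for (j in seq_len(nrow(events))) {
      s <- events[j, 1]; e <- events[j, 2]
      exact <- any(ri[, 1] == s & ri[, 2] == e)
      if (exact) {
        m[i, j] <- 1L
      } else if (any(ri[, 1] <= s & ri[, 2] >= e)) {
        m[i, j] <- NA_integer_           # inside a longer gap: inapplicable
      }
    }
  }
  m
}

#' Remove an alignment region
#'
#' Excludes the 1-based inclusive column range `start:end` (used for the
#' microsatellite motif whose length variation is homoplastic noise).
#' An empty range (`start > end`) is the identity.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param start,end 1-based inclusive column coordinates.
#' @return the masked alignment.
#' @export
mask_region <- function(aln, start, end) {
  L <- nchar(aln[1])
  stopifnot(length(unique(nchar(aln))) == 1L)
  if (start > end) return(aln)
  if (start < 1 || end > L) stop("mask range ", start, "-", end,
                                 " outside alignment of ", L, " columns")
  keep <- setdiff(seq_len(L), start:end)
  if (length(keep) == 0) warning("masking removed the whole alignment")
  vapply(aln, function(s)
    paste0(strsplit(s, "")[[1]][keep], collapse = ""), character(1))
}

#' Parameters of the paralog screen
#'
#' @param support_min minimum clade support (default 0.95).
#' @param stem_factor multiple of the median internal branch length a stem
#'   must reach (default 3).
#' @return object of class `paralog_params`.
#' @export
paralog_params <- function(support_min = 0.95, stem_factor = 3.0) {
  stopifnot(support_min > 0, support_min <= 1, stem_factor > 0)
  structure(list(support_min = support_min, stem_factor = stem_factor),
            class = "paralog_params")
}

#' Flag putative paralog sequences on a gene tree
#'
#' A clade is a paralog suspect when it is well supported
#' (support >= `support_min`), sits on a long stem
#' (>= `stem_factor` x median internal branch length), and joins sequences
#' from at least two a-priori taxa — single-copy orthologs should not form
#' deep mixed-taxon clades.  A suspect clade is only excluded when every
#' affected sample keeps at least one sequence outside it.
#'
#' @param tree `phylo` with `node.label` support values in `[0, 1]` and
#'   branch lengths.
#' @param taxon_map named character vector, sequence id -> a-priori taxon.
#' @param sample_map named character vector, sequence id -> sample; defaults
#'   to the taxon map (one accession per taxon).
#' @param params a [paralog_params()].
#' @return character vector of sequence ids to exclude.
#' @export
flag_paralogs <- function(tree, taxon_map, sample_map = taxon_map,
                          params = paralog_params()) {
  if (is.null(tree$node.label) || all(tree$node.label == "")) {
    stop("tree has no support values")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  internal_child <- tree$edge[, 2] > ntip
  med <- stats::median(tree$edge.length[internal_child])
  if (is.na(med) || med == 0) return(character(0))   # star tree: no stems

  cand <- list()
  for (i in which(internal_child)) {
    v <- tree$edge[i, 2]
    sup <- support[v - ntip]
    stem <- tree$edge.length[i]
    if (is.na(sup) || sup < params$support_min) next
    if (stem < params$stem_factor * med) next
    tips <- ape::extract.clade(tree, v)$tip.label
    if (length(unique(taxon_map[tips])) < 2L) next
    cand[[length(cand) + 1L]] <- tips
  }
  if (length(cand) == 0) return(character(0))
  cand <- cand[order(vapply(cand, length, integer(1)), decreasing = TRUE)]
  dropped <- character(0)
  for (tips in cand) {
    tips <- setdiff(tips, dropped)
    if (length(tips) == 0) next
    would_drop <- union(dropped, tips)
    affected <- unique(sample_map[tips])
    survives <- vapply(affected, function(s) {
      any(!names(sample_map)[sample_map == s] %in% would_drop)
    }, logical(1))
    if (all(survives)) dropped <- would_drop
  }
  dropped
}
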