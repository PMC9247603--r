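# Ploidy-aware allele calling from amplicon reads: quality filtering,
# clustering, cluster-size retention, PCR-chimera removal, IUPAC consensus,
# plus the clone-sampling and flow-cytometry utility calculators.

#' Quality-control parameters for allele calling
#'
#' @param phred_min Phred score below which a base counts as low quality
#'   (default 20).
#' @param max_lowq_frac maximum tolerated fraction of low-quality positions:
#'   reads with strictly more are discarded (default 0.10).
#' @param wobble_threshold minimum within-cluster frequency for a base to be
#'   retained as an IUPAC wobble in the consensus (default 0.20).
#' @param sanger_minor_peak minimum relative intensity of the weakest Sanger
#'   peak, carried for reporting (default 0.25).
#' @param min_read_factor factor of the per-allele expected read count below
#'   which a cluster is not an allele candidate (default 0.5).
#' @param cluster_cut_factor multiple of the estimated within-allele pairwise
#'   read distance at which agglomerative clustering stops merging
#'   (default 1.5).
#' @return object of class `qc_params`.
#' @export
qc_params <- function(phred_min = 20L, max_lowq_frac = 0.10,
                      wobble_threshold = 0.20, sanger_minor_peak = 0.25,
                      min_read_factor = 0.5, cluster_cut_factor = 1.5) {
  stopifnot(max_lowq_frac > 0, max_lowq_frac < 1,
            wobble_threshold > 0, wobble_threshold < 1,
            sanger_minor_peak > 0, sanger_minor_peak < 1,
            min_read_factor > 0, min_read_factor <= 1)
  structure(list(phred_min = phred_min, max_lowq_frac = max_lowq_frac,
                 wobble_threshold = wobble_threshold,
                 sanger_minor_peak = sanger_minor_peak,
                 min_read_factor = min_read_factor,
                 cluster_cut_factor = cluster_cut_factor),
            class = "qc_params")
}

#' Discard low-quality reads
#'
#' Retains exactly the reads whose fraction of positions with Phred score
#' below `phred_min` is at most `max_lowq_frac`; strictly more low-quality
#' positions means the read is discarded.
#'
#' @param reads a [read_set()].
#' @param params a [qc_params()].
#' @return the retained [read_set()].
#' @export
qc_filter <- function(reads, params = qc_params()) {
  if (length(reads) == 0) {
    warning("empty read set")
    return(reads)
  }
  frac <- vapply(reads$qual, function(q) mean(q < params$phred_min),
                 numeric(1))
  reads[frac <= params$max_lowq_frac]
}

# base x read indicator stacks used for Hamming distances and consensus
base_indicators <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  lapply(c("A", "C", "G", "T"), function(b) m == b)
}

hamming_matrix <- function(seqs) {
  L <- nchar(seqs[1])
  ind <- base_indicators(seqs)
  match_ <- Reduce(`+`, lapply(ind, function(I) tcrossprod(I * 1)))
  L - match_
}

#' Cluster reads into putative alleles
#'
#' Average-linkage agglomerative clustering on pairwise Hamming distance.
#' Merging stops at `cluster_cut_factor` times the expected within-allele
#' pairwise distance `2 * e * L`, where `e` is the mean per-base error
#' probability implied by the quality strings — reads of one allele differ
#' only by errors, reads of different alleles additionally by the allele
#' divergence.  Reads must be equal length (amplicon loci without indels).
#'
#' @param reads a [read_set()] from one sample and locus, QC-passed.
#' @param params a [qc_params()].
#' @return list of clusters ordered by size descending; each has `members`
#'   (read indices into `reads`), `ids`, and `size`.
#' @export
cluster_reads <- function(reads, params = qc_params()) {
  n <- length(reads)
  if (n == 0) return(list())
  if (length(unique(nchar(reads$seq))) != 1L) {
    stop("reads must be equal length (no-indel amplicons)")
  }
  if (n == 1L) {
    return(list(list(members = 1L, ids = reads$id, size = 1L)))
  }
  L <- nchar(reads$seq[1])
  e_hat <- mean(vapply(reads$qual, function(q) mean(10^(-q / 10)), numeric(1)))
  cut <- max(params$cluster_cut_factor * 2 * e_hat * L, 1)
  D <- hamming_matrix(reads$seq)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  grp <- stats::cutree(hc, h = cut)
  cl <- lapply(split(seq_len(n), grp), function(ix)
    list(members = ix, ids = reads$id[ix], size = length(ix)))
  cl[order(vapply(cl, `[[`, integer(1), "size"), decreasing = TRUE)]
}

#' Minimum read count for an allele candidate
#'
#' A cluster is a plausible allele only when it holds at least a set
#' fraction of the reads expected per allele: `ceil(factor * total / ploidy)`.
#'
#' @param total_reads total QC-passed reads of the sample at the locus.
#' @param ploidy 2, 4 or 6.
#' @param params a [qc_params()] (uses `min_read_factor`).
#' @return integer cutoff.
#' @export
min_reads_cutoff <- function(total_reads, ploidy, params = qc_params()) {
  stopifnot(total_reads > 0)
  if (!ploidy %in% c(2L, 4L, 6L)) stop("ploidy must be 2, 4 or 6")
  as.integer(ceiling(params$min_read_factor * total_reads / ploidy))
}

#' Flag PCR-chimeric reads against candidate alleles
#'
#' A read is flagged when some breakpoint `k` and ordered pair of distinct
#' candidate alleles `(a, b)` make its mismatches against the recombinant
#' `a[1..k] + b[k+1..L]` strictly smaller than its mismatches against every
#' single candidate allele.
#'
#' @param reads a [read_set()].
#' @param candidate_alleles character vector of candidate allele sequences
#'   (IUPAC consensus strings are compared by exact symbol match).
#' @return character vector of flagged read ids (no-op with < 2 candidates).
#' @export
detect_chimeras <- function(reads, candidate_alleles) {
  if (length(candidate_alleles) < 2L) return(character(0))
  L <- nchar(reads$seq[1])
  am <- do.call(rbind, strsplit(candidate_alleles, ""))
  na <- nrow(am)
  flagged <- logical(length(reads))
  for (i in seq_along(reads$id)) {
    r <- strsplit(reads$seq[i], "")[[1]]
    mm <- vapply(seq_len(na), function(j) cumsum(r != am[j, ]),
                 numeric(L))                       # L x na cumulative
    tot <- mm[L, ]
    best_single <- min(tot)
    best_rec <- Inf
    for (a in seq_len(na)) {
      for (b in seq_len(na)[-a]) {
        v <- mm[seq_len(L - 1L), a] + tot[b] - mm[seq_len(L - 1L), b]
        best_rec <- min(best_rec, min(v))
      }
    }
    flagged[i] <- best_rec < best_single
  }
  reads$id[flagged]
}

#' IUPAC consensus of a read cluster
#'
#' Per column, every base whose relative frequency reaches
#' `wobble_threshold` is retained; multiple retained bases are encoded as
#' the matching IUPAC ambiguity symbol (intra-allelic polymorphism), a
#' single retained base as itself.  Ties at the majority are encoded as the
#' IUPAC code over the tied bases.
#'
#' @param seqs character vector of aligned (equal-length) read sequences.
#' @param params a [qc_params()].
#' @return consensus string over the IUPAC alphabet.
#' @export
consensus_iupac <- function(seqs, params = qc_params()) {
  if (length(seqs) == 0) stop("empty cluster")
  m <- do.call(rbind, strsplit(seqs, ""))
  apply_col <- function(col) {
    f <- table(col) / length(col)
    keep <- names(f)[f >= params$wobble_threshold]
    if (length(keep) == 0) {
      keep <- names(f)[f == max(f)]      # ties: IUPAC over tied bases
    }
    iupac_code(keep)
  }
  paste0(apply(m, 2, apply_col), collapse = "")
}

iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste0(bases, collapse = "")
  rev_map <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                      vapply(Biostrings::IUPAC_CODE_MAP, function(s)
                        paste0(sort(strsplit(s, "")[[1]]), collapse = ""),
                        character(1)))
  code <- rev_map[key]
  if (is.na(code)) stop("no IUPAC code for bases ", key)
  unname(code)
}

#' Probability of observing all alleles among sequenced clones
#'
#' Inclusion–exclusion (coupon collector) over `k` equally frequent alleles:
#' the probability that `n` picked clones contain every allele at least once
#' is `sum_{i=0..k} (-1)^i C(k,i) ((k-i)/k)^n`.  With fewer clones than
#' alleles the probability is zero.
#'
#' @param n_clones number of clones picked.
#' @param n_alleles number of distinct alleles (`>= 1`).
#' @return probability in `[0, 1]`.
#' @seealso [clones_needed()]
#' @export
prob_all_alleles <- function(n_clones, n_alleles) {
  stopifnot(n_alleles >= 1)
  if (n_clones < n_alleles) return(0)
  i <- 0:n_alleles
  p <- sum((-1)^i * choose(n_alleles, i) * ((n_alleles - i) / n_alleles)^n_clones)
  min(max(p, 0), 1)
}

#' Smallest clone number reaching a target recovery probability
#'
#' @param n_alleles number of distinct alleles.
#' @param target required probability of recovering all alleles.
#' @return smallest integer `n` with `prob_all_alleles(n, n_alleles) >= target`.
#' @export
clones_needed <- function(n_alleles, target = 0.95) {
  n <- as.integer(n_alleles)
  while (prob_all_alleles(n, n_alleles) < target) n <- n + 1L
  n
}

#' Classify ploidy from a flow-cytometric fluorescence ratio
#'
#' The ratio of sample to internal-standard fluorescence falls into
#' non-overlapping per-ploidy reference ranges; the default ranges are the
#' spans observed for diploid, tetraploid and hexaploid accessions of the
#' study system (2x: 3.27–3.86, 4x: 5.76–6.28, 6x: 7.43–7.86).
#'
#' @param ratio observed fluorescence ratio.
#' @param reference data.frame with columns `ploidy`, `lower`, `upper`.
#' @return inferred ploidy (2, 4 or 6); out-of-range ratios are classified
#'   to the nearest range with a warning.
#' @export
classify_ploidy <- function(ratio, reference = ploidy_reference()) {
  o <- order(reference$lower)
  reference <- reference[o, ]
  if (any(reference$lower[-1] <= reference$upper[-nrow(reference)])) {
    stop("reference ranges overlap")
  }
  inside <- which(ratio >= reference$lower & ratio <= reference$upper)
  if (length(inside) == 1L) return(reference$ploidy[inside])
  d <- pmin(abs(ratio - reference$lower), abs(ratio - reference$upper))
  warning("ratio ", ratio, " outside all reference ranges; using nearest")
  reference$ploidy[which.min(d)]
}

#' @rdname classify_ploidy
#' @export
ploidy_reference <- function() {
  data.frame(ploidy = c(2L, 4L, 6L),
             lower = c(3.27, 5.76, 7.43),
             upper = c(3.86, 6.28, 7.86))
}

#' Call alleles for one sample and locus
#'
#' Full calling pipeline: quality filter, read clustering, ploidy-aware
#' cluster-size retention, chimera flagging against the candidate consensus
#' alleles, and IUPAC consensus of the surviving clusters.
#'
#' @param reads a [read_set()] of one sample at one locus.
#' @param ploidy sample ploidy (2, 4 or 6).
#' @param params a [qc_params()].
#' @param sample_id,locus_id identifiers carried into the result.
#' @return object of class `allele_set`: `alleles` (consensus strings,
#'   support-ordered), `support` (reads per allele), `flagged_chimeras`,
#'   `discarded_qc`, and a `warning` flag set when more alleles than the
#'   ploidy allows were retained.
#' @export
call_alleles <- function(reads, ploidy, params = qc_params(),
                         sample_id = "sample", locus_id = "locus") {
  kept <- qc_filter(reads, params)
  discarded <- setdiff(reads$id, kept$id)
  if (length(kept) == 0) {
    return(structure(list(sample_id = sample_id, locus_id = locus_id,
                          ploidy = ploidy, alleles = character(0),
                          support = integer(0), flagged_chimeras = character(0),
                          discarded_qc = discarded, warning = FALSE),
                     class = "allele_set"))
  }
  clusters <- cluster_reads(kept, params)
  cutoff <- min_reads_cutoff(length(kept), ploidy, params)
  big <- clusters[vapply(clusters, `[[`, integer(1), "size") >= cutoff]
  candidates <- vapply(big, function(cl)
    consensus_iupac(kept$seq[cl$members], params), character(1))
  flagged <- detect_chimeras(kept, candidates)
  alleles <- character(0); support <- integer(0)
  for (cl in big) {
    keep_ix <- cl$members[!kept$id[cl$members] %in% flagged]
    if (length(keep_ix) < cutoff) next
    alleles <- c(alleles, consensus_iupac(kept$seq[keep_ix], params))
    support <- c(support, length(keep_ix))
  }
  o <- order(support, decreasing = TRUE)
  structure(list(sample_id = sample_id, locus_id = locus_id, ploidy = ploidy,
                 alleles = alleles[o], support = support[o],
                 flagged_chimeras = flagged, discarded_qc = discarded,
                 warning = length(alleles) > ploidy),
            class = "allele_set")
}

#' Write called allele sets as FASTA
#'
#' One record per allele with header `sample|locus|allele_k|reads=n`.
#'
#' @param allele_sets a single `allele_set` or list of them.
#' @param path output FASTA file.
#' @export
write_allele_fasta <- function(allele_sets, path) {
  if (inherits(allele_sets, "allele_set")) allele_sets <- list(allele_sets)
  seqs <- character(0)
  for (as_ in allele_sets) {
    if (length(as_$alleles) == 0) next
    nm <- sprintf("%s|%s|allele_%d|reads=%d", as_$sample_id, as_$locus_id,
                  seq_along(as_$alleles), as_$support)
    seqs[nm] <- as_$alleles
  }
  write_fasta(seqs, path)
}

#' @export
print.allele_set <- function(x, ...) {
  cat("allele_set:", x$sample_id, "/", x$locus_id, "- ploidy", x$ploidy,
      "-", length(x$alleles), "allele(s), support:",
      paste(x$support, collapse = ", "), "\n")
  if (x$warning) cat("  warning: more alleles than expected from ploidy\n")
  invisible(x)
}
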