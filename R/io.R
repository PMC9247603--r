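#' Read set container
#'
#' Parallel vectors of read ids, sequences and per-base Phred qualities.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of nucleotide strings.
#' @param qual list of integer vectors, one per read, `nchar(seq)` long.
#' @param truth optional data.frame of simulation truth labels.
#' @return object of class `read_set`.
#' @export
read_set <- function(id, seq, qual, truth = NULL) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  ok <- vapply(seq_along(seq), function(i)
    nchar(seq[i]) == length(qual[[i]]), logical(1))
  if (!all(ok)) stop("sequence and quality lengths differ")
  structure(list(id = id, seq = seq, qual = qual, truth = truth),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x), "reads",
      if (length(x)) paste0("of length ", nchar(x$seq[1])), "\n")
  invisible(x)
}

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$seq[i], x$qual[i],
           truth = if (!is.null(x$truth)) x$truth[match(x$id[i], x$truth$id), ])
}

#' Write a read set as FASTQ
#' @param reads a [read_set()].
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(vapply(reads$qual, function(v)
    rawToChar(as.raw(v + 33L)), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- lapply(as.character(S4Vectors::mcols(x)$qualities), function(s)
    as.integer(charToRaw(s)) - 33L)
  read_set(names(x), unname(as.character(x)), q)
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a simulated data set to a directory
#'
#' Plain-text artifacts only: FASTQ reads per sample and locus, FASTA truth
#' alleles and plastid haplotypes, one newick file of sampled gene trees per
#' locus (one tree per line), TSV truth tables, and the planted network as
#' extended newick.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @export
write_simdata <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(dataset$reads)) {
    for (l in names(dataset$reads[[s]])) {
      write_fastq(dataset$reads[[s]][[l]],
                  file.path(dir, paste0(s, "_", l, ".fastq")))
    }
  }
  al <- dataset$alleles
  write_fasta(setNames(al$seq, al$allele), file.path(dir, "true_alleles.fasta"))
  write_fasta(dataset$plastid, file.path(dir, "plastid.fasta"))
  for (l in names(dataset$gene_trees$samples)) {
    ape::write.tree(dataset$gene_trees$samples[[l]]$trees,
                    file.path(dir, paste0("genetrees_", l, ".nwk")))
  }
  reg <- dataset$gene_trees$registry
  utils::write.table(reg, file.path(dir, "allele_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$history$samples, file.path(dir, "ploidy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(write_enewick(dataset$history$network),
             file.path(dir, "true_network.enwk"))
  invisible(dir)
}
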