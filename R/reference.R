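#' Reference sequence container
#'
#' A `ReferenceSequence` holds one uppercase nucleotide string per contig.
#' Contig order is meaningful: it defines the sort order of call sets.
#'
#' @param contigs named character vector of nucleotide strings
#'   (alphabet A, C, G, T, N). Names are the contig identifiers.
#' @return an object of class `ReferenceSequence`
#' @export
reference_sequence <- function(contigs) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("every contig must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig names: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(contigs)
  if (any(nchar(contigs) < 1L)) stop("empty contig sequence")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig ", names(contigs)[bad][1], " contains non-ACGTN characters")
  structure(list(contigs = contigs), class = "ReferenceSequence")
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; contig names are taken up to the first
#' whitespace in the FASTA header.
#'
#' @param path path to a FASTA file
#' @return a [reference_sequence()] object
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- nm
  reference_sequence(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param ref a [reference_sequence()] object
#' @param path output path
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ReferenceSequence"))
  ss <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @export
print.ReferenceSequence <- function(x, ...) {
  cat("ReferenceSequence with", length(x$contigs), "contig(s)\n")
  for (nm in names(x$contigs))
    cat(sprintf("  %s  %d bp\n", nm, nchar(x$contigs[[nm]])))
  invisible(x)
}

#' Contig names of a reference, in reference order
#' @param ref a `ReferenceSequence`
#' @return character vector
#' @export
contig_names <- function(ref) names(ref$contigs)

#' Contig lengths of a reference
#' @param ref a `ReferenceSequence`
#' @return named integer vector
#' @export
contig_lengths <- function(ref) {
  vapply(ref$contigs, nchar, integer(1))
}

# 1-based inclusive substring of a contig; no bounds forgiveness.
ref_slice <- function(ref, contig, start, end) {
  seq <- ref$contigs[[contig]]
  if (is.null(seq)) stop("contig not in reference: ", contig)
  if (start < 1L || end > nchar(seq) || start > end)
    stop(sprintf("slice %s:%d-%d outside contig bounds", contig, start, end))
  substr(seq, start, end)
}
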