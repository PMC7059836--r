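#' Region sets (BED-style interval collections)
#'
#' A `RegionSet` is a per-contig collection of merged, sorted intervals
#' carrying a class tag. Intervals follow the BED convention on input
#' (0-based, half-open); internally they are stored 1-based inclusive so
#' that a VCF position can be queried directly.
#'
#' @param intervals a data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open, BED convention); may have zero rows
#' @param class_tag one of `"confidence"`, `"exclusion"`, `"novel"`,
#'   `"par"`
#' @return an object of class `RegionSet`
#' @export
region_set <- function(intervals, class_tag = c("confidence", "exclusion",
                                                "novel", "par")) {
  class_tag <- match.arg(class_tag)
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(structure(list(class_tag = class_tag, ranges = list()),
                     class = "RegionSet"))
  }
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  start <- as.numeric(intervals$start)
  end <- as.numeric(intervals$end)
  if (any(start < 0)) stop("negative interval start")
  if (any(start >= end)) stop("interval start must be < end (0-based half-open)")
  ranges <- lapply(split(seq_len(nrow(intervals)), as.character(intervals$contig)),
                   function(i) {
                     IRanges::reduce(IRanges::IRanges(start = start[i] + 1L,
                                                      end = end[i]))
                   })
  structure(list(class_tag = class_tag, ranges = ranges), class = "RegionSet")
}

#' Read a BED file into a RegionSet
#'
#' Accepts BED with three or more columns; extra columns are ignored.
#' Overlapping intervals are merged.
#'
#' @param path path to a BED file
#' @inheritParams region_set
#' @return a [region_set()] object
#' @export
read_region_set <- function(path, class_tag = "confidence") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(region_set(NULL, class_tag))
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  bed <- bed[, 1:3]
  names(bed) <- c("contig", "start", "end")
  bed$contig <- as.character(bed$contig)
  region_set(bed, class_tag)
}

#' Write a RegionSet as BED3
#'
#' @param rs a `RegionSet`
#' @param path output path
#' @export
write_region_set <- function(rs, path) {
  stopifnot(inherits(rs, "RegionSet"))
  rows <- lapply(names(rs$ranges), function(ctg) {
    r <- rs$ranges[[ctg]]
    data.frame(contig = ctg, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test membership of 1-based positions in a RegionSet
#'
#' @param rs a `RegionSet`
#' @param contig character vector of contig names
#' @param pos integer vector of 1-based positions (VCF convention);
#'   recycled against `contig`
#' @return logical vector
#' @export
region_member <- function(rs, contig, pos) {
  stopifnot(inherits(rs, "RegionSet"))
  n <- max(length(contig), length(pos))
  contig <- rep_len(as.character(contig), n)
  pos <- rep_len(as.integer(pos), n)
  out <- logical(n)
  for (ctg in unique(contig)) {
    r <- rs$ranges[[ctg]]
    idx <- which(contig == ctg)
    if (is.null(r)) next
    out[idx] <- IRanges::overlapsAny(IRanges::IRanges(pos[idx], pos[idx]), r)
  }
  out
}

#' Total number of bases covered by a RegionSet
#' @param rs a `RegionSet`
#' @return numeric scalar
#' @export
region_covered_length <- function(rs) {
  stopifnot(inherits(rs, "RegionSet"))
  if (!length(rs$ranges)) return(0)
  sum(vapply(rs$ranges, function(r) sum(IRanges::width(r)), numeric(1)))
}

#' @export
print.RegionSet <- function(x, ...) {
  n <- sum(vapply(x$ranges, length, integer(1)))
  cat(sprintf("RegionSet <%s>: %d interval(s) on %d contig(s), %g bp covered\n",
              x$class_tag, n, length(x$ranges), region_covered_length(x)))
  invisible(x)
}
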