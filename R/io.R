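#' Read and write the pipeline's tabular formats
#'
#' Binned tracks travel as TSV with 0-based half-open coordinates
#' (`chrom`, `start0`, `end0`, `raw_count`, `gc`, `mappable`); internally
#' the package uses 1-based inclusive coordinates. Segmentations are
#' written SEG-like (`sample`, `chrom`, `start`, `end`, `rCN`, `aCN`,
#' `state`) and as BED (0-based half-open); SV truth and calls as BEDPE;
#' expression matrices as TSV with a header row of sample ids; gene sets
#' as GMT.
#'
#' @param track,segments,calls,m objects to write (see the corresponding
#'   builders).
#' @param path file path.
#' @name genomescars-io
NULL

#' @rdname genomescars-io
#' @export
write_binned_track <- function(track, path) {
  out <- data.frame(chrom = track$chrom, start0 = track$start - 1,
                    end0 = track$end, raw_count = track$count,
                    gc = track$gc, mappable = as.integer(track$mappable))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genomescars-io
#' @export
read_binned_track <- function(path) {
  x <- read.delim(path)
  data.frame(chrom = x$chrom, start = x$start0 + 1, end = x$end0,
             count = x$raw_count, gc = x$gc,
             mappable = as.logical(x$mappable))
}

#' @rdname genomescars-io
#' @export
write_segments_seg <- function(segments, path) {
  out <- data.frame(sample = segments$sample %||% "sample",
                    chrom = segments$chrom, start = segments$start,
                    end = segments$end, rCN = segments$rcn,
                    aCN = segments$acn %||% NA,
                    state = segments$state %||% NA)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genomescars-io
#' @export
read_segments_seg <- function(path) {
  x <- read.delim(path)
  data.frame(sample = x$sample, chrom = x$chrom, start = x$start,
             end = x$end, rcn = x$rCN, acn = x$aCN, state = x$state)
}

#' @rdname genomescars-io
#' @export
write_bed <- function(segments, path, name_col = NULL) {
  out <- data.frame(chrom = segments$chrom, start0 = segments$start - 1,
                    end0 = segments$end,
                    name = if (!is.null(name_col)) segments[[name_col]]
                           else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname genomescars-io
#' @export
write_bedpe <- function(calls, path) {
  out <- data.frame(chrom1 = calls$chrom1, start1 = calls$pos1 - 1,
                    end1 = calls$pos1, chrom2 = calls$chrom2,
                    start2 = calls$pos2 - 1, end2 = calls$pos2,
                    name = calls$type,
                    score = calls$n_pairs %||% ".",
                    strand1 = ".", strand2 = ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname genomescars-io
#' @export
write_expression_tsv <- function(m, path) {
  write.table(data.frame(feature = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genomescars-io
#' @export
read_expression_tsv <- function(path) {
  x <- read.delim(path, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

#' @rdname genomescars-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  sets
}

#' @rdname genomescars-io
#' @export
write_comb_json <- function(comb, path) {
  jsonlite::write_json(unclass(comb), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
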