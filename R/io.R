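#' Read segmented absolute copy number profiles
#'
#' Parses a segment table in one of three dialects into the canonical
#' segment representation used throughout the package: one row per segment
#' with columns `sample`, `chromosome`, `start`, `end`, `segVal` (integer
#' absolute copy number, diploid baseline 2). Coordinates are 1-based
#' inclusive. Chromosome names are normalised to the `chr`-prefixed form;
#' chromosome Y and unplaced contigs are dropped (a message reports how many
#' rows). Non-integer copy numbers are rounded half-up.
#'
#' @param source Path to a TSV file, or a `data.frame` already in the
#'   declared dialect.
#' @param format Input dialect: `"generic"` (columns `sample`, `chromosome`,
#'   `start`, `end`, `segVal`), `"sequenza"` (`chromosome`, `start.pos`,
#'   `end.pos`, `CNt`), or `"facets"` (`chrom`, `start`, `end`, `tcn.em`).
#' @param sample_id Sample identifier used for dialects that carry no sample
#'   column (sequenza, facets). Defaults to the file basename (or
#'   `"sample"` for in-memory tables).
#' @return A `data.table` of segments, sorted by sample, chromosome and
#'   start. Not yet merged: pass through [normalize_profile()] before
#'   feature computation.
#' @seealso [normalize_profile()], [write_segments()]
#' @export
read_segments <- function(source, format = c("generic", "sequenza", "facets"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (is.character(source) && length(source) == 1L) {
    tab <- data.table::fread(source, sep = "\t", data.table = TRUE)
    if (is.null(sample_id)) {
      sample_id <- sub("_segments\\.txt$|\\.tsv$|\\.txt$", "", basename(source))
    }
  } else {
    tab <- data.table::as.data.table(source)
    if (is.null(sample_id)) sample_id <- "sample"
  }

  cols <- switch(format,
    generic  = c(sample = "sample", chromosome = "chromosome",
                 start = "start", end = "end", segVal = "segVal"),
    sequenza = c(chromosome = "chromosome", start = "start.pos",
                 end = "end.pos", segVal = "CNt"),
    facets   = c(chromosome = "chrom", start = "start", end = "end",
                 segVal = "tcn.em"))
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols)) {
    stop("missing required column(s) for ", format, " format: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  segs <- data.table::data.table(
    sample = if ("sample" %in% names(cols)) as.character(tab[[cols[["sample"]]]])
             else rep(sample_id, nrow(tab)),
    chromosome = as.character(tab[[cols[["chromosome"]]]]),
    start = as.numeric(tab[[cols[["start"]]]]),
    end = as.numeric(tab[[cols[["end"]]]]),
    segVal = as.numeric(tab[[cols[["segVal"]]]]))

  # FACETS encodes chromosomes numerically with X as 23
  segs[, chromosome := normalize_chrom(chromosome)]
  keep <- segs$chromosome %in% paste0("chr", c(1:22, "X"))
  if (any(!keep)) {
    message("dropped ", sum(!keep),
            " segment(s) on chrY or unplaced contigs")
    segs <- segs[keep]
  }

  bad <- which(segs$segVal < 0)
  if (length(bad)) {
    stop("negative copy number in row ", bad[1L], ": ",
         paste(unlist(segs[bad[1L]]), collapse = " "), call. = FALSE)
  }
  if (any(segs$start > segs$end)) {
    stop("segment with start > end found", call. = FALSE)
  }
  segs[, segVal := floor(segVal + 0.5)]  # round half-up
  data.table::setorder(segs, sample, chromosome, start)
  segs[]
}

normalize_chrom <- function(chromosome) {
  x <- sub("^chr", "", as.character(chromosome))
  x[x == "23"] <- "X"
  paste0("chr", x)
}

#' Write segments as a generic seg TSV
#'
#' @param segs Segment table (`sample`, `chromosome`, `start`, `end`,
#'   `segVal`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  data.table::fwrite(segs[, c("sample", "chromosome", "start", "end", "segVal")],
                     path, sep = "\t")
  invisible(path)
}

#' Normalise a copy number profile
#'
#' Sorts segments within each sample and chromosome and merges runs of
#' contiguous segments (next start exactly one past the previous end) that
#' share the same copy number, so that every junction between contiguous
#' segments is a true copy number breakpoint. Gaps between segments are
#' permitted and preserved; overlapping segments are an error.
#'
#' @param segs Segment table as returned by [read_segments()]; may contain
#'   several samples.
#' @return A `data.table` of normalised segments.
#' @export
normalize_profile <- function(segs) {
  segs <- data.table::as.data.table(segs)
  data.table::setorder(segs, sample, chromosome, start)
  prev_end <- segs[, data.table::shift(end), by = .(sample, chromosome)]$V1
  overlap <- which(!is.na(prev_end) & segs$start <= prev_end)
  if (length(overlap)) {
    i <- overlap[1L]
    stop(sprintf("overlapping segments in sample %s on %s: %d-%d overlaps previous end %d",
                 segs$sample[i], segs$chromosome[i], as.integer(segs$start[i]),
                 as.integer(segs$end[i]), as.integer(prev_end[i])), call. = FALSE)
  }
  # merge contiguous equal-cn runs
  new_run <- is.na(prev_end) | segs$start != prev_end + 1 |
    segs$segVal != segs[, data.table::shift(segVal), by = .(sample, chromosome)]$V1
  run_id <- cumsum(new_run)
  out <- segs[, .(sample = sample[1L], chromosome = chromosome[1L],
                  start = start[1L], end = end[.N], segVal = segVal[1L]),
              by = .(run = run_id)]
  out[, run := NULL]
  data.table::setorder(out, sample, chromosome, start)
  out[]
}

# Validate that every chromosome in `segs` exists in `build` and that
# segments lie within chromosome bounds.
check_against_build <- function(segs, build) {
  chroms <- build$chromosomes
  unknown <- setdiff(unique(segs$chromosome), chroms$chromosome)
  if (length(unknown)) {
    stop("chromosome(s) absent from build ", sQuote(build$name), ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  len <- chroms$length[match(segs$chromosome, chroms$chromosome)]
  if (any(segs$start < 1 | segs$end > len)) {
    stop("segment outside chromosome bounds of build ", sQuote(build$name),
         call. = FALSE)
  }
  invisible(TRUE)
}
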