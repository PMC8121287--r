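#' Genome-wide copy number feature distributions
#'
#' Computes the eight copy number features of one sample's normalised
#' absolute copy number profile:
#'
#' * `BP10MB` - breakpoint count in each consecutive 10 Mb window, tiled
#'   from position 1 on every chromosome present in the profile (the last
#'   partial window included). A junction between consecutive segments is
#'   located at the end coordinate of its left segment.
#' * `BPArm` - breakpoint count per chromosome arm; two observations (p then
#'   q) for every chromosome of the build, zero where a chromosome carries
#'   no junctions.
#' * `CN` - the absolute copy number of each segment.
#' * `CNCP` - the copy number change point `|cn_right - cn_left|` at each
#'   junction.
#' * `OsCN` - lengths of oscillating copy number chains, see
#'   [oscillation_chains()].
#' * `SS` - log10 of each segment size in bp.
#' * `NC50` - minimal number of chromosomes carrying half of all altered
#'   segments, see [nc50()]; exactly one observation per sample.
#' * `BoChr` - chromosome index (1-22, X = 23) of each altered segment, see
#'   [bochr()].
#'
#' @param segs Normalised segments of a single sample (see
#'   [normalize_profile()]).
#' @param build A [genome_build][load_genome_build()].
#' @param baseline Copy number considered neutral (default 2).
#' @return A named list of 8 numeric vectors, one per feature.
#' @export
compute_features <- function(segs, build, baseline = 2) {
  segs <- data.table::as.data.table(segs)
  if (length(unique(segs$sample)) > 1L) {
    stop("compute_features() expects a single-sample profile", call. = FALSE)
  }
  check_against_build(segs, build)
  data.table::setorder(segs, chromosome, start)

  by_chr <- split(segs, segs$chromosome)
  chroms <- build$chromosomes

  bp10mb <- numeric(0)
  bparm <- stats::setNames(numeric(2L * nrow(chroms)),
                           paste0(rep(chroms$chromosome, each = 2), c("_p", "_q")))
  cncp <- numeric(0)

  for (chr in names(by_chr)) {
    x <- by_chr[[chr]]
    len <- chroms$length[chroms$chromosome == chr]
    p_end <- chroms$p_end[chroms$chromosome == chr]
    nwin <- ceiling(len / 1e7)
    junc <- if (nrow(x) > 1) x$end[-nrow(x)] else numeric(0)
    bp10mb <- c(bp10mb, tabulate(ceiling(junc / 1e7), nbins = nwin))
    bparm[paste0(chr, "_p")] <- sum(junc <= p_end)
    bparm[paste0(chr, "_q")] <- sum(junc > p_end)
    if (nrow(x) > 1) cncp <- c(cncp, abs(diff(x$segVal)))
  }

  list(
    BP10MB = bp10mb,
    BPArm = unname(bparm),
    CN = segs$segVal,
    CNCP = cncp,
    OsCN = oscillation_chains(segs),
    SS = log10(segs$end - segs$start + 1),
    NC50 = nc50(segs, baseline = baseline),
    BoChr = bochr(segs, baseline = baseline)
  )
}

#' Oscillating copy number chain lengths
#'
#' Traverses the segments of each chromosome in order. From the third
#' segment onward a counter increments while the current copy number equals
#' the copy number two segments back and differs from the immediately
#' preceding one; when the condition breaks the counter value (possibly 0)
#' is emitted and reset, and a chain still open at the chromosome end is
#' emitted as well. Chromosomes with fewer than three segments contribute
#' nothing.
#'
#' @inheritParams compute_features
#' @return Integer vector of chain lengths, concatenated over chromosomes.
#' @export
oscillation_chains <- function(segs) {
  segs <- data.table::as.data.table(segs)
  data.table::setorder(segs, chromosome, start)
  out <- integer(0)
  for (cn in split(segs$segVal, segs$chromosome)) {
    n <- length(cn)
    if (n < 3L) next
    count <- 0L
    open <- FALSE
    for (i in 3:n) {
      if (cn[i] == cn[i - 2L] && cn[i] != cn[i - 1L]) {
        count <- count + 1L
        open <- TRUE
      } else {
        out <- c(out, count)
        count <- 0L
        open <- FALSE
      }
    }
    if (open) out <- c(out, count)
  }
  out
}

#' NC50: chromosome concentration of copy number alterations
#'
#' The minimal number of chromosomes that jointly carry at least half of the
#' sample's altered segments (copy number different from the baseline).
#' Returns 0 for a fully unaltered profile.
#'
#' @inheritParams compute_features
#' @return A single non-negative integer.
#' @export
nc50 <- function(segs, baseline = 2) {
  altered <- table(segs$chromosome[segs$segVal != baseline])
  total <- sum(altered)
  if (total == 0) return(0L)
  a <- sort(as.integer(altered), decreasing = TRUE)
  which(cumsum(a) >= total / 2)[1L]
}

#' BoChr: per-chromosome burden of copy number alterations
#'
#' One observation per altered segment (copy number different from the
#' baseline); the value is the chromosome index, chr1-chr22 mapping to 1-22
#' and chrX to 23.
#'
#' @inheritParams compute_features
#' @return Integer vector of chromosome indices, possibly empty.
#' @export
bochr <- function(segs, baseline = 2) {
  chrom_index(segs$chromosome[segs$segVal != baseline])
}
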