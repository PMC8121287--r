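#' Tandem duplication phenotype (TDP) score
#'
#' Summarises the abundance, chromosomal dispersion and total size of tandem
#' duplications in one profile. A TD is an amplified segment (copy number
#' above the baseline) whose size lies between `min_size` and `max_size`
#' (defaults 1 kb and 2 Mb, inclusive). Writing `TD_total` for the number of
#' TDs, `TD_obs`/`TD_exp` for the observed and expected TD count per
#' chromosome (the expectation apportions `TD_total` by chromosome length
#' share) and `L` for the total TD size in Mb, the score is
#'
#' \deqn{score = \frac{TD_{total}}{\sum_{chr} |TD_{obs} - TD_{exp}| + 1} \times L}
#'
#' so evenly dispersed, abundant, large TD loads score high. A profile with
#' no TDs scores 0.
#'
#' @param segs Normalised segments of a single sample.
#' @param build A [genome_build][load_genome_build()].
#' @param min_size,max_size TD size range in bp (inclusive).
#' @param baseline Neutral copy number; amplification means `segVal >
#'   baseline`.
#' @return A list of class `tdp_result`: `td_total`, `td_obs`, `td_exp`
#'   (per-chromosome), `L_mb`, `score`.
#' @examples
#' build <- load_genome_build("toy")
#' segs <- data.frame(sample = "S1", chromosome = "chr1",
#'                    start = c(1, 5e6 + 1, 6e6 + 1, 10e6 + 1, 11.5e6 + 1),
#'                    end = c(5e6, 6e6, 10e6, 11.5e6, 30e6),
#'                    segVal = c(2, 3, 2, 3, 2))
#' tdp_score(segs, build)$score  # (2 / 2.6) * 2.5
#' @export
tdp_score <- function(segs, build, min_size = 1e3, max_size = 2e6,
                      baseline = 2) {
  segs <- data.table::as.data.table(segs)
  width <- segs$end - segs$start + 1
  is_td <- segs$segVal > baseline & width >= min_size & width <= max_size
  chroms <- build$chromosomes
  td_obs <- stats::setNames(integer(nrow(chroms)), chroms$chromosome)
  obs <- table(segs$chromosome[is_td])
  td_obs[names(obs)] <- as.integer(obs)
  td_total <- sum(td_obs)
  td_exp <- td_total * chroms$length / sum(chroms$length)
  names(td_exp) <- chroms$chromosome
  L_mb <- sum(width[is_td]) / 1e6
  score <- if (td_total == 0) 0 else
    td_total / (sum(abs(td_obs - td_exp)) + 1) * L_mb
  structure(list(td_total = td_total, td_obs = td_obs, td_exp = td_exp,
                 L_mb = L_mb, score = score),
            class = "tdp_result")
}

#' Chromothripsis state score
#'
#' Counts, per chromosome, the consecutive segment triples whose absolute
#' copy numbers follow the oscillating 2-1-2 pattern (overlapping triples
#' each counted), and returns the sum over chromosomes of the squared
#' counts. High scores indicate chromosomes carrying long runs of one-copy
#' losses interspersed with disomic segments, the copy number footprint of
#' chromothripsis.
#'
#' @param segs Normalised single-sample segments with integer copy numbers.
#' @return A single non-negative number.
#' @examples
#' segs <- data.frame(sample = "S1", chromosome = "chr1",
#'                    start = c(1, 11, 21, 31, 41), end = c(10, 20, 30, 40, 50),
#'                    segVal = c(2, 1, 2, 1, 2))
#' chromothripsis_score(segs)  # two triples on one chromosome -> 2^2 = 4
#' @export
chromothripsis_score <- function(segs) {
  segs <- data.table::as.data.table(segs)
  data.table::setorder(segs, chromosome, start)
  per_chr <- vapply(split(segs$segVal, segs$chromosome), function(cn) {
    n <- length(cn)
    if (n < 3L) return(0)
    sum(cn[1:(n - 2)] == 2 & cn[2:(n - 1)] == 1 & cn[3:n] == 2)
  }, numeric(1))
  sum(per_chr^2)
}

#' Per-sample score table for a cohort
#'
#' @param segs Normalised multi-sample segment table.
#' @param build A genome build.
#' @param ... Passed to [tdp_score()].
#' @return `data.table` with columns `sample`, `td_total`, `L_mb`,
#'   `tdp_score`, `chromothripsis_score`.
#' @export
score_cohort <- function(segs, build, ...) {
  segs <- data.table::as.data.table(segs)
  out <- lapply(unique(segs$sample), function(s) {
    prof <- segs[segs$sample == s]
    td <- tdp_score(prof, build, ...)
    data.table::data.table(sample = s, td_total = td$td_total,
                           L_mb = td$L_mb, tdp_score = td$score,
                           chromothripsis_score = chromothripsis_score(prof))
  })
  data.table::rbindlist(out)
}
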