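# Synthetic cohort generator: segmented absolute copy number profiles with
# planted mutational processes, used to exercise the full discovery /
# fitting / scoring stack without any external data.

#' Processes available to the simulator
#' @return Character vector of the five planted process names.
#' @export
sim_processes <- function() {
  c("FOCAL_AMP", "TANDEM_DUP", "WGD", "CHROMOTHRIPSIS", "QUIET")
}

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic cohort: the genome, cohort
#' size, the Dirichlet prior over per-sample process weights, and the event
#' rates of each planted process. Defaults: 200 samples on hg38, a sparse
#' Dirichlet (concentration 0.3 per process, so most tumors are dominated by
#' one or two processes), focal amplification rate 80 events (10-100 kb,
#' copy number 9-12), tandem duplication rate 120 events (100 kb-2 Mb, one
#' copy above baseline), whole-genome duplication as a Bernoulli ploidy
#' shift to 4, chromothripsis as a Bernoulli catastrophic event shattering
#' 1 + Poisson(2) chromosomes into 30-100 alternating 2/1 segments, and a
#' copy-number-quiet process contributing nothing.
#'
#' @param build Genome build (default hg38).
#' @param n_samples Cohort size.
#' @param concentration Dirichlet concentration per process (named, length
#'   5).
#' @param rates Named list of event-rate parameters; see Details in the
#'   package vignette.
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(build = load_genome_build("hg38"), n_samples = 200,
                       concentration = stats::setNames(rep(0.3, 5),
                                                       sim_processes()),
                       rates = list(focal_amp = 80, tandem_dup = 120,
                                    ct_extra_chroms = 2,
                                    focal_size = c(1e4, 1e5),
                                    focal_cn = c(9, 12),
                                    td_size = c(1e5, 2e6),
                                    ct_segments = c(30, 100)),
                       seed = 1L) {
  stopifnot(n_samples >= 1, all(concentration > 0),
            identical(sort(names(concentration)), sort(sim_processes())))
  structure(list(build = build, n_samples = as.integer(n_samples),
                 concentration = concentration[sim_processes()],
                 rates = rates, seed = as.integer(seed)),
            class = "sim_config")
}

# Sample a chromosome proportional to length, then a start position such
# that [start, start+size-1] fits; reject overlaps with already-placed
# event intervals; up to `tries` attempts.
place_event <- function(size, chroms, occupied, tries = 10L) {
  for (t in seq_len(tries)) {
    ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
    len <- chroms$length[ci]
    if (len <= size) next
    start <- sample.int(len - size, 1L)
    end <- start + size - 1
    occ <- occupied[[chroms$chromosome[ci]]]
    if (!is.null(occ) && nrow(occ) &&
        any(start <= occ$end & end >= occ$start)) next
    return(list(chromosome = chroms$chromosome[ci], start = start, end = end))
  }
  NULL
}

#' Simulate one copy number profile
#'
#' Starts from a diploid genome and applies events drawn from the planted
#' processes in proportion to the mixture weights (see [sim_config()]).
#' Consumes the current RNG state; seed upstream (as [simulate_cohort()]
#' does) for reproducibility.
#'
#' @param mix Named non-negative process weights summing to 1.
#' @param config A [sim_config()].
#' @param sample_id Sample identifier for the output rows.
#' @return Normalised segment `data.table` covering the genome.
#' @export
simulate_profile <- function(mix, config, sample_id = "S1") {
  stopifnot(abs(sum(mix) - 1) < 1e-8, all(mix >= 0))
  mix <- mix[sim_processes()]
  chroms <- config$build$chromosomes
  r <- config$rates

  baseline <- if (stats::runif(1) < mix[["WGD"]]) 4L else 2L
  occupied <- list()
  events <- list()
  add_event <- function(chromosome, start, end, cn) {
    ev <- data.table::data.table(chromosome = chromosome, start = start,
                                 end = end, segVal = cn)
    events[[length(events) + 1L]] <<- ev
    occ <- occupied[[chromosome]]
    occupied[[chromosome]] <<- if (is.null(occ)) ev[, .(start, end)]
                               else rbind(occ, ev[, .(start, end)])
  }

  # chromothripsis: catastrophic event shattering whole chromosomes into
  # alternating 2/1 runs
  if (stats::runif(1) < mix[["CHROMOTHRIPSIS"]]) {
    n_ct <- 1L + stats::rpois(1L, r$ct_extra_chroms)
    n_ct <- min(n_ct, nrow(chroms))
    cts <- sample.int(nrow(chroms), n_ct, prob = chroms$length)
    for (ci in cts) {
      len <- chroms$length[ci]
      m <- sample(seq(r$ct_segments[1], r$ct_segments[2]), 1L)
      cuts <- sort(sample.int(len - 1L, m - 1L))
      starts <- c(1, cuts + 1)
      ends <- c(cuts, len)
      cns <- rep_len(c(2L, 1L), m)
      for (j in seq_len(m)) {
        add_event(chroms$chromosome[ci], starts[j], ends[j], cns[j])
      }
    }
  }

  n_fa <- stats::rpois(1L, mix[["FOCAL_AMP"]] * r$focal_amp)
  for (i in seq_len(n_fa)) {
    size <- round(stats::runif(1, r$focal_size[1], r$focal_size[2]))
    pos <- place_event(size, chroms, occupied)
    if (is.null(pos)) { warning("focal amplification skipped: no placement"); next }
    add_event(pos$chromosome, pos$start, pos$end,
              sample(seq(r$focal_cn[1], r$focal_cn[2]), 1L))
  }

  n_td <- stats::rpois(1L, mix[["TANDEM_DUP"]] * r$tandem_dup)
  for (i in seq_len(n_td)) {
    size <- round(stats::runif(1, r$td_size[1], r$td_size[2]))
    pos <- place_event(size, chroms, occupied)
    if (is.null(pos)) { warning("tandem duplication skipped: no placement"); next }
    add_event(pos$chromosome, pos$start, pos$end, baseline + 1L)
  }

  ev <- if (length(events)) data.table::rbindlist(events) else
    data.table::data.table(chromosome = character(0), start = numeric(0),
                           end = numeric(0), segVal = integer(0))
  segs <- fill_baseline(ev, chroms, baseline)
  segs[, sample := sample_id]
  data.table::setcolorder(segs, c("sample", "chromosome", "start", "end",
                                  "segVal"))
  normalize_profile(segs)
}

# Complete event intervals into a full-coverage profile by filling the
# remaining genome with the baseline copy number.
fill_baseline <- function(events, chroms, baseline) {
  out <- list()
  for (ci in seq_len(nrow(chroms))) {
    chr <- chroms$chromosome[ci]
    len <- chroms$length[ci]
    ev <- events[events$chromosome == chr]
    data.table::setorder(ev, start)
    rows <- list()
    cursor <- 1
    for (j in seq_len(nrow(ev))) {
      if (ev$start[j] > cursor) {
        rows[[length(rows) + 1L]] <- list(chr, cursor, ev$start[j] - 1,
                                          baseline)
      }
      rows[[length(rows) + 1L]] <- list(chr, ev$start[j], ev$end[j],
                                        ev$segVal[j])
      cursor <- ev$end[j] + 1
    }
    if (cursor <= len) {
      rows[[length(rows) + 1L]] <- list(chr, cursor, len, baseline)
    }
    out[[ci]] <- data.table::rbindlist(rows)
  }
  res <- data.table::rbindlist(out)
  data.table::setnames(res, c("chromosome", "start", "end", "segVal"))
  res
}

#' Simulate a cohort with planted processes
#'
#' Draws per-sample process weights from a Dirichlet prior, simulates each
#' profile independently, and records the ground truth: the planted weight
#' matrix and each process's expected 80-component catalog profile (the
#' normalised mean catalog of `n_reference` pure-process samples generated
#' under the same configuration).
#'
#' @param config A [sim_config()].
#' @param scheme Component scheme used for the truth profiles.
#' @param n_reference Pure samples per process used to estimate the truth
#'   profiles.
#' @return List with `segments` (all samples, generic seg columns), `truth`
#'   (list: `weights`, `process_catalogs` with processes as rows), and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), scheme = default_scheme(),
                            n_reference = 20) {
  procs <- sim_processes()
  with_seed(config$seed, {
    a <- config$concentration
    g <- matrix(stats::rgamma(config$n_samples * length(a),
                              shape = rep(a, each = config$n_samples)),
                nrow = config$n_samples)
    weights <- g / rowSums(g)
    dimnames(weights) <- list(sprintf("S%03d", seq_len(config$n_samples)),
                              procs)
    profiles <- lapply(seq_len(config$n_samples), function(i) {
      simulate_profile(weights[i, ], config, sample_id = rownames(weights)[i])
    })
    segments <- data.table::rbindlist(profiles)

    process_catalogs <- t(vapply(procs, function(p) {
      mix <- stats::setNames(as.numeric(procs == p), procs)
      pure <- data.table::rbindlist(lapply(seq_len(n_reference), function(i) {
        simulate_profile(mix, config, sample_id = sprintf("%s_%02d", p, i))
      }))
      cat_mat <- tally_cn_catalog(pure, config$build, scheme)
      prof <- colMeans(cat_mat)
      prof / sum(prof)
    }, numeric(nrow(scheme))))
    colnames(process_catalogs) <- scheme$label

    list(segments = segments,
         truth = list(weights = weights, process_catalogs = process_catalogs),
         config = config)
  })
}
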