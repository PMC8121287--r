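# Independent brute-force oracles. These deliberately re-derive every
# quantity by naive enumeration, sharing no code with the package internals.

toy_build <- function() load_genome_build("toy")

# one segment row
seg_row <- function(sample, chromosome, start, end, segVal) {
  data.frame(sample = sample, chromosome = chromosome, start = start,
             end = end, segVal = segVal, stringsAsFactors = FALSE)
}

# Brute-force recomputation of all 8 features for one sample.
oracle_features <- function(segs, build, baseline = 2) {
  segs <- segs[order(segs$chromosome, segs$start), ]
  chroms <- build$chromosomes
  obs <- list(BP10MB = numeric(0), BPArm = numeric(0), CN = numeric(0),
              CNCP = numeric(0), OsCN = numeric(0), SS = numeric(0),
              NC50 = numeric(0), BoChr = numeric(0))

  for (chr in unique(segs$chromosome)) {
    x <- segs[segs$chromosome == chr, ]
    len <- chroms$length[chroms$chromosome == chr]
    junctions <- if (nrow(x) > 1) x$end[seq_len(nrow(x) - 1)] else numeric(0)
    # windows [1,1e7], (1e7,2e7], ... enumerated one by one
    w <- 1
    while ((w - 1) * 1e7 < len) {
      lo <- (w - 1) * 1e7
      hi <- w * 1e7
      obs$BP10MB <- c(obs$BP10MB, sum(junctions > lo & junctions <= hi))
      w <- w + 1
    }
    for (j in seq_along(junctions)) {
      obs$CNCP <- c(obs$CNCP, abs(x$segVal[j + 1] - x$segVal[j]))
    }
  }
  # arms over every build chromosome
  for (i in seq_len(nrow(chroms))) {
    chr <- chroms$chromosome[i]
    x <- segs[segs$chromosome == chr, ]
    junctions <- if (nrow(x) > 1) x$end[seq_len(nrow(x) - 1)] else numeric(0)
    obs$BPArm <- c(obs$BPArm, sum(junctions <= chroms$p_end[i]),
                   sum(junctions > chroms$p_end[i]))
  }
  obs$CN <- segs$segVal
  obs$SS <- log10(segs$end - segs$start + 1)
  # oscillating chains by explicit per-position scan
  for (chr in unique(segs$chromosome)) {
    cn <- segs$segVal[segs$chromosome == chr]
    if (length(cn) < 3) next
    count <- 0
    emitted_here <- FALSE
    for (i in 3:length(cn)) {
      if (cn[i] == cn[i - 2] && cn[i] != cn[i - 1]) {
        count <- count + 1
        emitted_here <- FALSE
      } else {
        obs$OsCN <- c(obs$OsCN, count)
        count <- 0
        emitted_here <- TRUE
      }
    }
    if (!emitted_here) obs$OsCN <- c(obs$OsCN, count)
  }
  # NC50 by exhaustive subset search
  altered <- segs[segs$segVal != baseline, ]
  total <- nrow(altered)
  if (total == 0) {
    obs$NC50 <- 0
  } else {
    counts <- table(altered$chromosome)
    found <- NA
    for (k in seq_along(counts)) {
      subsets <- utils::combn(length(counts), k)
      for (col in seq_len(ncol(subsets))) {
        if (sum(counts[subsets[, col]]) >= total / 2) { found <- k; break }
      }
      if (!is.na(found)) break
    }
    obs$NC50 <- found
  }
  chr_index <- function(chr) {
    x <- sub("chr", "", chr)
    if (x == "X") 23 else as.numeric(x)
  }
  obs$BoChr <- vapply(altered$chromosome, chr_index, numeric(1),
                      USE.NAMES = FALSE)
  obs
}

# Naive per-observation tally against the scheme definition.
oracle_tally_row <- function(feats, scheme) {
  counts <- setNames(numeric(nrow(scheme)), scheme$label)
  for (f in names(feats)) {
    for (v in feats[[f]]) {
      hit <- NULL
      for (i in which(scheme$feature == f)) {
        ok <- if (scheme$kind[i] == "discrete") v == scheme$lower[i]
              else v > scheme$lower[i] & v <= scheme$upper[i]
        if (ok) { hit <- i; break }
      }
      stopifnot(!is.null(hit))
      counts[hit] <- counts[hit] + 1
    }
  }
  counts
}

# Sliding-window 2-1-2 triple count, squared per chromosome.
oracle_chromothripsis <- function(segs) {
  segs <- segs[order(segs$chromosome, segs$start), ]
  total <- 0
  for (chr in unique(segs$chromosome)) {
    cn <- segs$segVal[segs$chromosome == chr]
    n_triples <- 0
    if (length(cn) >= 3) {
      for (i in seq_len(length(cn) - 2)) {
        if (cn[i] == 2 && cn[i + 1] == 1 && cn[i + 2] == 2) {
          n_triples <- n_triples + 1
        }
      }
    }
    total <- total + n_triples^2
  }
  total
}

# Random full-coverage profile on the toy build (occasionally with gaps).
random_toy_profile <- function(sample_id = "S1", max_segments = 10,
                               gap_prob = 0.1) {
  build <- toy_build()
  rows <- list()
  for (i in seq_len(nrow(build$chromosomes))) {
    chr <- build$chromosomes$chromosome[i]
    len <- build$chromosomes$length[i]
    n <- sample.int(max_segments, 1)
    cuts <- sort(sample.int(len - 1, n - 1))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, len)
    cn <- sample(0:12, n, replace = TRUE)
    keep <- stats::runif(n) >= gap_prob
    keep[1] <- TRUE
    rows[[i]] <- data.frame(sample = sample_id, chromosome = chr,
                            start = starts[keep], end = ends[keep],
                            segVal = cn[keep])
  }
  normalize_profile(do.call(rbind, rows))
}
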