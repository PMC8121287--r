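#' @keywords internal
"_PACKAGE"

#' @import data.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cosine similarity between two vectors; zero vectors map to 0 by convention.
cosine_vec <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# chr1..chr22 -> 1..22, chrX -> 23 (chrY is never tallied)
chrom_index <- function(chromosome) {
  x <- sub("^chr", "", chromosome)
  idx <- suppressWarnings(as.integer(x))
  idx[x == "X"] <- 23L
  idx
}
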