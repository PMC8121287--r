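#' Associate signature exposures with sample covariates
#'
#' For every signature x covariate pair: continuous covariates (including
#' ordinal ones) are tested by two-sided Pearson correlation; binary
#' covariates split the cohort into two groups compared by a two-sided
#' Mann-Whitney U test (exact for small tie-free groups, normal
#' approximation with tie correction otherwise), with the difference of
#' group means as the effect. Missing values are dropped pairwise.
#' Benjamini-Hochberg adjustment is applied across all testable rows of one
#' call.
#'
#' @param exposures Samples x signatures matrix (relative or absolute);
#'   rownames are sample identifiers.
#' @param covariates `data.frame` with a `sample` column plus one column per
#'   covariate.
#' @param kinds Named character vector mapping covariate names to
#'   `"continuous"` or `"binary"`. Unnamed covariates default to
#'   `"continuous"` for numeric columns with more than two distinct values
#'   and `"binary"` otherwise.
#' @return `data.frame` with columns `signature`, `covariate`, `kind`,
#'   `effect` (Pearson r, or group mean difference second level minus
#'   first), `p_value`, `fdr`, `n_used`. Rows with fewer than 3 usable pairs
#'   or an empty group get `NA` effect and p-value (with a warning) and are
#'   excluded from the FDR adjustment.
#' @export
associate_exposures <- function(exposures, covariates, kinds = NULL) {
  exposures <- as.matrix(exposures)
  covariates <- as.data.frame(covariates)
  if (!"sample" %in% names(covariates)) {
    stop("covariate table must have a 'sample' column", call. = FALSE)
  }
  shared <- intersect(rownames(exposures), covariates$sample)
  if (!length(shared)) stop("no shared sample identifiers", call. = FALSE)
  exposures <- exposures[shared, , drop = FALSE]
  covariates <- covariates[match(shared, covariates$sample), , drop = FALSE]
  cov_names <- setdiff(names(covariates), "sample")

  kind_of <- function(nm) {
    if (!is.null(kinds) && nm %in% names(kinds)) return(kinds[[nm]])
    x <- covariates[[nm]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) "continuous"
    else "binary"
  }

  rows <- list()
  for (sig in colnames(exposures)) {
    for (nm in cov_names) {
      kind <- kind_of(nm)
      x <- exposures[, sig]
      y <- covariates[[nm]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      effect <- p <- NA_real_
      if (kind == "continuous") {
        if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(as.numeric(y)) > 0) {
          ct <- stats::cor.test(x, as.numeric(y), method = "pearson")
          effect <- unname(ct$estimate)
          p <- ct$p.value
        } else {
          warning("covariate ", nm, " x ", sig,
                  ": too few usable pairs or zero variance; row excluded from FDR")
        }
      } else {
        g <- factor(y)
        if (nlevels(g) == 2 && all(table(g) > 0) && length(x) >= 3) {
          wt <- suppressWarnings(stats::wilcox.test(x[g == levels(g)[1]],
                                                    x[g == levels(g)[2]]))
          effect <- mean(x[g == levels(g)[2]]) - mean(x[g == levels(g)[1]])
          p <- wt$p.value
        } else {
          warning("binary covariate ", nm, " x ", sig,
                  ": empty group or too few pairs; row excluded from FDR")
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, covariate = nm, kind = kind, effect = effect,
        p_value = p, n_used = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  usable <- !is.na(out$p_value)
  out$fdr[usable] <- stats::p.adjust(out$p_value[usable], method = "BH")
  out[, c("signature", "covariate", "kind", "effect", "p_value", "fdr",
          "n_used")]
}
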