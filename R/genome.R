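#' Load a packaged genome build
#'
#' A genome build carries the chromosome lengths and the p-arm boundary
#' (centromere position) used for arm-level breakpoint counting. Only the 23
#' tallied chromosomes (1-22 and X) are included; chromosome Y is never
#' tallied. The `"toy"` build is a small 2-chromosome genome (chr1 30 Mb with
#' arm boundary at 15 Mb, chr2 20 Mb with arm boundary at 10 Mb) used in all
#' worked examples and tests.
#'
#' @param name Build identifier, one of `"hg38"`, `"hg19"` or `"toy"`.
#' @return An object of class `genome_build`: a list with elements `name` and
#'   `chromosomes` (a `data.table` with columns `chromosome`, `length`,
#'   `p_end`; the p arm is `[1, p_end]` and the q arm `(p_end, length]`).
#' @examples
#' build <- load_genome_build("toy")
#' build$chromosomes
#' @export
load_genome_build <- function(name) {
  available <- c("hg38", "hg19", "toy")
  if (length(name) != 1L || !name %in% available) {
    stop("unknown genome build ", sQuote(name), "; available builds: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0("genome_", name, ".tsv"),
                      package = "cnsig", mustWork = TRUE)
  chromosomes <- data.table::fread(path, sep = "\t",
                                   colClasses = list(character = "chromosome",
                                                     numeric = c("length",
                                                                 "p_end")))
  stopifnot(all(chromosomes$length > 0),
            all(chromosomes$p_end > 0 & chromosomes$p_end < chromosomes$length))
  structure(list(name = name, chromosomes = chromosomes),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build>", x$name, "-", nrow(x$chromosomes),
      "tallied chromosomes,", sum(x$chromosomes$length), "bp\n")
  invisible(x)
}

genome_length <- function(build) sum(build$chromosomes$length)
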