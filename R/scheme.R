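#' The default 80-component copy number classification scheme
#'
#' Each of the 8 copy number features is partitioned into ordered, mutually
#' exclusive, jointly exhaustive components; feature observations are counted
#' into these components to build the catalog matrix. The default scheme has
#' 7 BP10MB + 11 BPArm + 10 CN + 7 CNCP + 5 OsCN + 13 SS + 4 NC50 + 23 BoChr
#' = 80 components. Most components are anchored at discrete integer values
#' (e.g. `CN[2]` = segments with absolute copy number exactly 2); the rest
#' are half-open ranges `(lower, upper]` (e.g. the log10 segment-size bins).
#' The scheme ships as a plain TSV so alternative component boundaries can
#' be dropped in without code changes.
#'
#' @param path Optional path to a scheme TSV (columns `feature`, `label`,
#'   `lower`, `upper`, `kind`); defaults to the packaged 80-component scheme.
#' @return A `data.table` of class `component_scheme`.
#' @examples
#' scheme <- default_scheme()
#' nrow(scheme)            # 80
#' table(scheme$feature)
#' @export
default_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cn_components_80.tsv", package = "cnsig",
                        mustWork = TRUE)
  }
  scheme <- data.table::fread(path, sep = "\t")
  stopifnot(identical(names(scheme)[1:5],
                      c("feature", "label", "lower", "upper", "kind")),
            !anyDuplicated(scheme$label))
  data.table::setattr(scheme, "class",
                      c("component_scheme", class(scheme)))
  scheme
}

# Vectorised classification of observations of one feature into component
# indices (relative to that feature's block). Bins are contiguous and
# ordered, so the index is found from the ordered vector of upper bounds.
classify_feature_values <- function(values, block) {
  uppers <- block$upper
  idx <- findInterval(values, uppers, left.open = TRUE) + 1L
  bad <- idx > nrow(block) |
    (block$kind[pmin(idx, nrow(block))] == "discrete" &
       values != block$lower[pmin(idx, nrow(block))])
  if (any(bad)) {
    stop("value(s) outside the ", block$feature[1L], " component scheme: ",
         paste(utils::head(values[bad], 3), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Classify one feature observation into its component
#'
#' @param feature Feature name, e.g. `"CN"`.
#' @param value Observation value.
#' @param scheme A [component_scheme][default_scheme()].
#' @return The matching component label.
#' @examples
#' classify_observation("CN", 2)    # "CN[2]"
#' classify_observation("CN", 12)   # "CN[>8]"
#' @export
classify_observation <- function(feature, value, scheme = default_scheme()) {
  rows <- which(scheme$feature == feature)
  block <- scheme[rows, ]
  if (!nrow(block)) stop("unknown feature ", sQuote(feature), call. = FALSE)
  block$label[classify_feature_values(value, block)]
}

#' The 96 trinucleotide substitution classes
#'
#' Labels in COSMIC order: the six pyrimidine-referenced substitution
#' subtypes (C>A, C>G, C>T, T>A, T>C, T>G) each expanded by the four 5' and
#' four 3' flanking bases, e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))
  }))
}
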