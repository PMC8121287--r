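#' Build the sample-by-component copy number catalog
#'
#' For each sample, computes the 8 copy number feature distributions with
#' [compute_features()] and counts every observation into its component of
#' the classification scheme. The resulting non-negative integer matrix
#' (samples x 80 components in scheme order) is the input to signature
#' discovery and fitting.
#'
#' @param segs Normalised multi-sample segment table.
#' @param build A [genome_build][load_genome_build()].
#' @param scheme A [component_scheme][default_scheme()].
#' @param baseline Neutral copy number (default 2).
#' @return Integer matrix with samples as rows and component labels as
#'   columns; the scheme is attached as attribute `"scheme"`.
#' @examples
#' segs <- data.frame(sample = "S1", chromosome = "chr1",
#'                    start = 1, end = 30e6, segVal = 2)
#' tally_cn_catalog(segs, load_genome_build("toy"))["S1", "CN[2]"]
#' @export
tally_cn_catalog <- function(segs, build, scheme = default_scheme(),
                             baseline = 2) {
  segs <- data.table::as.data.table(segs)
  if (nrow(segs) == 0L) stop("no segments supplied", call. = FALSE)
  samples <- unique(segs$sample)
  blocks <- split(seq_len(nrow(scheme)), scheme$feature)
  mat <- matrix(0L, nrow = length(samples), ncol = nrow(scheme),
                dimnames = list(samples, scheme$label))
  for (s in samples) {
    prof <- segs[segs$sample == s]
    feats <- compute_features(prof, build, baseline = baseline)
    for (f in names(feats)) {
      block <- scheme[blocks[[f]], ]
      if (!length(feats[[f]])) next
      idx <- classify_feature_values(feats[[f]], block)
      counts <- tabulate(idx, nbins = nrow(block))
      mat[s, blocks[[f]]] <- mat[s, blocks[[f]]] + counts
    }
  }
  attr(mat, "scheme") <- scheme
  mat
}

#' Build the SBS-96 mutation catalog
#'
#' Classifies single-base substitutions into the 96 trinucleotide classes
#' (six pyrimidine-referenced substitution subtypes times the 5' and 3'
#' flanking bases). Substitutions reported on the purine strand are
#' reverse-complemented (base and flanks) before classification.
#'
#' @param mutations Table with columns `sample`, `chromosome`, `position`,
#'   `ref`, `alt` (MAF-style column names `Tumor_Sample_Barcode`,
#'   `Chromosome`, `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`
#'   are also accepted).
#' @param reference Path to a FASTA file, or a
#'   [Biostrings::DNAStringSet-class] whose names include the mutation
#'   chromosomes.
#' @return Integer matrix, samples x 96 components in COSMIC order.
#' @export
tally_sbs_catalog <- function(mutations, reference) {
  mut <- data.table::as.data.table(mutations)
  aliases <- c(sample = "Tumor_Sample_Barcode", chromosome = "Chromosome",
               position = "Start_Position", ref = "Reference_Allele",
               alt = "Tumor_Seq_Allele2")
  for (nm in names(aliases)) {
    if (!nm %in% names(mut) && aliases[[nm]] %in% names(mut)) {
      data.table::setnames(mut, aliases[[nm]], nm)
    }
  }
  need <- c("sample", "chromosome", "position", "ref", "alt")
  missing_cols <- setdiff(need, names(mut))
  if (length(missing_cols)) {
    stop("missing required mutation column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  names(reference) <- sub("\\s.*$", "", names(reference))

  bases <- c("A", "C", "G", "T")
  snv <- mut$ref %in% bases & mut$alt %in% bases
  if (any(!snv)) {
    warning("skipped ", sum(!snv), " non-SNV record(s)")
    mut <- mut[snv]
  }

  samples <- unique(mut$sample)
  labels <- sbs96_labels()
  mat <- matrix(0L, nrow = length(samples), ncol = 96,
                dimnames = list(samples, labels))
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  for (i in seq_len(nrow(mut))) {
    chrom <- as.character(mut$chromosome[i])
    if (!chrom %in% names(reference)) {
      alt_name <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom)
                  else paste0("chr", chrom)
      if (!alt_name %in% names(reference)) {
        stop("chromosome ", sQuote(chrom), " not in reference", call. = FALSE)
      }
      chrom <- alt_name
    }
    pos <- as.integer(mut$position[i])
    seq_len_chr <- length(reference[[chrom]])
    if (pos < 2L || pos > seq_len_chr - 1L) {
      warning("record ", i, ": position too close to sequence end, skipped")
      next
    }
    ctx <- strsplit(as.character(Biostrings::subseq(
      reference[[chrom]], pos - 1L, pos + 1L)), "")[[1L]]
    if (ctx[2L] != mut$ref[i]) {
      stop(sprintf(
        "reference mismatch at record %d (%s:%d): table says %s, sequence has %s",
        i, chrom, pos, mut$ref[i], ctx[2L]), call. = FALSE)
    }
    if (any(!ctx %in% bases)) {
      warning("record ", i, ": ambiguous base in context, skipped")
      next
    }
    ref <- mut$ref[i]; alt <- mut$alt[i]; l <- ctx[1L]; r <- ctx[3L]
    if (ref %in% c("A", "G")) {  # purine strand: reverse complement
      tmp <- comp[[l]]; l <- comp[[r]]; r <- tmp
      ref <- comp[[ref]]; alt <- comp[[alt]]
    }
    lab <- paste0(l, "[", ref, ">", alt, "]", r)
    mat[as.character(mut$sample[i]), lab] <-
      mat[as.character(mut$sample[i]), lab] + 1L
  }
  mat
}

#' Export feature observations in long format
#'
#' @param segs Normalised multi-sample segment table.
#' @param build A genome build.
#' @param baseline Neutral copy number.
#' @return `data.table` with columns `sample`, `feature`, `value`.
#' @export
feature_observations <- function(segs, build, baseline = 2) {
  segs <- data.table::as.data.table(segs)
  out <- lapply(unique(segs$sample), function(s) {
    feats <- compute_features(segs[segs$sample == s], build,
                              baseline = baseline)
    data.table::rbindlist(lapply(names(feats), function(f) {
      if (!length(feats[[f]])) return(NULL)
      data.table::data.table(sample = s, feature = f, value = feats[[f]])
    }))
  })
  data.table::rbindlist(out)
}
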