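build <- load_genome_build("toy")
scheme <- default_scheme()

test_that("the default scheme has 80 components over 8 features", {
  expect_equal(nrow(scheme), 80)
  counts <- table(scheme$feature)
  expect_equal(length(counts), 8)
  expect_equal(as.integer(counts[c("BP10MB", "BPArm", "CN", "CNCP", "OsCN",
                                   "SS", "NC50", "BoChr")]),
               c(7, 11, 10, 7, 5, 13, 4, 23))
  expect_true(all(c("CN[2]", "CN[>8]", "CNCP[1]") %in% scheme$label))
  bochr <- scheme$label[scheme$feature == "BoChr"]
  expect_equal(bochr, sprintf("BoChr[%d]", 1:23))
})

test_that("observation classification hits the anchored components", {
  expect_equal(classify_observation("CN", 2, scheme), "CN[2]")
  expect_equal(classify_observation("CN", 12, scheme), "CN[>8]")
  expect_equal(classify_observation("SS", 7.0, scheme), "SS[6.5,7]")
  expect_equal(classify_observation("NC50", 0, scheme), "NC50[<=1]")
  expect_error(classify_observation("CN", 2.5, scheme), "outside")
  expect_error(classify_observation("XX", 1, scheme), "unknown feature")
})

test_that("a flat diploid profile tallies as expected", {
  prof <- rbind(seg_row("S1", "chr1", 1, 3e7, 2),
                seg_row("S1", "chr2", 1, 2e7, 2))
  cat_m <- tally_cn_catalog(prof, build, scheme)
  expect_equal(dim(cat_m), c(1, 80))
  expect_equal(unname(cat_m[1, "CN[2]"]), 2)
  expect_equal(unname(cat_m[1, "BP10MB[0]"]), 5)   # 3 + 2 windows
  expect_equal(unname(cat_m[1, "BPArm[0]"]), 4)
  expect_equal(unname(cat_m[1, "NC50[<=1]"]), 1)
  expect_equal(sum(cat_m[1, scheme$feature == "BoChr"]), 0)
})

test_that("catalog rows are invariant to input row permutation", {
  set.seed(21)
  prof <- random_toy_profile("A")
  shuffled <- prof[sample.int(nrow(prof)), ]
  shuffled$sample <- "B"
  both <- tally_cn_catalog(rbind(prof, normalize_profile(shuffled)), build)
  expect_equal(unname(both["A", ]), unname(both["B", ]))
})

test_that("tally conserves observation counts and matches the naive oracle", {
  set.seed(31)
  for (i in 1:100) {
    prof <- random_toy_profile()
    cat_m <- tally_cn_catalog(prof, build, scheme)
    feats <- compute_features(prof, build)
    for (f in names(feats)) {
      expect_equal(sum(cat_m[1, scheme$feature == f]), length(feats[[f]]),
                   info = paste("conservation", f))
    }
    expect_equal(unname(cat_m[1, ]),
                 unname(oracle_tally_row(feats, as.data.frame(scheme))))
  }
})

test_that("an empty segment table is rejected", {
  prof <- seg_row("S1", "chr1", 1, 3e7, 2)
  expect_error(tally_cn_catalog(prof[0, ], build), "no segments")
})

write_test_fasta <- function() {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", "AACAATCTTG", ">chr2", "ACGTNACGTA"), path)
  path
}

test_that("SBS-96 catalog has COSMIC structure", {
  labels <- sbs96_labels()
  expect_length(labels, 96)
  subs <- unique(gsub(".*\\[(.*)\\].*", "\\1", labels))
  expect_equal(subs, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
})

test_that("SBS classification uses pyrimidine context with reverse complement", {
  fa <- write_test_fasta()
  on.exit(unlink(fa))
  # chr1 = AACAATCTTG: C at pos 3 (ctx ACA), T at 7 (ctx TCT -> as is),
  # G at 10 unusable (sequence end)
  mut <- data.frame(sample = c("S1", "S1", "S1"),
                    chromosome = "chr1",
                    position = c(3, 6, 7),
                    ref = c("C", "T", "C"),
                    alt = c("T", "A", "A"))
  # position 6 is T (ctx ATC); position 7 is actually C (ctx TCT)
  cat_m <- tally_sbs_catalog(mut, fa)
  expect_equal(dim(cat_m), c(1, 96))
  expect_equal(unname(cat_m[1, "A[C>T]A"]), 1)
  expect_equal(unname(cat_m[1, "A[T>A]C"]), 1)
  expect_equal(unname(cat_m[1, "T[C>A]T"]), 1)
  expect_equal(sum(cat_m), 3)
})

test_that("purine records are reverse complemented onto pyrimidine labels", {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(c(">chr1", "TTGTT"), fa)  # G at pos 3, context T G T
  mut <- data.frame(sample = "S1", chromosome = "chr1", position = 3,
                    ref = "G", alt = "A")
  cat_m <- tally_sbs_catalog(mut, fa)
  expect_equal(unname(cat_m[1, "A[C>T]A"]), 1)
  expect_equal(sum(cat_m), 1)
})

test_that("SBS tally errors on reference mismatch and skips ambiguous context", {
  fa <- write_test_fasta()
  on.exit(unlink(fa))
  bad <- data.frame(sample = "S1", chromosome = "chr1", position = 3,
                    ref = "G", alt = "A")
  expect_error(tally_sbs_catalog(bad, fa), "reference mismatch")
  # chr2 = ACGTNACGTA; position 4 (T) has context GTN
  amb <- data.frame(sample = "S1", chromosome = "chr2", position = 4,
                    ref = "T", alt = "C")
  expect_warning(cat_m <- tally_sbs_catalog(amb, fa), "ambiguous")
  expect_equal(sum(cat_m), 0)
})
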