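test_that("extract_window obeys the 115+45 geometry and labels", {
  g <- rand_dna(1000, seed = 3)
  w <- extract_window(g, tss = 500, gene = "g1", promoter_name = "g1p")
  expect_equal(nchar(w$sequence), 160L)
  lab <- position_labels(w)
  expect_equal(lab[1], -115L)
  expect_equal(lab[length(lab)], 44L)
  # label 0 is the TSS base itself
  expect_equal(substr(w$sequence, w$up + 1, w$up + 1),
               substr(g, 501, 501))
  # +1 display convention skips 0
  expect_equal(position_labels(w, "plus1")[c(115, 116)], c("-1", "+1"))
})

test_that("minus-strand windows are reverse-complemented genomic segments", {
  g <- "AAAACGTTTT"
  w <- extract_window(g, tss = 5, strand = "-", up = 2, down = 2)
  segment <- substr(g, 5, 8) # genomic [tss-down+1, tss+up] 0-based = 4..7
  expected <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(segment)))
  expect_equal(w$sequence, expected)
  # the TSS base in transcription orientation is the complement of g[tss]
  expect_equal(substr(w$sequence, w$up + 1, w$up + 1), "C") # comp of "G"
})

test_that("extract_window errors on out-of-bounds and bad alphabet", {
  g <- rand_dna(20, seed = 4)
  expect_error(extract_window(g, tss = 3, up = 5, down = 2), "bounds")
  expect_error(extract_window("ACGTNACGTNACGT", tss = 4, up = 2, down = 2),
               "non-ACGT")
})

test_that("mutate_promoter hits the configured rate and count", {
  w <- rand_window(11)
  lib <- mutate_promoter(w, mutagenesis_config(seed = 21))
  expect_length(lib$variants, 1501L)
  expect_equal(lib$variants[1], w$sequence)
  # mean mutations per mutated variant ~ Binomial(160, 0.1)
  mean_mut <- mean(rowSums(lib$masks[-1, ]))
  se <- sqrt(160 * 0.1 * 0.9 / 1500)
  expect_lt(abs(mean_mut - 16), 3 * se)
  # per-position frequency within 4 binomial SE everywhere
  freq <- colMeans(lib$masks[-1, ])
  expect_true(all(abs(freq - 0.1) < 4 * sqrt(0.1 * 0.9 / 1500)))
})

test_that("rate 0 is degenerate and masks reconstruct by string diff", {
  w <- rand_window(12, L = 40, up = 20)
  lib0 <- mutate_promoter(w, mutagenesis_config(rate = 0, n_variants = 5,
                                                seed = 2))
  expect_true(all(lib0$variants == w$sequence))
  expect_false(any(lib0$masks))

  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 50, seed = 5))
  recomputed <- t(vapply(lib$variants, function(v) {
    strsplit(v, "")[[1]] != strsplit(w$sequence, "")[[1]]
  }, logical(40)))
  dimnames(recomputed) <- NULL
  expect_identical(unname(lib$masks), recomputed)
})

test_that("mutated bases are uniform over the three alternatives", {
  w <- rand_window(13, L = 30, up = 15)
  lib <- mutate_promoter(w, mutagenesis_config(rate = 0.5, n_variants = 2000,
                                               seed = 9))
  # at position 1, tabulate substitute bases; chi-square uniformity
  wt <- substr(w$sequence, 1, 1)
  subs <- lib$seq_matrix[lib$masks[, 1], 1]
  tab <- table(factor(subs, levels = setdiff(c("A", "C", "G", "T"), wt)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("assemble_oligo concatenates and flags internal sites", {
  v <- rand_dna(160, seed = 31)
  oc <- assemble_oligo(v)
  expect_equal(nchar(oc$full_sequence), 160 + 2 * 20 + 2 * 6)
  expect_match(oc$full_sequence, paste0("ACTAGT", v, "GGGCCC"), fixed = TRUE)
  expect_length(oc$flags, 0)

  v2 <- paste0(substr(v, 1, 50), "ACTAGT", substr(v, 57, 160))
  oc2 <- assemble_oligo(v2)
  expect_true("internal_SpeI_site" %in% oc2$flags)
  expect_error(assemble_oligo(v, primer_fwd = ""), "primer")
})

test_that("assign_barcodes builds a unique, seeded, capacity-checked map", {
  w <- rand_window(14, L = 20, up = 10)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 1, seed = 3))
  m <- assign_barcodes(lib, barcodes_per_variant = 3L, seed = 5)
  expect_equal(nrow(m), 6L)
  expect_false(anyDuplicated(m$barcode) > 0)
  expect_equal(sort(unique(m$variant_id)), 1:2)
  expect_true(all(nchar(m$barcode) == 20L))
  expect_true(all(m$read_support >= 0))
  m2 <- assign_barcodes(lib, barcodes_per_variant = 3L, seed = 5)
  expect_identical(m$barcode, m2$barcode)
  expect_error(assign_barcodes(lib, barcodes_per_variant = 5L,
                               barcode_length = 2L),
               "capacity|exceeds")
})

test_that("barcode-count distributions with mass at zero behave", {
  w <- rand_window(15, L = 20, up = 10)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 9999,
                                               seed = 6))
  m <- assign_barcodes(lib, barcodes_per_variant = function(n) rpois(n, 1),
                       seed = 8)
  n_var <- length(lib$variants)
  zero_frac <- 1 - length(unique(m$variant_id)) / n_var
  p0 <- exp(-1)
  se <- sqrt(p0 * (1 - p0) / n_var)
  expect_lt(abs(zero_frac - p0), 3 * se)
})

test_that("library FASTA/TSV round trip is lossless", {
  w <- rand_window(16, L = 60, up = 40)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 25, seed = 4))
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  lib2 <- read_library(dir)
  expect_identical(lib2$variants, lib$variants)
  expect_identical(unname(lib2$masks), unname(lib$masks))
  expect_identical(lib2$promoter$sequence, lib$promoter$sequence)
  expect_identical(lib2$config$rate, lib$config$rate)
})
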