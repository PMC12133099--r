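test_that("mutation indicators mirror the masks and string diffs", {
  w <- rand_window(71, L = 30, up = 20)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 40, seed = 8))
  ind <- mutation_indicators(lib)
  expect_equal(dim(ind), c(30, 41))
  expect_false(any(ind[, 1])) # wild type
  # string-diff oracle
  wt <- strsplit(w$sequence, "")[[1]]
  for (v in c(2, 17, 41)) {
    expect_equal(ind[, v], strsplit(lib$variants[v], "")[[1]] != wt)
  }
})

test_that("MI is zero under exact independence and degenerate marginals", {
  lib <- two_variant_library()
  ind <- mutation_indicators(lib)
  # identical RNA/DNA ratio for every variant -> joint factorizes
  ct <- count_table(dna = c(10, 30), rna = c(20, 60))
  fp <- information_footprint(ct, ind, alpha = 0)
  expect_equal(fp$mi[1], 0, tolerance = 1e-14)
  # positions 2..4 are never mutated: degenerate marginal, MI 0
  expect_equal(fp$mi[2:4], rep(0, 3))
})

test_that("MI matches the frozen 2x2 entropy value", {
  lib <- two_variant_library()
  ct <- count_table(dna = c(10, 10), rna = c(10, 0))
  fp <- information_footprint(ct, lib, alpha = 0)
  # oracle: H(m) + H(s) - H(m,s) on (10,10,10,0) = 0.2516292
  expect_equal(fp$mi[1], oracle_mi_2x2(c(10, 10, 10, 0)),
               tolerance = 1e-12)
  expect_equal(fp$mi[1], 0.2516292, tolerance = 1e-6)
})

test_that("MI is bounded, DNA/RNA-symmetric and scale-invariant", {
  w <- rand_window(72, L = 25, up = 15)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 60, seed = 5))
  set.seed(31)
  ct <- count_table(dna = rpois(61, 40), rna = rpois(61, 40))
  fp <- information_footprint(ct, lib, alpha = 0)
  expect_true(all(fp$mi >= 0 & fp$mi <= 1))
  swapped <- count_table(dna = ct$rna, rna = ct$dna)
  expect_equal(information_footprint(swapped, lib, alpha = 0)$mi, fp$mi,
               tolerance = 1e-12)
  scaled <- count_table(dna = 7 * ct$dna, rna = 7 * ct$rna)
  expect_equal(information_footprint(scaled, lib, alpha = 0)$mi, fp$mi,
               tolerance = 1e-12)
})

test_that("expression shifts vanish for flat expression and at wt bases", {
  w <- rand_window(73, L = 20, up = 10)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 30, seed = 4))
  ct <- count_table(dna = rep(10, 31), rna = rep(10, 31))
  sh <- expression_shift_matrix(ct, lib, alpha = 0)
  expect_true(all(abs(sh) < 1e-12, na.rm = TRUE))
  wt <- strsplit(w$sequence, "")[[1]]
  set.seed(9)
  ct2 <- count_table(dna = rpois(31, 30) + 1, rna = rpois(31, 30) + 1)
  sh2 <- expression_shift_matrix(ct2, lib)
  expect_equal(sh2[cbind(1:20, match(wt, c("A", "C", "G", "T")))],
               rep(0, 20))
})

test_that("smoothing preserves constants and reproduces the kernel", {
  expect_equal(smooth_footprint(rep(2.5, 40), 3), rep(2.5, 40))
  # unit impulse deep in the interior: response equals the normalized
  # kernel (edge renormalization never triggers there)
  L <- 61L
  x <- numeric(L)
  x[31] <- 1
  sm <- smooth_footprint(x, 3)
  off <- -12:12
  kern <- exp(-off^2 / 18)
  kern <- kern / sum(kern)
  expect_equal(sm[31 + off], kern, tolerance = 1e-12)
  # random vector vs naive sliding-window oracle
  set.seed(5)
  y <- runif(30)
  naive <- vapply(1:30, function(i) {
    j <- max(1, i - 12):min(30, i + 12)
    w <- exp(-(j - i)^2 / 18)
    sum(w * y[j]) / sum(w)
  }, 0)
  expect_equal(smooth_footprint(y, 3), naive, tolerance = 1e-12)
})

test_that("footprint correlation behaves like Pearson r", {
  set.seed(6)
  a <- runif(50)
  b <- runif(50)
  expect_equal(footprint_correlation(a, a), 1)
  expect_equal(footprint_correlation(a, 3 - 2 * a), -1)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(footprint_correlation(a, b), manual, tolerance = 1e-12)
  expect_warning(r <- footprint_correlation(a, rep(1, 50)), "variance")
  expect_true(is.na(r))
})

test_that("a planted repressor site footprints with the right sign", {
  arch <- sim_repressor_promoter(3)
  fp <- simulate_footprint(arch, "repressed", seed = 30)
  gt <- ground_truth_sites(arch)
  site <- gt[gt$name == "repA", ]
  inside <- (site$start + 1):site$end
  hex <- c(81:86, 104:109) # informative RNAP hexamer positions
  outside <- setdiff(seq_along(fp$mi), c(inside, 81:115))
  expect_gt(mean(fp$mi[inside]) / mean(fp$mi[outside]), 3)
  # shift signs: up inside the repressor, down inside the RNAP hexamers
  mutant_mean <- function(i) {
    r <- fp$shift[i, ]
    mean(r[!is.na(r) & r != 0])
  }
  expect_gt(mean(vapply(inside, mutant_mean, 0) > 0), 0.9)
  expect_gt(mean(vapply(hex, mutant_mean, 0) < 0), 0.9)
})
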