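make_three_site_arch <- function(seed = 50) {
  w <- rand_window(seed, L = 60, up = 40)
  rnap <- site_matrix(w, start = 25, len = 10, penalty = 1.5)
  act <- site_matrix(w, start = 10, len = 8, penalty = 2)
  rep1 <- site_matrix(w, start = 40, len = 8, penalty = 2)
  architecture_spec(w, list(
    site_spec("RNAP", rnap, base_weight = 0.8, name = "rnap"),
    site_spec("activator", act, base_weight = 0.5, omega = 12,
              name = "actA"),
    site_spec("repressor", rep1, base_weight = 5, name = "repA")),
    condition_activity = list(on = c(actA = 1, repA = 1),
                              off = c(actA = 0.3, repA = 0)))
}

test_that("site_energy is additive over positions", {
  w <- rand_window(41, L = 20, up = 10)
  m <- site_matrix(w, start = 5, len = 5, penalty = 2)
  wt_sub <- substr(w$sequence, 6, 10)
  expect_equal(site_energy(m, wt_sub), 0)
  # one substitution at offset 3 costs exactly its entry
  sub <- strsplit(wt_sub, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), sub[3])[1]
  sub[3] <- alt
  expect_equal(site_energy(m, paste(sub, collapse = "")), 2)
  # random 5-mers against a per-position loop
  set.seed(7)
  for (k in 1:10) {
    s <- rand_dna(5)
    looked <- sum(vapply(1:5, function(j) {
      m$energies[j, substr(s, j, j)]
    }, 0))
    expect_equal(site_energy(m, s), looked)
  }
  expect_error(site_energy(m, "ACGT"), "length")
})

test_that("expression_rate matches closed forms in degenerate cases", {
  w <- rand_window(42, L = 30, up = 20)
  rnap <- site_matrix(w, start = 10, len = 6, penalty = 1)
  arch1 <- architecture_spec(w, list(
    site_spec("RNAP", rnap, base_weight = 1, name = "rnap")),
    condition_activity = list(c1 = c()))
  expect_equal(expression_rate(arch1, w$sequence, "c1"), 0.5)

  rep1 <- site_matrix(w, start = 20, len = 6, penalty = 2)
  arch2 <- architecture_spec(w, list(
    site_spec("RNAP", rnap, base_weight = 1, name = "rnap"),
    site_spec("repressor", rep1, base_weight = 50, name = "repA")),
    condition_activity = list(on = c(repA = 1), off = c(repA = 0)))
  # inactive repressor removes its states entirely
  expect_equal(expression_rate(arch2, w$sequence, "off"), 0.5)
  expect_lt(expression_rate(arch2, w$sequence, "on"), 0.02)
})

test_that("rates equal the exhaustive state-sum oracle on 3-site archs", {
  arch <- make_three_site_arch()
  set.seed(99)
  lib <- mutate_promoter(arch$promoter,
                         mutagenesis_config(n_variants = 10, rate = 0.15,
                                            seed = 77))
  for (cond in c("on", "off")) {
    got <- expression_rates(arch, lib, cond)
    want <- vapply(lib$variants, oracle_expression_rate, 0,
                   arch = arch, condition = cond, USE.NAMES = FALSE)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rates live in [0,1]; activity and omega act monotonically", {
  arch <- make_three_site_arch()
  lib <- mutate_promoter(arch$promoter,
                         mutagenesis_config(n_variants = 30, seed = 12))
  acts <- seq(0, 1, by = 0.25)
  prev <- NULL
  for (a in acts) {
    arch$condition_activity$scan <- c(actA = 0.5, repA = a)
    r <- expression_rates(arch, lib, "scan")
    expect_true(all(r >= 0 & r <= 1))
    if (!is.null(prev)) expect_true(all(r <= prev + 1e-12))
    prev <- r
  }
  # raising an activator's omega cannot lower the wild-type rate
  wt_rates <- vapply(c(1, 2, 5, 20), function(om) {
    arch$sites$actA$omega <- om
    expression_rate(arch, arch$promoter$sequence, "on")
  }, 0)
  expect_true(all(diff(wt_rates) >= -1e-12))
})

test_that("simulate_counts conserves depth and respects zero rates", {
  w <- rand_window(43, L = 30, up = 20)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 49, seed = 3))
  rates <- runif(50)
  rates[7] <- 0
  ct <- simulate_counts(lib, rates, simulation_config(1e5, 1e5), seed = 2)
  expect_equal(sum(ct$dna), 1e5)
  expect_equal(sum(ct$rna), 1e5)
  expect_equal(ct$rna[7], 0)
  expect_error(simulate_counts(lib, rep(0, 50), seed = 2), "zero")
})

test_that("RNA shares track abundance x rate", {
  # two variants, rates 0.2/0.8, equal abundance
  ct <- simulate_counts(2L, c(0.2, 0.8),
                        simulation_config(1e6, 1e6,
                                          abundance_dispersion = 0),
                        seed = 11)
  share <- ct$rna[2] / sum(ct$rna)
  se <- sqrt(0.8 * 0.2 / 1e6)
  expect_lt(abs(share - 0.8), 3 * se)
})

test_that("generate_dataset is deterministic and directionally correct", {
  arch <- sim_repressor_promoter(7)
  ds1 <- generate_dataset(arch, conditions = c("repressed", "induced"),
                          replicates = 2,
                          mut_cfg = mutagenesis_config(n_variants = 400,
                                                       seed = 1),
                          sim_cfg = simulation_config(2e5, 2e5), seed = 5)
  ds2 <- generate_dataset(arch, conditions = c("repressed", "induced"),
                          replicates = 2,
                          mut_cfg = mutagenesis_config(n_variants = 400,
                                                       seed = 1),
                          sim_cfg = simulation_config(2e5, 2e5), seed = 5)
  expect_identical(ds1$counts$simRep$repressed[[1]]$rna,
                   ds2$counts$simRep$repressed[[1]]$rna)
  gt <- ds1$ground_truth
  expect_true("repA" %in% gt$name)
  expect_equal(gt$end[gt$name == "repA"] - gt$start[gt$name == "repA"], 15)

  # heavily site-mutated variants out-express intact ones when repressed
  lib <- ds1$libraries$simRep
  site <- gt[gt$name == "repA", ]
  hits <- rowSums(lib$masks[, (site$start + 1):site$end, drop = FALSE])
  ct <- ds1$counts$simRep$repressed[[1]]
  expr <- (ct$rna + 1) / (ct$dna + 1)
  expect_gt(mean(expr[hits >= 2]), mean(expr[hits == 0]))
})

test_that("write_dataset emits a parseable ground-truth BED and manifest", {
  arch <- sim_repressor_promoter(8)
  ds <- generate_dataset(arch, conditions = "repressed", replicates = 1,
                         mut_cfg = mutagenesis_config(n_variants = 50,
                                                      seed = 2),
                         sim_cfg = simulation_config(1e4, 1e4), seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  bed <- data.table::fread(file.path(dir, "ground_truth.bed"))
  expect_equal(nrow(bed), 2) # rnap + repressor
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_true(file.exists(file.path(dir, "simRep",
                                    "counts_repressed_rep1.tsv")))
})

test_that("overlapping sites demand a mutual-exclusion rule", {
  w <- rand_window(44, L = 40, up = 20)
  rnap <- site_matrix(w, start = 10, len = 10, penalty = 1)
  act <- site_matrix(w, start = 15, len = 10, penalty = 1)
  expect_error(architecture_spec(w, list(
    site_spec("RNAP", rnap, base_weight = 1, name = "rnap"),
    site_spec("activator", act, base_weight = 1, name = "actA"))),
    "mutual-exclusion")
  # a repressor overlapping RNAP is the standard occlusion architecture
  occl <- architecture_spec(w, list(
    site_spec("RNAP", rnap, base_weight = 1, name = "rnap"),
    site_spec("repressor", act, base_weight = 1, name = "repA")))
  expect_s3_class(occl, "architecture_spec")
})
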