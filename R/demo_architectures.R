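# Canonical synthetic promoter architectures. These are the stated worlds
# behind the package's recovery benchmarks: one promoter per footprint
# class (extended binding sites / single-mutation emergent TSS / inactive),
# built from realistic component choices — a sigma-70 core whose -35 and
# -10 hexamers are the only sequence-sensitive parts of the RNAP
# footprint (1.5 k_BT per mutation), and a strong occlusion repressor
# (base weight 100, LacI-class ~100-fold repression).

# core-promoter geometry shared by the demo architectures (array indices
# into the default 160-bp window, up = 115): -35 hexamer at labels
# [-35, -29), 17-bp neutral spacer, -10 hexamer at labels [-12, -6)
.DEMO_M35_START <- 80L
.DEMO_M10_START <- 103L
.DEMO_REP_START <- 40L   # repressor at labels [-75, -60)
.DEMO_REP_LEN <- 15L

# random 160-bp window; optionally overwrite a subsequence
.demo_window <- function(seed, name, plant = NULL, at = NULL) {
  set.seed(seed)
  s <- sample(DNA_BASES, 160L, replace = TRUE)
  if (!is.null(plant)) {
    p <- strsplit(plant, "", fixed = TRUE)[[1]]
    s[(at + 1L):(at + length(p))] <- p
  }
  promoter_window(paste(s, collapse = ""), gene = name,
                  promoter_name = name, strand = "+",
                  up = 115L, down = 45L)
}

.demo_rnap_matrix <- function(window, penalty = 1.5) {
  m35 <- site_matrix(window, .DEMO_M35_START, 6L, penalty = penalty)
  m10 <- site_matrix(window, .DEMO_M10_START, 6L, penalty = penalty)
  spacer <- matrix(0, .DEMO_M10_START - .DEMO_M35_START - 6L, 4,
                   dimnames = list(NULL, DNA_BASES))
  energy_matrix(.DEMO_M35_START, rbind(m35$energies, spacer, m10$energies))
}

#' Canonical single-repressor promoter (SITES class)
#'
#' A sigma-70 core promoter (sequence-sensitive -35/-10 hexamers,
#' 1.5 k_BT per mutation, base weight 1) plus a 15-bp occlusion repressor
#' at labels `[-75, -60)` (1.5 k_BT per mutation, base weight 100).
#' Conditions: `"repressed"` (repressor fully active) and `"induced"`
#' (active fraction 0).
#'
#' @param seed integer seed for the random window sequence.
#' @param name promoter name.
#' @return an [architecture_spec()].
#' @export
sim_repressor_promoter <- function(seed = 1L, name = "simRep") {
  w <- .demo_window(seed, name)
  rep_mat <- site_matrix(w, .DEMO_REP_START, .DEMO_REP_LEN, penalty = 1.5)
  architecture_spec(w, list(
    site_spec("RNAP", .demo_rnap_matrix(w), base_weight = 1, name = "rnap"),
    site_spec("repressor", rep_mat, base_weight = 100, name = "repA")),
    condition_activity = list(repressed = c(repA = 1), induced = c(repA = 0)))
}

#' Canonical emergent-TSS promoter (SPIKE class)
#'
#' The wild-type window carries `TATAAA` at labels `[-68, -62)` — a
#' minus-10 element failing only its last key position. The RNAP energy
#' matrix rewards the completing A-to-T mutation with -9 k_BT while the
#' basal weight is 1e-3, so only the ~1/30 of variants carrying exactly
#' that substitution express: a single-position MI spike (echoing
#' single-mutation TSS creation at an otherwise inactive promoter).
#'
#' @inheritParams sim_repressor_promoter
#' @return an [architecture_spec()]; the planted mutation is array index
#'   52 (label -63), A to T.
#' @export
sim_spike_promoter <- function(seed = 1L, name = "simSpike") {
  w <- .demo_window(seed, name, plant = "TATAAA", at = 47L)
  hex <- site_matrix(w, 47L, 6L, penalty = 0,
                     rewards = data.frame(offset = 5L, base = "T",
                                          energy = -9))
  architecture_spec(w, list(
    site_spec("RNAP", hex, base_weight = 1e-3, name = "rnap")),
    condition_activity = list(default = c()))
}

#' Canonical inactive promoter (INACTIVE class)
#'
#' No functional element engages RNAP anywhere in the window: the energy
#' matrix is flat (every mutation neutral), so expression carries no
#' sequence dependence and the footprint is pure sampling noise. Note that
#' a merely *weak* but sequence-sensitive core would still footprint —
#' sequencing normalizes away the absolute expression level — so
#' inactivity must mean flatness, not a small RNAP weight.
#'
#' @inheritParams sim_repressor_promoter
#' @return an [architecture_spec()].
#' @export
sim_inactive_promoter <- function(seed = 1L, name = "simOff") {
  w <- .demo_window(seed, name)
  flat <- energy_matrix(.DEMO_M35_START,
                        matrix(0, 29, 4, dimnames = list(NULL, DNA_BASES)))
  architecture_spec(w, list(
    site_spec("RNAP", flat, base_weight = 1e-4, name = "rnap")),
    condition_activity = list(default = c()))
}

#' One-call footprint simulation for a demo architecture
#'
#' Designs the mutant library at default settings, computes thermodynamic
#' rates, simulates counts at default depth and returns the footprint
#' (with shift matrix attached).
#'
#' @param arch an [architecture_spec()].
#' @param condition condition name.
#' @param seed integer seed (library and counts derive sub-seeds from it).
#' @param sim_cfg a [simulation_config()].
#' @param n_variants library size (default 1500).
#' @return a `footprint`; the library is attached as attribute `library`.
#' @export
simulate_footprint <- function(arch, condition = "default", seed = 1L,
                               sim_cfg = simulation_config(),
                               n_variants = 1500L) {
  lib <- mutate_promoter(arch$promoter,
                         mutagenesis_config(n_variants = n_variants,
                                            seed = seed))
  rates <- expression_rates(arch, lib, condition)
  ct <- simulate_counts(lib, rates, sim_cfg, seed = seed + 1L,
                        condition = condition)
  fp <- information_footprint(ct, lib)
  attr(fp, "library") <- lib
  fp
}
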