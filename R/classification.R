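# Automated triage of footprints into three classes:
#   SITES    - an active TSS with one or more binding sites (extended
#              regions of elevated MI),
#   SPIKE    - an otherwise inactive promoter switched on at an alternative
#              TSS by a single mutation (one isolated high-MI position),
#   INACTIVE - no active TSS under this condition.
# The discriminating statistic is the coefficient of variation (CV) of the
# footprint before vs after Gaussian smoothing: smoothing collapses the
# variation of an isolated spike much more than that of an extended site.

#' Coefficient of variation (population convention)
#'
#' Standard deviation over mean, with the population (divide by n) standard
#' deviation to avoid the n vs n-1 ambiguity.
#'
#' @param values numeric vector.
#' @return sd/mean, or NA with a warning when the mean is not positive.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    warning("coefficient of variation undefined for non-positive mean")
    return(NA_real_)
  }
  sqrt(mean((values - m)^2)) / m
}

#' Calibrate the activity floor from a no-signal simulation
#'
#' Simulates footprints of libraries whose variants all express at the same
#' rate (no sequence dependence), at the given depth, and returns five
#' times the median per-position MI — the scale of pure sampling noise.
#' Footprints whose mean MI falls below this floor are called INACTIVE.
#'
#' @param depth_dna,depth_rna sequencing depths (defaults 1e6).
#' @param n_variants,L library size and window length (defaults 1500/160).
#' @param alpha MI pseudocount (default 1).
#' @param n_sims number of simulated footprints pooled (default 5).
#' @param seed integer seed.
#' @return the calibrated `t_active` value (bits).
#' @export
calibrate_t_active <- function(depth_dna = 1e6, depth_rna = 1e6,
                               n_variants = 1500L, L = 160L, alpha = 1,
                               n_sims = 5L, seed = 100L) {
  .check_seed(seed)
  seq0 <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  w <- promoter_window(seq0, up = 115L, down = L - 115L)
  mis <- unlist(lapply(seq_len(n_sims), function(k) {
    lib <- mutate_promoter(w, mutagenesis_config(n_variants = n_variants,
                                                 seed = sample.int(1e8, 1)))
    ct <- simulate_counts(lib, rates = rep(0.5, length(lib$variants)),
                          simulation_config(depth_dna, depth_rna),
                          seed = sample.int(1e8, 1))
    information_footprint(ct, lib, alpha = alpha)$mi
  }))
  5 * median(mis)
}

# Default activity floor, frozen from calibrate_t_active() at the default
# depth (1e6/1e6), library size (1500 x 160 bp) and alpha = 1, seed 100.
# Scale-bearing: footprints computed at very different depths need their
# own calibration via calibrate_t_active().
T_ACTIVE_DEFAULT <- 7.97221e-07

#' Classify a footprint as SITES, SPIKE or INACTIVE
#'
#' A footprint whose mean MI is below `t_active` is INACTIVE. Otherwise the
#' ratio of the smoothed CV to the raw CV decides: an isolated single
#' position of high MI loses most of its variation under smoothing (ratio
#' below `t_ratio`, SPIKE), whereas an extended binding site keeps it
#' (SITES). The raw/smoothed CVs and the ratio are returned as diagnostics.
#'
#' @param fp a `footprint` (needs `mi` and `mi_smoothed` at matching
#'   sigma), or a numeric MI vector (smoothed with `sigma`).
#' @param t_active mean-MI activity floor in bits (default frozen from
#'   [calibrate_t_active()] at default depth; scale-bearing).
#' @param t_ratio spike cut on cv_smooth/cv_raw (default 0.55).
#' @param sigma smoothing bandwidth used when `fp` is a bare vector.
#' @return a `footprint_class`: list with `label`, `cv_raw`, `cv_smooth`,
#'   `ratio`, `t_active`, `t_ratio`.
#' @export
classify_footprint <- function(fp, t_active = T_ACTIVE_DEFAULT,
                               t_ratio = 0.55, sigma = 3) {
  if (inherits(fp, "footprint")) {
    mi <- fp$mi
    mi_s <- fp$mi_smoothed
  } else {
    mi <- fp
    mi_s <- smooth_footprint(mi, sigma)
  }
  out <- list(label = "INACTIVE", cv_raw = NA_real_, cv_smooth = NA_real_,
              ratio = NA_real_, t_active = t_active, t_ratio = t_ratio)
  if (!all(is.finite(mi)) || mean(mi) <= 0) {
    warning("degenerate footprint; labeled INACTIVE")
    class(out) <- "footprint_class"
    return(out)
  }
  out$cv_raw <- coefficient_of_variation(mi)
  out$cv_smooth <- coefficient_of_variation(mi_s)
  out$ratio <- out$cv_smooth / out$cv_raw
  if (mean(mi) >= t_active) {
    out$label <- if (out$ratio < t_ratio) "SPIKE" else "SITES"
  }
  class(out) <- "footprint_class"
  out
}

#' @export
print.footprint_class <- function(x, ...) {
  cat(sprintf("%s (cv_raw %.3g, cv_smooth %.3g, ratio %.3g)\n",
              x$label, x$cv_raw, x$cv_smooth, x$ratio))
  invisible(x)
}
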