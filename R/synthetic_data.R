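# Thermodynamic (statistical-mechanics) promoter models and the synthetic
# Reg-Seq dataset generator built on them. Expression is the equilibrium
# probability that RNA polymerase occupies the promoter, computed from a
# sum over binding microstates with Boltzmann weights; binding energies are
# additive per-position energy matrices in k_BT units with wild-type
# entries fixed at zero.

#' Additive per-position binding-energy matrix
#'
#' Energies are in k_BT units; by convention the wild-type base entry is 0
#' at every position, so `site_energy()` of the wild-type subsequence is 0
#' and mutations add their per-position penalties (or rewards, if
#' negative).
#'
#' @param start 0-based array index of the site's first position within the
#'   promoter window.
#' @param energies L_site x 4 numeric matrix, columns A, C, G, T.
#' @return an `energy_matrix`.
#' @export
energy_matrix <- function(start, energies) {
  energies <- as.matrix(energies)
  stopifnot(ncol(energies) == 4, nrow(energies) >= 1)
  colnames(energies) <- DNA_BASES
  if (any(apply(energies, 1L, min) > 0)) {
    stop("every row must contain a non-positive entry (wild-type convention)",
         call. = FALSE)
  }
  structure(list(start = as.integer(start), energies = energies,
                 length = nrow(energies)),
            class = "energy_matrix")
}

#' Build a site energy matrix relative to a window's wild-type sequence
#'
#' Convenience constructor: wild-type entries 0, all other entries
#' `penalty`, with optional per-position rewards for specific non-wild-type
#' bases (used to plant emergent elements whose binding a single mutation
#' can switch on).
#'
#' @param window a [promoter_window()].
#' @param start 0-based array index of the site start.
#' @param len site length in bp.
#' @param penalty energy cost (k_BT) of any mutation within the site.
#' @param rewards optional data.frame(offset, base, energy) of entries that
#'   override the penalty (offset 0-based within the site).
#' @return an [energy_matrix()].
#' @export
site_matrix <- function(window, start, len, penalty = 2,
                        rewards = NULL) {
  wt <- .dna_codes(window$sequence)
  stopifnot(start >= 0, start + len <= length(wt))
  E <- matrix(penalty, nrow = len, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(len)) E[j, wt[start + j]] <- 0
  if (!is.null(rewards)) {
    for (k in seq_len(nrow(rewards))) {
      E[rewards$offset[k] + 1L, rewards$base[k]] <- rewards$energy[k]
    }
  }
  energy_matrix(start, E)
}

#' Specification of one protein-binding site in an architecture
#'
#' @param role `"RNAP"`, `"activator"` or `"repressor"`.
#' @param matrix an [energy_matrix()].
#' @param base_weight dimensionless Boltzmann weight of the factor on the
#'   wild-type site: (copy number / N_NS) * exp(-beta * delta-epsilon_wt).
#' @param omega cooperativity factor with RNAP (activators: omega > 1;
#'   ignored for RNAP itself).
#' @param excludes_rnap if TRUE the factor cannot co-occupy with RNAP
#'   (default TRUE for repressors, FALSE otherwise).
#' @param name site label (used for condition activities and ground truth).
#' @return a `site_spec`.
#' @export
site_spec <- function(role = c("RNAP", "activator", "repressor"), matrix,
                      base_weight = 1, omega = 1,
                      excludes_rnap = NULL, name = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(matrix, "energy_matrix"), base_weight >= 0, omega > 0)
  if (is.null(excludes_rnap)) excludes_rnap <- role == "repressor"
  if (is.null(name)) name <- role
  structure(list(role = role, matrix = matrix, base_weight = base_weight,
                 omega = omega, excludes_rnap = isTRUE(excludes_rnap),
                 name = name),
            class = "site_spec")
}

#' Ground-truth regulatory architecture for the synthetic generator
#'
#' Exactly one RNAP site plus any number of activator/repressor sites, and
#' per-condition active fractions for the transcription factors (allosteric
#' activity is an input, not modeled mechanistically). Overlapping sites
#' must be mutually exclusive (a repressor overlapping RNAP is the standard
#' occlusion architecture).
#'
#' @param promoter a [promoter_window()].
#' @param sites list of [site_spec()]s (exactly one with role `"RNAP"`).
#' @param condition_activity named list: condition -> named numeric vector
#'   of active fractions in `[0, 1]` per site name; missing entries default
#'   to 1 (RNAP is always fully active).
#' @return an `architecture_spec`.
#' @export
architecture_spec <- function(promoter, sites,
                              condition_activity = list(default = c())) {
  stopifnot(inherits(promoter, "promoter_window"))
  roles <- vapply(sites, function(s) s$role, "")
  if (sum(roles == "RNAP") != 1L) {
    stop("exactly one RNAP site required", call. = FALSE)
  }
  nms <- vapply(sites, function(s) s$name, "")
  if (anyDuplicated(nms)) stop("site names must be unique", call. = FALSE)
  names(sites) <- nms
  L <- nchar(promoter$sequence)
  iv <- lapply(sites, function(s) {
    c(s$matrix$start, s$matrix$start + s$matrix$length)
  })
  for (v in iv) {
    if (v[1] < 0 || v[2] > L) stop("site interval outside window", call. = FALSE)
  }
  # overlapping pairs must carry a mutual-exclusion rule
  n <- length(sites)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      overlap <- iv[[a]][1] < iv[[b]][2] && iv[[b]][1] < iv[[a]][2]
      if (overlap) {
        pair <- sites[c(a, b)]
        rnap <- vapply(pair, function(s) s$role == "RNAP", TRUE)
        excl <- vapply(pair, function(s) s$excludes_rnap, TRUE)
        ok <- any(rnap) && any(excl[!rnap])
        if (!ok) stop("overlapping sites '", nms[a], "' and '", nms[b],
                      "' without a mutual-exclusion rule", call. = FALSE)
      }
    }
  }
  for (cond in names(condition_activity)) {
    act <- condition_activity[[cond]]
    if (length(act) && (any(act < 0) || any(act > 1))) {
      stop("active fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(promoter = promoter, sites = sites,
                 condition_activity = condition_activity),
            class = "architecture_spec")
}

#' Ground-truth site intervals of an architecture
#'
#' @param arch an [architecture_spec()].
#' @return data.frame: name, role, start, end (0-based half-open array
#'   coordinates), label_start, label_end (promoter-relative).
#' @export
ground_truth_sites <- function(arch) {
  up <- arch$promoter$up
  do.call(rbind, lapply(arch$sites, function(s) {
    data.frame(promoter = arch$promoter$promoter_name, name = s$name,
               role = s$role, start = s$matrix$start,
               end = s$matrix$start + s$matrix$length,
               label_start = s$matrix$start - up,
               label_end = s$matrix$start + s$matrix$length - up,
               row.names = NULL)
  }))
}

#' Binding energy of a subsequence under an additive energy matrix
#'
#' Sum over positions of the entry for the observed base.
#'
#' @param matrix an [energy_matrix()].
#' @param subsequence DNA string of the matrix's length.
#' @return energy in k_BT.
#' @export
site_energy <- function(matrix, subsequence) {
  stopifnot(inherits(matrix, "energy_matrix"))
  codes <- .dna_codes(subsequence)
  if (length(codes) != matrix$length) {
    stop("subsequence length ", length(codes), " != matrix length ",
         matrix$length, call. = FALSE)
  }
  sum(matrix$energies[cbind(seq_along(codes), codes)])
}

# per-site Boltzmann factors q_s(v, c) for all variants at once:
# base_weight * activity(condition) * exp(-E_site(variant))
.site_factors <- function(arch, seq_chars, condition) {
  act <- arch$condition_activity[[condition]]
  lapply(arch$sites, function(s) {
    m <- s$matrix
    cols <- seq.int(m$start + 1L, m$start + m$length)
    sub <- seq_chars[, cols, drop = FALSE]
    codes <- match(sub, DNA_BASES)
    E <- matrix(m$energies[cbind(rep(seq_len(m$length), each = nrow(sub)),
                                 codes)],
                nrow = nrow(sub))
    a <- if (s$role == "RNAP") 1 else {
      if (!is.null(act) && s$name %in% names(act)) act[[s$name]] else 1
    }
    s$base_weight * a * exp(-rowSums(E))
  })
}

# admissible occupancy microstates: all subsets of sites minus those
# violating mutual exclusion with RNAP or overlap exclusivity
.microstates <- function(arch) {
  n <- length(arch$sites)
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  colnames(states) <- names(arch$sites)
  rnap <- which(vapply(arch$sites, function(s) s$role == "RNAP", TRUE))
  excl <- vapply(arch$sites, function(s) s$excludes_rnap, TRUE)
  iv <- lapply(arch$sites, function(s) {
    c(s$matrix$start, s$matrix$start + s$matrix$length)
  })
  keep <- rep(TRUE, nrow(states))
  for (k in seq_len(nrow(states))) {
    occ <- which(states[k, ])
    if (length(occ) < 2) next
    if (rnap %in% occ && any(excl[setdiff(occ, rnap)])) { keep[k] <- FALSE; next }
    # co-bound overlapping non-exclusive pairs are geometrically impossible
    for (a in seq_along(occ)[-length(occ)]) for (b in (a + 1):length(occ)) {
      i <- occ[a]; j <- occ[b]
      if (iv[[i]][1] < iv[[j]][2] && iv[[j]][1] < iv[[i]][2]) {
        keep[k] <- FALSE
      }
    }
  }
  states[keep, , drop = FALSE]
}

#' Thermodynamic expression rates of promoter variants
#'
#' Enumerates all admissible occupancy microstates of the architecture's
#' sites. A state's weight is the product of the occupied sites' Boltzmann
#' factors (base weight x condition activity x exp(-energy)) times the
#' cooperativity omega of each occupied activator co-bound with RNAP. The
#' expression rate is the RNAP-bound probability: sum of RNAP-containing
#' state weights over the partition sum. Always in `[0, 1]`.
#'
#' @param arch an [architecture_spec()].
#' @param variants character vector of window-length DNA strings, or a
#'   `variant_library`.
#' @param condition condition name (keys `arch$condition_activity`).
#' @return numeric vector of rates, one per variant.
#' @export
expression_rates <- function(arch, variants, condition = "default") {
  if (inherits(variants, "variant_library")) {
    chars <- variants$seq_matrix
  } else {
    L <- nchar(arch$promoter$sequence)
    if (any(nchar(variants) != L)) {
      stop("variant length != window length", call. = FALSE)
    }
    chars <- .seq_matrix(variants)
  }
  q <- .site_factors(arch, chars, condition)
  states <- .microstates(arch)
  rnap_name <- names(arch$sites)[vapply(arch$sites,
                                        function(s) s$role == "RNAP", TRUE)]
  omegas <- vapply(arch$sites, function(s) s$omega, 0)
  V <- nrow(chars)
  Z <- numeric(V)
  Zb <- numeric(V)
  for (k in seq_len(nrow(states))) {
    occ <- which(states[k, ])
    w <- rep(1, V)
    for (i in occ) w <- w * q[[i]]
    if (length(occ) && states[k, rnap_name]) {
      for (i in occ) {
        s <- arch$sites[[i]]
        if (s$role == "activator") w <- w * omegas[i]
      }
    }
    Z <- Z + w
    if (states[k, rnap_name]) Zb <- Zb + w
  }
  Zb / Z
}

#' @rdname expression_rates
#' @param variant a single DNA string.
#' @export
expression_rate <- function(arch, variant, condition = "default") {
  expression_rates(arch, variant, condition)[1L]
}

#' Simulation settings for sequencing-count generation
#'
#' @param depth_dna,depth_rna total DNA and RNA reads per sample
#'   (default 1e6 each).
#' @param abundance_dispersion log-scale (natural log) standard deviation
#'   of per-variant abundances (default 0.5; real pools are uneven).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(depth_dna = 1e6, depth_rna = 1e6,
                              abundance_dispersion = 0.5) {
  stopifnot(depth_dna > 0, depth_rna > 0, abundance_dispersion >= 0)
  structure(list(depth_dna = depth_dna, depth_rna = depth_rna,
                 abundance_dispersion = abundance_dispersion),
            class = "simulation_config")
}

#' Simulate DNA and RNA sequencing counts for a library
#'
#' Variant abundances are drawn once per replicate from a log-normal
#' distribution; DNA counts are multinomial with probabilities proportional
#' to abundance, RNA counts multinomial with probabilities proportional to
#' abundance x expression rate.
#'
#' @param library a `variant_library` (or anything of matching length).
#' @param rates per-variant expression rates in `[0, 1]`.
#' @param cfg a [simulation_config()].
#' @param seed integer seed.
#' @param condition,replicate labels carried into the [count_table()].
#' @return a `count_table`.
#' @export
simulate_counts <- function(library, rates, cfg = simulation_config(),
                            seed = 1L, condition = "cond", replicate = 1L) {
  V <- if (inherits(library, "variant_library")) length(library$variants)
       else as.integer(library)
  stopifnot(length(rates) == V, all(rates >= 0), all(rates <= 1))
  if (all(rates == 0) && cfg$depth_rna > 0) {
    stop("all expression rates are zero but depth_rna > 0", call. = FALSE)
  }
  .check_seed(seed)
  abundance <- exp(rnorm(V, 0, cfg$abundance_dispersion))
  dna <- as.vector(rmultinom(1L, cfg$depth_dna, abundance))
  rna <- as.vector(rmultinom(1L, cfg$depth_rna, abundance * rates))
  ids <- if (inherits(library, "variant_library")) variant_ids(library)
         else seq_len(V)
  count_table(dna, rna, condition = condition, replicate = replicate,
              variant_id = ids)
}

#' Generate a complete ground-truth synthetic Reg-Seq dataset
#'
#' For each architecture: designs the mutant library with the default
#' mutagenesis settings, assigns barcodes, computes thermodynamic
#' expression rates per condition, and simulates sequencing counts per
#' condition and replicate. Ground-truth site intervals and per-condition
#' activities are recorded for downstream benchmarking.
#'
#' @param archs list of [architecture_spec()]s (one per promoter).
#' @param conditions character vector of condition names.
#' @param replicates replicates per condition (default 2).
#' @param mut_cfg a [mutagenesis_config()].
#' @param sim_cfg a [simulation_config()].
#' @param seed master seed; per-promoter/condition/replicate seeds are
#'   derived deterministically from it.
#' @return a `synthetic_dataset`: list with `libraries`, `barcode_maps`,
#'   `counts` (nested promoter -> condition -> replicate), `ground_truth`,
#'   `conditions`, `seed`.
#' @export
generate_dataset <- function(archs, conditions = "default", replicates = 2L,
                             mut_cfg = mutagenesis_config(),
                             sim_cfg = simulation_config(), seed = 1L) {
  if (inherits(archs, "architecture_spec")) archs <- list(archs)
  libraries <- list()
  maps <- list()
  counts <- list()
  truth <- list()
  for (p in seq_along(archs)) {
    arch <- archs[[p]]
    pname <- arch$promoter$promoter_name
    cfg_p <- mut_cfg
    cfg_p$seed <- (seed * 1009L + p) %% .Machine$integer.max
    lib <- mutate_promoter(arch$promoter, cfg_p)
    libraries[[pname]] <- lib
    maps[[pname]] <- assign_barcodes(lib, seed = cfg_p$seed + 1L)
    truth[[pname]] <- ground_truth_sites(arch)
    counts[[pname]] <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      rates <- expression_rates(arch, lib, cond)
      counts[[pname]][[cond]] <- lapply(seq_len(replicates), function(r) {
        s <- (seed * 7907L + p * 101L + ci * 13L + r) %% .Machine$integer.max
        simulate_counts(lib, rates, sim_cfg, seed = s,
                        condition = cond, replicate = r)
      })
    }
  }
  structure(list(libraries = libraries, barcode_maps = maps, counts = counts,
                 ground_truth = do.call(rbind, truth),
                 conditions = conditions, replicates = replicates,
                 seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Library FASTA/TSVs per promoter, barcode-map TSVs, count TSVs per
#' condition/replicate, ground-truth BED (promoter-relative 0-based
#' half-open intervals) and a manifest JSON with the seeds used.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pname in names(ds$libraries)) {
    pdir <- file.path(dir, pname)
    write_library(ds$libraries[[pname]], pdir)
    write_barcode_map(ds$barcode_maps[[pname]],
                      file.path(pdir, "barcode_map.tsv"))
    for (cond in names(ds$counts[[pname]])) {
      for (r in seq_along(ds$counts[[pname]][[cond]])) {
        write_count_table(ds$counts[[pname]][[cond]][[r]],
                          file.path(pdir, sprintf("counts_%s_rep%d.tsv",
                                                  cond, r)))
      }
    }
  }
  gt <- ds$ground_truth
  data.table::fwrite(data.table::data.table(
    chrom = gt$promoter, start = gt$label_start, end = gt$label_end,
    name = gt$name, score = 0, strand = "."),
    file.path(dir, "ground_truth.bed"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(list(seed = ds$seed, conditions = ds$conditions,
                            replicates = ds$replicates),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
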