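# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately re-derive each quantity by the most direct route
# (entropies, exhaustive enumeration, naive loops) so they cannot share a
# code path with the implementation they check.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_window <- function(seed, L = 160L, up = 115L) {
  set.seed(seed)
  promoter_window(rand_dna(L), up = up, down = L - up,
                  promoter_name = paste0("p", seed))
}

# --- mutual information on a 2x2 table via entropies -------------------
# columns/cells: (wt,dna), (wt,rna), (mut,dna), (mut,rna)
oracle_mi_2x2 <- function(n) {
  p <- n / sum(n)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  pm <- c(p[1] + p[2], p[3] + p[4])
  ps <- c(p[1] + p[3], p[2] + p[4])
  H(pm) + H(ps) - H(p)
}

# a two-variant library realizing an arbitrary 2x2 joint table at its
# first position: variant 1 wild type, variant 2 mutated at position 1
two_variant_library <- function(L = 4L) {
  wt <- paste(rep("A", L), collapse = "")
  mut <- paste0("C", substr(wt, 2, L))
  w <- promoter_window(wt, up = 0L, down = L)
  lib <- mutate_promoter(w, mutagenesis_config(n_variants = 1,
                                               rate = 0, seed = 1))
  lib$variants[2] <- mut
  lib$seq_matrix[2, 1] <- "C"
  lib$masks[2, 1] <- TRUE
  lib
}

# --- HMM: exhaustive enumeration over all state paths ------------------
oracle_hmm_loglik <- function(params, x) {
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lp <- apply(paths, 1L, function(s) {
    l <- log(params$initial[s[1]]) +
      dnorm(x[1], params$means[s[1]], params$sds[s[1]], log = TRUE)
    if (Tn > 1) for (t in 2:Tn) {
      l <- l + log(params$transition[s[t - 1], s[t]]) +
        dnorm(x[t], params$means[s[t]], params$sds[s[t]], log = TRUE)
    }
    l
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

oracle_hmm_viterbi <- function(params, x) {
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lp <- apply(paths, 1L, function(s) {
    l <- log(params$initial[s[1]]) +
      dnorm(x[1], params$means[s[1]], params$sds[s[1]], log = TRUE)
    if (Tn > 1) for (t in 2:Tn) {
      l <- l + log(params$transition[s[t - 1], s[t]]) +
        dnorm(x[t], params$means[s[t]], params$sds[s[t]], log = TRUE)
    }
    l
  })
  as.integer(paths[which.max(lp), ])
}

rand_hmm_params <- function() {
  a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
  hmm_params(matrix(c(a, 1 - a, 1 - b, b), 2, byrow = TRUE),
             initial = { p <- runif(1, 0.05, 0.95); c(p, 1 - p) },
             means = sort(rnorm(2, 0, 1)),
             sds = runif(2, 0.3, 1.5))
}

# --- thermodynamic occupancy: independent exhaustive state sum ---------
# plain-loop re-derivation: subsets via bit masks, per-position energy
# lookups, omega only on activator+RNAP co-occupancy, exclusion rules
oracle_expression_rate <- function(arch, variant, condition) {
  sites <- arch$sites
  n <- length(sites)
  act <- arch$condition_activity[[condition]]
  q <- numeric(n)
  for (i in seq_len(n)) {
    s <- sites[[i]]
    E <- 0
    for (j in seq_len(s$matrix$length)) {
      base <- substr(variant, s$matrix$start + j, s$matrix$start + j)
      E <- E + s$matrix$energies[j, base]
    }
    a <- if (s$role == "RNAP") 1
         else if (!is.null(act) && s$name %in% names(act)) act[[s$name]]
         else 1
    q[i] <- s$base_weight * a * exp(-E)
  }
  rnap <- which(vapply(sites, function(s) s$role == "RNAP", TRUE))
  iv <- lapply(sites, function(s) c(s$matrix$start,
                                    s$matrix$start + s$matrix$length))
  Z <- 0; Zb <- 0
  for (mask in 0:(2^n - 1)) {
    occ <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (rnap %in% occ) {
      for (i in setdiff(occ, rnap)) if (sites[[i]]$excludes_rnap) ok <- FALSE
    }
    if (length(occ) >= 2) {
      for (a2 in seq_along(occ)[-length(occ)]) {
        for (b2 in (a2 + 1):length(occ)) {
          i <- occ[a2]; j <- occ[b2]
          if (iv[[i]][1] < iv[[j]][2] && iv[[j]][1] < iv[[i]][2]) ok <- FALSE
        }
      }
    }
    if (!ok) next
    w <- prod(q[occ])
    if (rnap %in% occ) {
      for (i in occ) if (sites[[i]]$role == "activator") {
        w <- w * sites[[i]]$omega
      }
    }
    Z <- Z + w
    if (rnap %in% occ) Zb <- Zb + w
  }
  Zb / Z
}

# --- emergent minus-10 scan: brute force over mutations x hexamers -----
oracle_scan_tss <- function(window, key = c(1L, 2L, 6L),
                            consensus = "TATAAT") {
  seqv <- strsplit(window$sequence, "", fixed = TRUE)[[1]]
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  L <- length(seqv)
  out <- list()
  for (pos in 0:(L - 1L)) {
    for (b in setdiff(c("A", "C", "G", "T"), seqv[pos + 1L])) {
      mut <- seqv
      mut[pos + 1L] <- b
      for (h in max(0L, pos - 5L):min(L - 6L, pos)) {
        wt_hex <- seqv[(h + 1L):(h + 6L)]
        mut_hex <- mut[(h + 1L):(h + 6L)]
        wt_ok <- all(wt_hex[key] == cons[key])
        mut_all <- all(mut_hex[key] == cons[key])
        if (!wt_ok && mut_all) {
          out[[length(out) + 1L]] <-
            data.frame(position = pos, to_base = b, hexamer_start = h)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), to_base = character(0),
                      hexamer_start = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$hexamer_start, res$position, res$to_base), , drop = FALSE]
}

jaccard_interval <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}
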