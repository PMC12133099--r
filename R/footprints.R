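# Information footprints and expression-shift matrices: the two per-base
# summary statistics linking promoter sequence to expression. The footprint
# is, at each position, the mutual information between a variant's mutation
# status there (wild-type vs mutated) and the source of a sequencing read
# (DNA vs RNA); positions inside functional elements shift reads between
# the two pools and light up, neutral positions carry ~0 bits.

#' Per-position mutation indicator table
#'
#' `indicators[i, v]` is TRUE iff variant `v` is mutated at array position
#' `i` (0-based position `i - 1`).
#'
#' @param library a `variant_library`.
#' @return L x V logical matrix.
#' @export
mutation_indicators <- function(library) {
  stopifnot(inherits(library, "variant_library"))
  t(library$masks)
}

# MI (bits) of 2x2 joint count tables, vectorized over rows of an n x 4
# matrix with columns (wt_dna, wt_rna, mut_dna, mut_rna); alpha already added
.mi_2x2 <- function(n) {
  tot <- rowSums(n)
  p <- n / tot
  pm_wt <- p[, 1] + p[, 2]
  pm_mut <- p[, 3] + p[, 4]
  ps_dna <- p[, 1] + p[, 3]
  ps_rna <- p[, 2] + p[, 4]
  marg <- cbind(pm_wt * ps_dna, pm_wt * ps_rna, pm_mut * ps_dna,
                pm_mut * ps_rna)
  term <- p * log2(p / marg)
  term[p == 0] <- 0
  mi <- rowSums(term)
  # clamp tiny negative rounding noise
  pmax(mi, 0)
}

#' Information footprint of a promoter
#'
#' For each position, forms the 2x2 joint table over mutation status
#' (wild-type vs mutated base) and read source (DNA vs RNA) by summing the
#' variant counts in each cell, adds a pseudocount `alpha` to every cell,
#' and computes the mutual information in bits. MI is bounded by 1 bit for
#' these binary/binary tables, is symmetric in the DNA/RNA labels, and
#' (at `alpha = 0`) is invariant to scaling all counts by a constant.
#'
#' @param counts a [count_table()] whose rows align with the library's
#'   variants (missing variants are treated as zero counts).
#' @param indicators L x V logical matrix from [mutation_indicators()], or
#'   a `variant_library`.
#' @param alpha pseudocount added to each joint cell (default 1).
#' @param sigma Gaussian smoothing bandwidth in bp for the stored
#'   `mi_smoothed` track (default 3); see [smooth_footprint()].
#' @param library optional `variant_library` used to also compute the
#'   expression-shift matrix (stored in `$shift`).
#' @return a `footprint`: list with `mi`, `mi_smoothed`, `labels`
#'   (promoter-relative positions), `alpha`, `sigma`, and `shift` (L x 4 or
#'   NULL), plus `promoter`, `condition`, `replicate` fields.
#' @export
information_footprint <- function(counts, indicators, alpha = 1,
                                  sigma = 3, library = NULL) {
  if (inherits(indicators, "variant_library")) {
    library <- indicators
    indicators <- mutation_indicators(indicators)
  }
  V <- ncol(indicators)
  dna <- numeric(V)
  rna <- numeric(V)
  idx <- seq_len(min(nrow(counts), V))
  dna[idx] <- counts$dna[idx]
  rna[idx] <- counts$rna[idx]
  ind <- indicators * 1 # numeric for matrix products
  mut_dna <- as.vector(ind %*% dna)
  mut_rna <- as.vector(ind %*% rna)
  n <- cbind(wt_dna = sum(dna) - mut_dna, wt_rna = sum(rna) - mut_rna,
             mut_dna = mut_dna, mut_rna = mut_rna) + alpha
  zero <- rowSums(n) == 0
  mi <- numeric(nrow(n))
  if (any(!zero)) mi[!zero] <- .mi_2x2(n[!zero, , drop = FALSE])
  if (any(zero)) {
    warning("position(s) with zero total counts and alpha = 0; MI set to 0")
  }
  # a never- (or always-) mutated position has a degenerate marginal: MI 0
  lab <- if (!is.null(library)) position_labels(library$promoter)
         else seq_len(nrow(n)) - 1L
  fp <- structure(list(
    mi = mi, mi_smoothed = smooth_footprint(mi, sigma), labels = lab,
    alpha = alpha, sigma = sigma,
    shift = if (!is.null(library)) {
      expression_shift_matrix(counts, library, alpha)
    } else NULL,
    promoter = if (!is.null(library)) library$promoter$promoter_name
               else NA_character_,
    condition = attr(counts, "condition") %||% NA_character_,
    replicate = attr(counts, "replicate") %||% NA_integer_),
    class = "footprint")
  fp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("footprint %s/%s rep %s: L=%d, mean MI %.2g bits, max %.2g\n",
              x$promoter, x$condition, x$replicate, length(x$mi),
              mean(x$mi), max(x$mi)))
  invisible(x)
}

#' Expression-shift matrix
#'
#' Per-variant normalized expression is
#' `e_v = ((rna_v + alpha)/(R + alpha V)) / ((dna_v + alpha)/(D + alpha V))`.
#' The shift for base `b` at position `i` is the fractional change of the
#' mean `e` among variants carrying `b` there relative to the mean among
#' variants carrying the wild-type base. Wild-type-base entries are 0 by
#' construction; base/position combinations with no representatives are NA.
#' Positive shifts mean the mutation increases expression (repressor-like),
#' negative shifts decrease it (activator/RNAP-like).
#'
#' @inheritParams information_footprint
#' @param library a `variant_library`.
#' @return L x 4 numeric matrix, columns A, C, G, T.
#' @export
expression_shift_matrix <- function(counts, library, alpha = 1) {
  stopifnot(inherits(library, "variant_library"))
  V <- length(library$variants)
  dna <- numeric(V)
  rna <- numeric(V)
  idx <- seq_len(min(nrow(counts), V))
  dna[idx] <- counts$dna[idx]
  rna[idx] <- counts$rna[idx]
  D <- sum(dna); R <- sum(rna)
  e <- ((rna + alpha) / (R + alpha * V)) / ((dna + alpha) / (D + alpha * V))
  chars <- library$seq_matrix
  L <- ncol(chars)
  wt <- strsplit(library$promoter$sequence, "", fixed = TRUE)[[1]]
  shift <- matrix(NA_real_, nrow = L, ncol = 4,
                  dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES) {
    hit <- chars == b
    nb <- colSums(hit)
    mean_b <- ifelse(nb > 0, colSums(e * hit) / nb, NA_real_)
    shift[, b] <- mean_b
  }
  wt_mean <- shift[cbind(seq_len(L), match(wt, DNA_BASES))]
  if (any(!is.na(wt_mean) & wt_mean == 0)) {
    warning("zero wild-type-base mean expression at some position(s)")
  }
  shift <- (shift - wt_mean) / wt_mean
  shift[cbind(seq_len(L), match(wt, DNA_BASES))] <- 0
  shift
}

#' Gaussian-smooth a footprint
#'
#' Discrete Gaussian convolution with the kernel truncated at `4 * sigma`;
#' at the edges the kernel weights are renormalized by their in-window sum,
#' so a constant input maps to itself everywhere.
#'
#' @param mi numeric vector (per-position MI, but any track works).
#' @param sigma kernel standard deviation in bp (> 0; default 3).
#' @return numeric vector, same length.
#' @export
smooth_footprint <- function(mi, sigma = 3) {
  stopifnot(sigma > 0)
  K <- ceiling(4 * sigma)
  off <- -K:K
  w <- exp(-off^2 / (2 * sigma^2))
  L <- length(mi)
  num <- numeric(L)
  den <- numeric(L)
  for (j in seq_along(off)) {
    src <- seq_len(L) + off[j]
    ok <- src >= 1 & src <= L
    num[ok] <- num[ok] + w[j] * mi[src[ok]]
    den[ok] <- den[ok] + w[j]
  }
  num / den
}

#' Pearson correlation between two footprints
#'
#' The replicate-agreement statistic: plain Pearson correlation of the raw
#' MI tracks.
#'
#' @param fpA,fpB `footprint` objects or numeric vectors of equal length.
#' @return Pearson r (NA with a warning if either track has zero variance).
#' @export
footprint_correlation <- function(fpA, fpB) {
  a <- if (inherits(fpA, "footprint")) fpA$mi else fpA
  b <- if (inherits(fpB, "footprint")) fpB$mi else fpB
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance footprint; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
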