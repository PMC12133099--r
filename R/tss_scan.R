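# Emergent transcription-start-site detection: single mutations that
# complete the sigma-70 minus-10 element. The consensus hexamer is TATAAT;
# its first two bases and its last base (positions 1, 2 and 6) dominate
# recognition. A new TSS is predicted wherever the wild-type hexamer fails
# at least one of those key positions and a single substitution makes all
# three match.

MINUS10_CONSENSUS <- "TATAAT"
MINUS10_KEY_POSITIONS <- c(1L, 2L, 6L)

#' Score a hexamer against the minus-10 consensus
#'
#' @param hexamer DNA 6-mer.
#' @param consensus consensus hexamer (default TATAAT).
#' @param key_positions 1-based positions within the hexamer that dominate
#'   sigma-70 recognition (default 1, 2, 6).
#' @return list with `key_matches` (subset of `key_positions` that match)
#'   and `full_matches` (count over all 6 positions).
#' @export
score_minus10 <- function(hexamer, consensus = MINUS10_CONSENSUS,
                          key_positions = MINUS10_KEY_POSITIONS) {
  h <- strsplit(toupper(hexamer), "", fixed = TRUE)[[1]]
  if (length(h) != 6) stop("hexamer must have length 6", call. = FALSE)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  hits <- h == cons
  list(key_matches = key_positions[hits[key_positions]],
       full_matches = sum(hits))
}

#' Scan a promoter window for single-mutation emergent minus-10 elements
#'
#' For every position, alternative base and overlapping hexamer: a
#' candidate is emitted iff the wild-type hexamer fails at least one key
#' position of the minus-10 consensus and the mutated hexamer matches all
#' of them. The predicted TSS sits `tss_offset` bp downstream of the
#' hexamer's last base (default 7, canonical sigma-70 spacing between the
#' minus-10 element and initiation).
#'
#' @param window a [promoter_window()].
#' @param consensus,key_positions see [score_minus10()].
#' @param tss_offset predicted TSS distance downstream of the hexamer end
#'   (default 7 bp).
#' @return data.frame of candidates: `position` (0-based array index of
#'   the mutation), `position_label`, `from_base`, `to_base`,
#'   `hexamer_start`, `hexamer_label_start`, `hexamer_label_end`
#'   (half-open), `predicted_tss_label`, `mutant_hexamer`.
#' @export
scan_emergent_tss <- function(window, consensus = MINUS10_CONSENSUS,
                              key_positions = MINUS10_KEY_POSITIONS,
                              tss_offset = 7L) {
  stopifnot(inherits(window, "promoter_window"))
  seqv <- strsplit(window$sequence, "", fixed = TRUE)[[1]]
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  L <- length(seqv)
  up <- window$up
  res <- list()
  for (h in 0:(L - 6L)) {                     # hexamer start, 0-based
    hex <- seqv[(h + 1L):(h + 6L)]
    wt_key_ok <- hex[key_positions] == cons[key_positions]
    if (all(wt_key_ok)) next                  # nothing to complete
    if (sum(!wt_key_ok) > 1L) next            # one substitution cannot fix 2+
    j <- key_positions[!wt_key_ok]            # the single failing key position
    b <- cons[j]
    pos <- h + j - 1L                         # 0-based mutation position
    mut_hex <- hex
    mut_hex[j] <- b
    res[[length(res) + 1L]] <- data.frame(
      position = pos, position_label = pos - up,
      from_base = hex[j], to_base = b,
      hexamer_start = h,
      hexamer_label_start = h - up, hexamer_label_end = h + 6L - up,
      predicted_tss_label = h + 5L + tss_offset - up,
      mutant_hexamer = paste(mut_hex, collapse = ""))
  }
  if (!length(res)) {
    return(data.frame(position = integer(0), position_label = integer(0),
                      from_base = character(0), to_base = character(0),
                      hexamer_start = integer(0),
                      hexamer_label_start = integer(0),
                      hexamer_label_end = integer(0),
                      predicted_tss_label = integer(0),
                      mutant_hexamer = character(0)))
  }
  out <- do.call(rbind, res)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Corroborate emergent-TSS candidates with an expression-shift matrix
#'
#' Annotates each candidate with the expression shift of its mutation (from
#' a condition where the native promoter is inactive) and flags it
#' "supported" when that shift is a positive outlier: greater than
#' `spike_threshold` times the median absolute shift of the whole matrix.
#'
#' @param candidates output of [scan_emergent_tss()].
#' @param shift L x 4 expression-shift matrix (rows = array positions).
#' @param spike_threshold outlier multiplier (default 5).
#' @return `candidates` with added `shift` and `supported` columns.
#' @export
corroborate_with_shift <- function(candidates, shift, spike_threshold = 5) {
  if (nrow(candidates) == 0) {
    candidates$shift <- numeric(0)
    candidates$supported <- logical(0)
    return(candidates)
  }
  mad0 <- median(abs(shift[shift != 0]), na.rm = TRUE)
  sh <- shift[cbind(candidates$position + 1L,
                    match(candidates$to_base, DNA_BASES))]
  candidates$shift <- sh
  candidates$supported <- !is.na(sh) & sh > spike_threshold * mad0
  candidates
}
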