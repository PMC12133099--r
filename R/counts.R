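# Turning raw barcode observations into per-variant DNA/RNA count tables:
# the mapping-run read-support filter, variant assignment by bounded
# Hamming matching, and barcode-to-variant aggregation.

#' Filter promoter/barcode pairs by mapping-run read support
#'
#' Pairs seen in fewer than `min_reads` reads in the mapping run are
#' discarded (default 3, the standard low-support cutoff).
#'
#' @param observations data.frame with a `reads` column (one row per
#'   promoter/barcode pair).
#' @param min_reads minimum total reads to retain a pair (default 3).
#' @return the retained rows.
#' @export
filter_pairs <- function(observations, min_reads = 3L) {
  stopifnot("reads" %in% names(observations), all(observations$reads >= 0))
  observations[observations$reads >= min_reads, , drop = FALSE]
}

#' Assign a sequenced promoter read to a library variant
#'
#' Bounded Hamming matching: the read is assigned to the nearest library
#' variant if that nearest variant is unique and within `max_mismatch`
#' mismatches. Ties are left unassigned. Reads farther than `max_mismatch`
#' from every variant are registered as NEW variants — synthesis-error
#' variants present in the ordered pool but absent from the design.
#'
#' @param promoter_read DNA string, same length as the library variants.
#' @param library a `variant_library`.
#' @param max_mismatch maximum allowed Hamming distance (default 4).
#' @return list with `variant_id` (integer index or NA), `status`
#'   (`"assigned"`, `"tie"` or `"new"`) and `distance`.
#' @export
assign_variant <- function(promoter_read, library, max_mismatch = 4L) {
  stopifnot(inherits(library, "variant_library"))
  codes <- .dna_codes(toupper(promoter_read))
  L <- ncol(library$seq_matrix)
  if (length(codes) != L) {
    stop("read length ", length(codes), " != variant length ", L,
         call. = FALSE)
  }
  d <- rowSums(sweep(library$seq_matrix, 2L, DNA_BASES[codes], "!="))
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin > max_mismatch) {
    list(variant_id = NA_integer_, status = "new", distance = dmin)
  } else if (length(hits) > 1L) {
    list(variant_id = NA_integer_, status = "tie", distance = dmin)
  } else {
    list(variant_id = hits, status = "assigned", distance = dmin)
  }
}

#' Aggregate barcode counts to per-variant DNA/RNA counts
#'
#' Sums the DNA-sample and RNA-sample counts of all barcodes mapped to each
#' variant. Barcodes absent from the map are excluded and reported via a
#' message and the `unmapped` attribute.
#'
#' @param dna_counts,rna_counts data.frames with columns `barcode`, `count`.
#' @param map a `barcode_map` (barcode -> variant_id).
#' @param n_variants number of variants in the library (rows of the output;
#'   default: max variant_id in the map).
#' @param condition,replicate labels for the resulting [count_table()].
#' @return a `count_table` with one row per variant (zero-filled).
#' @export
aggregate_counts <- function(dna_counts, rna_counts, map,
                             n_variants = max(map$variant_id),
                             condition = "cond", replicate = 1L) {
  sum_one <- function(bc) {
    stopifnot(all(c("barcode", "count") %in% names(bc)))
    idx <- match(bc$barcode, map$barcode)
    unmapped <- bc$barcode[is.na(idx)]
    mapped <- !is.na(idx)
    out <- numeric(n_variants)
    if (any(mapped)) {
      agg <- tapply(bc$count[mapped], map$variant_id[idx[mapped]], sum)
      out[as.integer(names(agg))] <- agg
    }
    list(counts = out, unmapped = unmapped)
  }
  d <- sum_one(dna_counts)
  r <- sum_one(rna_counts)
  unmapped <- unique(c(d$unmapped, r$unmapped))
  if (length(unmapped)) {
    message(length(unmapped), " unmapped barcode(s) excluded")
  }
  ct <- count_table(d$counts, r$counts, condition = condition,
                    replicate = replicate)
  attr(ct, "unmapped") <- unmapped
  ct
}

#' Split variant-level counts across barcodes
#'
#' Inverse of [aggregate_counts()] for simulation: distributes each
#' variant's DNA and RNA counts across its barcodes multinomially with
#' equal probabilities.
#'
#' @param counts a `count_table` (rows aligned with library variants).
#' @param map a `barcode_map`.
#' @param seed integer seed.
#' @return data.table: barcode, variant_id, dna, rna.
#' @export
split_counts_by_barcode <- function(counts, map, seed = 1L) {
  .check_seed(seed)
  out <- data.table::as.data.table(map)[, c("barcode", "variant_id")]
  out$dna <- 0; out$rna <- 0
  for (v in unique(out$variant_id)) {
    rows <- which(out$variant_id == v)
    k <- length(rows)
    dv <- counts$dna[v]; rv <- counts$rna[v]
    if (dv > 0) out$dna[rows] <- as.vector(rmultinom(1, dv, rep(1, k)))
    if (rv > 0) out$rna[rows] <- as.vector(rmultinom(1, rv, rep(1, k)))
  }
  out
}
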