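# Readers and writers for the plain-text interchange formats:
# library FASTA + mask/metadata TSV, barcode-map TSV, count-table TSV,
# footprint and shift TSVs, BED site files.

#' Write a variant library to FASTA plus metadata TSVs
#'
#' Produces `library.fa` (one record per variant, id `<promoter>__v<k>`),
#' `masks.tsv` (variant_id, comma-separated 0-based mutated positions) and
#' `promoter.tsv` (window metadata). [read_library()] restores an identical
#' object.
#'
#' @param library a `variant_library`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "variant_library"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- variant_ids(library)
  dna <- Biostrings::DNAStringSet(library$variants)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, file.path(dir, "library.fa"))
  pos <- apply(library$masks, 1L, function(m) {
    paste(which(m) - 1L, collapse = ",")
  })
  data.table::fwrite(
    data.table::data.table(variant_id = ids, mutated_positions = pos),
    file.path(dir, "masks.tsv"), sep = "\t")
  w <- library$promoter
  cfg <- library$config
  data.table::fwrite(data.table::data.table(
    gene = w$gene, promoter_name = w$promoter_name,
    tss_genomic = w$tss_genomic, strand = w$strand,
    up = w$up, down = w$down,
    rate = cfg$rate, n_variants = cfg$n_variants,
    include_wildtype = cfg$include_wildtype, seed = cfg$seed),
    file.path(dir, "promoter.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a variant library written by [write_library()]
#'
#' @param dir directory containing `library.fa`, `masks.tsv`, `promoter.tsv`.
#' @return a `variant_library`.
#' @export
read_library <- function(dir) {
  dna <- Biostrings::readDNAStringSet(file.path(dir, "library.fa"))
  meta <- data.table::fread(file.path(dir, "promoter.tsv"), sep = "\t")
  variants <- as.character(dna)
  wt_idx <- if (meta$include_wildtype) 1L else NA_integer_
  wt_seq <- if (meta$include_wildtype) unname(variants[1L]) else {
    stop("cannot reconstruct wild type from a library without it",
         call. = FALSE)
  }
  window <- promoter_window(wt_seq, gene = meta$gene,
                            promoter_name = meta$promoter_name,
                            tss_genomic = meta$tss_genomic,
                            strand = meta$strand,
                            up = meta$up, down = meta$down)
  cfg <- mutagenesis_config(rate = meta$rate, n_variants = meta$n_variants,
                            include_wildtype = meta$include_wildtype,
                            seed = meta$seed)
  chars <- .seq_matrix(variants)
  masks <- sweep(chars, 2L, chars[wt_idx, ], "!=")
  structure(list(promoter = window, variants = unname(variants),
                 masks = masks, seq_matrix = chars, config = cfg),
            class = "variant_library")
}

#' @rdname write_library
#' @param map a `barcode_map`.
#' @param path output TSV path.
#' @export
write_barcode_map <- function(map, path) {
  data.table::fwrite(data.table::as.data.table(map), path, sep = "\t")
  invisible(path)
}

#' @rdname write_library
#' @export
read_barcode_map <- function(path) {
  map <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = "barcode"))
  structure(map, class = c("barcode_map", class(map)))
}

#' Per-variant DNA/RNA counts for one condition and replicate
#'
#' @param dna,rna non-negative integer vectors, one entry per variant.
#' @param condition,replicate sample labels.
#' @param variant_id optional ids (default 1..V indices).
#' @return a `count_table` (data.table: variant_id, dna, rna).
#' @export
count_table <- function(dna, rna, condition = "cond", replicate = 1L,
                        variant_id = seq_along(dna)) {
  stopifnot(length(dna) == length(rna), all(dna >= 0), all(rna >= 0))
  ct <- data.table::data.table(variant_id = variant_id,
                               dna = as.numeric(dna), rna = as.numeric(rna))
  structure(ct, class = c("count_table", class(ct)),
            condition = condition, replicate = as.integer(replicate))
}

#' @rdname count_table
#' @param counts a `count_table`.
#' @param path output TSV path.
#' @export
write_count_table <- function(counts, path) {
  data.table::fwrite(data.table::as.data.table(counts), path, sep = "\t")
  invisible(path)
}

#' @rdname count_table
#' @param condition,replicate labels attached on read.
#' @export
read_count_table <- function(path, condition = "cond", replicate = 1L) {
  ct <- data.table::fread(path, sep = "\t")
  count_table(ct$dna, ct$rna, condition = condition, replicate = replicate,
              variant_id = ct$variant_id)
}

#' Write a footprint (and optionally its shift matrix) to TSV
#'
#' The footprint TSV has columns `position` (promoter-relative 0-based
#' label), `mi`, `mi_smoothed`; the shift TSV has `position`, `A`, `C`,
#' `G`, `T`.
#'
#' @param fp a `footprint` object (see [information_footprint()]).
#' @param path output TSV path.
#' @param shift_path optional path for the expression-shift matrix.
#' @export
write_footprint <- function(fp, path, shift_path = NULL) {
  data.table::fwrite(data.table::data.table(
    position = fp$labels, mi = fp$mi, mi_smoothed = fp$mi_smoothed),
    path, sep = "\t")
  if (!is.null(shift_path) && !is.null(fp$shift)) {
    sh <- data.table::data.table(position = fp$labels)
    for (b in DNA_BASES) sh[[b]] <- fp$shift[, b]
    data.table::fwrite(sh, shift_path, sep = "\t")
  }
  invisible(path)
}

#' Write binding-site calls as a BED-like file
#'
#' Promoter name as the sequence name, 0-based half-open array interval,
#' name = sign, score = mean posterior x 1000.
#'
#' @param calls data.frame of site calls (see [decode_sites()]).
#' @param path output path.
#' @export
write_sites_bed <- function(calls, path) {
  bed <- data.table::data.table(
    chrom = calls$promoter, start = calls$start, end = calls$end,
    name = calls$sign, score = round(1000 * calls$mean_posterior),
    strand = ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
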