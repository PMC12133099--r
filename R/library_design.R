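#' Promoter window anchored at a transcription start site
#'
#' A `promoter_window` holds the mutagenesis target: the sequence running
#' from `up` bp upstream of the TSS to `down` bp downstream, always in
#' transcription orientation. Array index `i` (0-based) carries the
#' promoter-relative label `i - up`, so label 0 is the TSS base itself and
#' the window length is exactly `up + down`.
#'
#' @param sequence DNA string of length `up + down` (A/C/G/T only).
#' @param gene gene name.
#' @param promoter_name promoter identifier (unique per window).
#' @param tss_genomic 0-based genomic coordinate of the TSS base.
#' @param strand `"+"` or `"-"`.
#' @param up bp upstream of the TSS included in the window (default 115).
#' @param down bp downstream including the TSS base itself (default 45).
#' @return an object of class `promoter_window`.
#' @seealso [extract_window()] to build one from a genome sequence.
#' @export
promoter_window <- function(sequence, gene = "gene", promoter_name = "p1",
                            tss_genomic = NA_integer_, strand = "+",
                            up = 115L, down = 45L) {
  up <- as.integer(up); down <- as.integer(down)
  stopifnot(up >= 0, down >= 1, strand %in% c("+", "-"))
  sequence <- toupper(sequence)
  .dna_codes(sequence) # validates the alphabet
  if (nchar(sequence) != up + down) {
    stop("sequence length ", nchar(sequence), " != up + down = ", up + down,
         call. = FALSE)
  }
  structure(
    list(gene = gene, promoter_name = promoter_name,
         tss_genomic = as.integer(tss_genomic), strand = strand,
         sequence = sequence, up = up, down = down),
    class = "promoter_window")
}

#' @export
print.promoter_window <- function(x, ...) {
  cat(sprintf("promoter_window %s (%s) strand %s, %d bp [-%d, +%d)\n",
              x$promoter_name, x$gene, x$strand, nchar(x$sequence),
              x$up, x$down))
  invisible(x)
}

#' Promoter-relative labels of a window or library
#'
#' Labels are 0-based relative to the TSS: index `i` maps to `i - up`,
#' label 0 is the TSS base. Set `display = "plus1"` for the +1-style
#' display convention (no label 0; ... -2, -1, +1, +2 ...).
#'
#' @param window a `promoter_window`.
#' @param display `"zero"` (default) or `"plus1"`.
#' @return integer (or character, for `"plus1"`) vector of length L.
#' @export
position_labels <- function(window, display = c("zero", "plus1")) {
  display <- match.arg(display)
  L <- nchar(window$sequence)
  lab <- seq_len(L) - 1L - window$up
  if (display == "zero") return(lab)
  ifelse(lab >= 0, paste0("+", lab + 1L), as.character(lab))
}

#' Extract a TSS-anchored promoter window from a genome sequence
#'
#' Takes the region from `up` bp upstream of the TSS to `down` bp downstream
#' (the TSS base counts as the first downstream base). On the minus strand
#' the genomic segment is reverse-complemented so that upstream always means
#' upstream in transcription orientation.
#'
#' @param genome_sequence DNA string (a chromosome or contig).
#' @param tss 0-based genomic coordinate of the TSS base.
#' @param strand `"+"` or `"-"`.
#' @inheritParams promoter_window
#' @return a [promoter_window()].
#' @examples
#' w <- extract_window(paste(rep("ACGT", 100), collapse = ""), tss = 200)
#' nchar(w$sequence) # 160
#' @export
extract_window <- function(genome_sequence, tss, strand = "+",
                           up = 115L, down = 45L,
                           gene = "gene", promoter_name = "p1") {
  stopifnot(strand %in% c("+", "-"))
  up <- as.integer(up); down <- as.integer(down); tss <- as.integer(tss)
  G <- nchar(genome_sequence)
  if (strand == "+") {
    from <- tss - up       # 0-based inclusive
    to <- tss + down       # 0-based exclusive
  } else {
    from <- tss - down + 1L
    to <- tss + up + 1L
  }
  if (from < 0L || to > G) {
    stop("window [", from, ", ", to, ") out of genome bounds [0, ", G, ")",
         call. = FALSE)
  }
  seq <- toupper(substr(genome_sequence, from + 1L, to))
  .dna_codes(seq)
  if (strand == "-") seq <- .revcomp(seq)
  promoter_window(seq, gene = gene, promoter_name = promoter_name,
                  tss_genomic = tss, strand = strand, up = up, down = down)
}

#' Mutagenesis settings
#'
#' @param rate per-position substitution probability (default 0.1).
#' @param n_variants number of mutated sequences to draw (default 1500).
#' @param include_wildtype prepend the unmutated sequence as variant 1
#'   (default TRUE); the full pool then has `n_variants + 1` members.
#' @param seed integer seed for the generator.
#' @return a `mutagenesis_config` list.
#' @export
mutagenesis_config <- function(rate = 0.1, n_variants = 1500L,
                               include_wildtype = TRUE, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, n_variants >= 1)
  structure(list(rate = rate, n_variants = as.integer(n_variants),
                 include_wildtype = isTRUE(include_wildtype),
                 seed = as.integer(seed)),
            class = "mutagenesis_config")
}

#' Randomly mutagenize a promoter window
#'
#' Each position of each variant is mutated independently with probability
#' `cfg$rate`; a mutated base is replaced by one of the three alternatives
#' chosen uniformly. The result records, per variant, a logical mask of
#' mutated positions.
#'
#' @param window a [promoter_window()].
#' @param cfg a [mutagenesis_config()].
#' @return a `variant_library`: list with `promoter`, `variants` (character
#'   vector, variant 1 = wild type when configured), `masks` (V x L logical
#'   matrix), `seq_matrix` (V x L character matrix) and the config used.
#' @examples
#' w <- extract_window(paste(rep("ACGT", 100), collapse = ""), tss = 200)
#' lib <- mutate_promoter(w, mutagenesis_config(n_variants = 10, seed = 7))
#' rowSums(lib$masks)[1] # wild type: 0 mutations
#' @export
mutate_promoter <- function(window, cfg = mutagenesis_config()) {
  stopifnot(inherits(window, "promoter_window"),
            inherits(cfg, "mutagenesis_config"))
  .check_seed(cfg$seed)
  L <- nchar(window$sequence)
  n <- cfg$n_variants
  wt <- .dna_codes(window$sequence)
  hit <- matrix(runif(n * L) < cfg$rate, nrow = n, ncol = L)
  # offsets 1..3 rotate the wild-type code to one of its three alternatives
  off <- matrix(0L, nrow = n, ncol = L)
  nm <- sum(hit)
  if (nm > 0) off[hit] <- sample.int(3L, nm, replace = TRUE)
  codes <- sweep(off, 2L, wt, "+")
  codes <- ((codes - 1L) %% 4L) + 1L
  chars <- matrix(DNA_BASES[codes], nrow = n, ncol = L)
  variants <- apply(chars, 1L, paste, collapse = "")
  masks <- hit
  if (cfg$include_wildtype) {
    variants <- c(window$sequence, variants)
    masks <- rbind(FALSE, masks)
    chars <- rbind(DNA_BASES[wt], chars)
  }
  rownames(masks) <- NULL
  structure(
    list(promoter = window, variants = variants, masks = masks,
         seq_matrix = chars, config = cfg),
    class = "variant_library")
}

#' @export
print.variant_library <- function(x, ...) {
  cat(sprintf("variant_library: %d variants of %d bp (%s)%s\n",
              length(x$variants), nchar(x$promoter$sequence),
              x$promoter$promoter_name,
              if (x$config$include_wildtype) ", variant 1 = wild type" else ""))
  invisible(x)
}

#' Variant identifiers of a library
#'
#' Stable ids of the form `<promoter>__v<k>`, `k` starting at 0 for the
#' wild type when it is included.
#'
#' @param library a `variant_library`.
#' @return character vector.
#' @export
variant_ids <- function(library) {
  k <- seq_along(library$variants) - 1L
  if (!library$config$include_wildtype) k <- k + 1L
  paste0(library$promoter$promoter_name, "__v", k)
}

# recognition sequences (standard, NEB catalogue)
RESTRICTION_SITES <- c(SpeI = "ACTAGT", ApaI = "GGGCCC",
                       SbfI = "CCTGCAGG", SalI = "GTCGAC")

#' Assemble the synthesis oligo for one promoter variant
#'
#' The ordered oligo is fwd-primer + SpeI site + variant + ApaI site +
#' reverse-primer region. Variants that carry any configured recognition
#' sequence internally are flagged (they would be cut during cloning) but
#' not rejected.
#'
#' @param variant DNA string (the mutagenized promoter sequence).
#' @param primer_fwd,primer_rev flanking amplification primers. The study's
#'   orthogonal primer sequences are not bundled; the defaults are neutral
#'   20-mer placeholders and should be replaced for real orders.
#' @param sites named character vector of recognition sequences; the first
#'   is placed 5' of the variant, the second 3'; all are screened for
#'   internal matches.
#' @param variant_id identifier carried into the construct.
#' @return an `oligo_construct` list with `full_sequence` and `flags`.
#' @export
assemble_oligo <- function(variant,
                           primer_fwd = "GTCCTAAGGTACTGAACTGG",
                           primer_rev = "CCTTCAGGTTCAGACAAGTG",
                           sites = RESTRICTION_SITES[c("SpeI", "ApaI")],
                           variant_id = NA_character_) {
  if (!nzchar(primer_fwd) || !nzchar(primer_rev)) {
    stop("empty primer", call. = FALSE)
  }
  stopifnot(length(sites) >= 2)
  .dna_codes(variant)
  flags <- character(0)
  screen <- RESTRICTION_SITES[unique(c(names(sites), names(RESTRICTION_SITES)))]
  screen <- screen[!is.na(screen)]
  for (nm in names(screen)) {
    if (grepl(screen[[nm]], variant, fixed = TRUE)) {
      flags <- c(flags, paste0("internal_", nm, "_site"))
    }
  }
  full <- paste0(primer_fwd, sites[[1]], variant, sites[[2]], primer_rev)
  structure(list(variant_id = variant_id, full_sequence = full,
                 variant = variant, sites = sites, flags = flags),
            class = "oligo_construct")
}

#' Assign random sequencing barcodes to library variants
#'
#' Emulates the randomized-barcode ligation step: each variant receives a
#' number of unique random `barcode_length`-mers; duplicated barcodes are
#' resampled, so the map is collision-free by construction. Read support per
#' barcode is drawn to mimic mapping-run coverage.
#'
#' @param library a `variant_library`.
#' @param barcodes_per_variant either a single non-negative integer (fixed
#'   count per variant), an integer vector of per-variant counts, or a
#'   function `n -> integer vector` (a count distribution). Default:
#'   Poisson with mean 13, the study-scale median after genome integration.
#' @param barcode_length barcode length in bp (default 20).
#' @param read_support_lambda mean of the Poisson read-support draw
#'   (default 20; supports the mapping-run >= 3 read filter downstream).
#' @param seed integer seed.
#' @return a `barcode_map`: data.table with columns `barcode`,
#'   `variant_id` (integer index into the library), `read_support`.
#' @export
assign_barcodes <- function(library,
                            barcodes_per_variant = function(n) rpois(n, 13),
                            barcode_length = 20L,
                            read_support_lambda = 20,
                            seed = 1L) {
  stopifnot(inherits(library, "variant_library"))
  .check_seed(seed)
  V <- length(library$variants)
  counts <-
    if (is.function(barcodes_per_variant)) {
      as.integer(barcodes_per_variant(V))
    } else if (length(barcodes_per_variant) == 1L) {
      rep(as.integer(barcodes_per_variant), V)
    } else {
      stopifnot(length(barcodes_per_variant) == V)
      as.integer(barcodes_per_variant)
    }
  if (any(counts < 0)) stop("negative barcode count", call. = FALSE)
  total <- sum(counts)
  if (total > 4^barcode_length / 2) {
    stop("requested ", total, " barcodes exceeds half the ",
         barcode_length, "-mer space", call. = FALSE)
  }
  draw <- function(n) {
    if (n == 0L) return(character(0))
    m <- matrix(sample(DNA_BASES, n * barcode_length, replace = TRUE),
                nrow = n)
    apply(m, 1L, paste, collapse = "")
  }
  bc <- draw(total)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- draw(sum(dup))
  }
  map <- data.table::data.table(
    barcode = bc,
    variant_id = rep(seq_len(V), counts),
    read_support = rpois(total, read_support_lambda))
  structure(map, class = c("barcode_map", class(map)),
            seed = seed, barcode_length = as.integer(barcode_length))
}
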