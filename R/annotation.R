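#' Keep variants with potentially large effects
#'
#' Restricts to consequence classes expected to alter protein function:
#' missense, nonsense, splice-site, frameshift, and (as a documented
#' extension) in-frame indels — a single-residue in-frame deletion can
#' abolish enzyme activity and would be discarded by a frameshift-only
#' definition.
#'
#' @param variants A variant table (see [variant-table]).
#' @param include_inframe Keep the `inframe_indel` class (default `TRUE`).
#' @return Filtered variant table.
#' @export
large_effect_filter <- function(variants, include_inframe = TRUE) {
  classes <- large_effect_classes()
  if (!include_inframe) classes <- setdiff(classes, "inframe_indel")
  dplyr::filter(variants, .data$consequence %in% classes)
}

#' Flag variants present in a known-mutation catalog
#'
#' Sets `known_catalog = TRUE` for records matching a catalog entry by
#' positional key `(chrom, pos, ref, alt)` or, failing that, by rsID.
#'
#' @param variants A variant table.
#' @param catalog Catalog tibble from [read_variant_catalog()] (columns
#'   `chrom`, `pos`, `ref`, `alt`, optional `rsid`).
#' @return `variants` with `known_catalog` updated; the number of flagged
#'   records is attached as attribute `n_flagged`.
#' @export
known_catalog_flag <- function(variants, catalog) {
  if (nrow(catalog) == 0) {
    variants$known_catalog <- FALSE
    return(structure(variants, n_flagged = 0L))
  }
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  ckey <- variant_key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  hit <- key %in% ckey
  if ("rsid" %in% names(catalog)) {
    rs <- stats::na.omit(catalog$rsid)
    hit <- hit | (!is.na(variants$var_id) & variants$var_id %in% rs)
  }
  variants$known_catalog <- hit
  structure(variants, n_flagged = sum(hit))
}

#' Allele frequency from printed count/total pairs
#'
#' Computes `allele_count / allele_number` rounded half-up at a
#' caller-chosen number of decimals, reproducing the mixed precisions that
#' population databases print.
#'
#' @param allele_count Non-negative integer(s), at most `allele_number`.
#' @param allele_number Positive integer(s).
#' @param decimals Number of decimal places for half-up rounding.
#' @return Numeric vector of rounded frequencies in \[0, 1\].
#' @examples
#' af_from_counts(2, 140214, 6)   # 0.000014
#' af_from_counts(715, 5008, 4)   # 0.1428
#' @export
af_from_counts <- function(allele_count, allele_number, decimals) {
  if (any(allele_number <= 0)) abort("allele_number must be positive")
  if (any(allele_count < 0) || any(allele_count > allele_number)) {
    abort("allele_count must be in [0, allele_number]")
  }
  round_half_up(allele_count / allele_number, decimals)
}

#' Frequency decisions for every record
#'
#' Computes, per record, the maximum allele frequency over the selected
#' populations and whether it passes a rarity threshold. Records with no
#' frequency data are treated as absent from controls: `max_frequency = 0`,
#' `no_data = TRUE`, pass.
#'
#' @param variants A variant table.
#' @param threshold Maximum tolerated frequency (default 0.005, i.e. 0.5%).
#' @param populations Optional subset of population labels to consider;
#'   unknown labels are fatal, listing the known ones.
#' @return `variants` with added `max_frequency`, `freq_no_data`,
#'   `freq_passed` columns.
#' @export
frequency_decision <- function(variants, threshold = 0.005, populations = NULL) {
  maxf <- max_pop_frequency(variants$pop_freqs, populations)
  no_data <- vapply(variants$pop_freqs, function(pf) {
    is.null(pf) || nrow(pf) == 0 ||
      (!is.null(populations) && !any(pf$population %in% populations))
  }, logical(1))
  variants$max_frequency <- maxf
  variants$freq_no_data <- no_data
  variants$freq_passed <- maxf <= threshold
  variants
}

#' Keep rare variants
#'
#' Filters on the maximum allele frequency across the selected populations
#' (default threshold 0.5%). Absence of frequency data counts as rarity
#' evidence, mirroring the "absent from controls" logic of pathogenicity
#' assessment.
#'
#' @inheritParams frequency_decision
#' @return Records passing the threshold, with the [frequency_decision()]
#'   columns attached.
#' @export
rare_filter <- function(variants, threshold = 0.005, populations = NULL) {
  dec <- frequency_decision(variants, threshold, populations)
  dplyr::filter(dec, .data$freq_passed)
}
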