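#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero at `digits` decimals. Base round() is half-even;
# printed database frequencies follow the half-up convention.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

# Strip a "chr" prefix so hg19 dialects compare equal.
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

is_x_chrom <- function(chrom) normalize_chrom(chrom) %in% c("X", "x", "23")

# Numeric-then-lexical chromosome order (1..22, X, Y, MT, rest).
chrom_rank <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  special <- c(X = 23, Y = 24, MT = 25, M = 25)
  n <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(!is.na(n), n, unname(special[chrom]))
  ifelse(is.na(r), 100 + as.numeric(factor(chrom)), r)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

# Canonical record order used throughout: (chrom, pos, ref, alt).
sort_variants <- function(variants) {
  dplyr::arrange(
    variants,
    chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt
  )
}

# Derive a component-specific RNG seed from a root seed and a text label,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
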