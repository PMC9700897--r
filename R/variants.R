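#' Variant table schema
#'
#' Every pipeline stage consumes and returns a *variant table*: a tibble with
#' one row per (site, ALT allele) and the columns
#'
#' * `chrom`, `pos`, `ref`, `alt` — the positional identity key (VCF 1-based
#'   coordinates, `chr` prefix stripped),
#' * `var_id` — optional rsID (`NA` when absent),
#' * `gene`, `consequence`, `in_functional_domain`, `in_repeat_region`,
#'   `known_catalog`, `hgvs_c`, `hgvs_p` — the parsed annotation bundle,
#' * `pop_freqs` — list-column of tibbles with `population`, `allele_count`,
#'   `allele_number`, `frequency`,
#' * one `gt_<sample>` character column per genotyped pedigree member holding
#'   the VCF genotype string (`"0/1"`, `"1"` for hemizygous calls, `"./."`).
#'
#' @name variant-table
#' @keywords internal
NULL

#' Consequence classes recognized by the pipeline
#'
#' The single-category consequence vocabulary used by the annotation bundle.
#'
#' @return Character vector of valid consequence class labels.
#' @export
consequence_classes <- function() {
  c("missense", "nonsense", "splice_site", "frameshift", "inframe_indel",
    "synonymous", "utr5", "utr3", "upstream", "other")
}

# Consequence classes treated as potentially large-effect. The in-frame
# indel class is included because a single-residue deletion can abolish
# enzyme function while leaving the reading frame intact.
large_effect_classes <- function() {
  c("missense", "nonsense", "splice_site", "frameshift", "inframe_indel")
}

#' Zygosity of a genotype call
#'
#' Derives zygosity from a VCF genotype string, the sample's sex, and the
#' chromosome. On the X chromosome males are hemizygous: a single-allele call
#' (`"1"`) or a concordant diploid spelling (`"1/1"`) maps to `hemi_alt` /
#' `hemi_ref`; a discordant male-X heterozygous call is a QC artifact and is
#' coerced to `missing` with a warning.
#'
#' @param gt Character vector of VCF genotype strings (`"0/1"`, `"1|0"`,
#'   `"1"`, `"./."`, `"."`).
#' @param sex `"male"` or `"female"`, recycled to the length of `gt`.
#' @param chrom Chromosome labels, recycled to the length of `gt`.
#' @return Character vector over `hom_ref`, `het`, `hom_alt`, `hemi_ref`,
#'   `hemi_alt`, `missing`.
#' @examples
#' genotype_zygosity(c("0/1", "1/1", "./."), "female", "7")
#' genotype_zygosity("1", "male", "X")
#' @export
genotype_zygosity <- function(gt, sex, chrom) {
  n <- length(gt)
  sex <- rep_len(sex, n)
  chrom <- rep_len(chrom, n)
  alleles <- strsplit(gsub("\\|", "/", as.character(gt)), "/", fixed = TRUE)
  male_x <- sex == "male" & is_x_chrom(chrom)

  one <- function(al, hemi) {
    al[al == "."] <- NA
    a <- suppressWarnings(as.integer(al))
    if (length(a) == 0 || anyNA(a)) return("missing")
    if (any(a > 1)) return("missing")  # non-biallelic leftovers
    if (hemi) {
      if (length(a) == 1) return(if (a == 1) "hemi_alt" else "hemi_ref")
      if (a[1] != a[2]) return("het_on_male_x")
      return(if (a[1] == 1) "hemi_alt" else "hemi_ref")
    }
    if (length(a) == 1) return(if (a == 1) "het" else "hom_ref")
    s <- sum(a)
    c("hom_ref", "het", "hom_alt")[s + 1]
  }

  z <- vapply(seq_len(n), function(i) one(alleles[[i]], male_x[i]), character(1))
  bad <- z == "het_on_male_x"
  if (any(bad)) {
    warn(sprintf(
      "%d heterozygous male X genotype call(s) coerced to missing", sum(bad)
    ))
    z[bad] <- "missing"
  }
  z
}

# TRUE when the call carries at least one ALT allele.
carries_alt <- function(zyg) zyg %in% c("het", "hom_alt", "hemi_alt")

# Matrix of zygosities, sites x genotyped pedigree members.
zygosity_matrix <- function(variants, pedigree) {
  members <- dplyr::filter(pedigree, .data$genotyped)
  cols <- paste0("gt_", members$sample_id)
  missing_cols <- setdiff(cols, names(variants))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "variant table lacks genotype column(s) for pedigree sample(s): %s",
      paste(sub("^gt_", "", missing_cols), collapse = ", ")
    ))
  }
  m <- vapply(seq_len(nrow(members)), function(i) {
    genotype_zygosity(variants[[cols[i]]], members$sex[i], variants$chrom)
  }, character(nrow(variants)))
  if (nrow(variants) == 1) m <- matrix(m, nrow = 1)
  if (nrow(variants) == 0) m <- matrix(character(0), nrow = 0, ncol = nrow(members))
  colnames(m) <- members$sample_id
  m
}

# Maximum population allele frequency per record over selected populations;
# 0 when there is no frequency data (treated as absent from controls).
max_pop_frequency <- function(pop_freqs, populations = NULL) {
  known <- unique(unlist(lapply(pop_freqs, function(pf) pf$population)))
  if (!is.null(populations)) {
    unknown <- setdiff(populations, known)
    if (length(unknown) > 0) {
      abort(sprintf(
        "unknown population label(s): %s (known: %s)",
        paste(unknown, collapse = ", "),
        if (length(known) > 0) paste(sort(known), collapse = ", ") else "<none>"
      ))
    }
  }
  vapply(pop_freqs, function(pf) {
    if (is.null(pf) || nrow(pf) == 0) return(0)
    if (!is.null(populations)) pf <- pf[pf$population %in% populations, , drop = FALSE]
    if (nrow(pf) == 0) return(0)
    max(pf$frequency)
  }, numeric(1))
}

empty_pop_freqs <- function() {
  tibble(
    population = character(0), allele_count = integer(0),
    allele_number = integer(0), frequency = numeric(0)
  )
}

#' Long genotype view of a variant table
#'
#' Pivot the wide `gt_<sample>` columns into a tidy long table with derived
#' zygosity, one row per (variant, sample).
#'
#' @param variants A variant table (see [variant-table]).
#' @param pedigree A pedigree tibble from [read_pedigree()].
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `sample_id`, `gt`,
#'   `zygosity`.
#' @export
genotypes_long <- function(variants, pedigree) {
  zm <- zygosity_matrix(variants, pedigree)
  members <- dplyr::filter(pedigree, .data$genotyped)
  purrr::map_dfr(seq_len(nrow(members)), function(i) {
    sid <- members$sample_id[i]
    tibble(
      chrom = variants$chrom, pos = variants$pos,
      ref = variants$ref, alt = variants$alt,
      sample_id = sid,
      gt = variants[[paste0("gt_", sid)]],
      zygosity = zm[, sid]
    )
  })
}
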