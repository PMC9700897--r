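#' Write a variant table back to VCF
#'
#' Emits a VCF v4.2 file under the same INFO-key convention that
#' [read_quartet_vcf()] parses, so `read_quartet_vcf(write_quartet_vcf(x))`
#' round-trips to a field-identical record list.
#'
#' @param variants A variant table (see [variant-table]).
#' @param pedigree Pedigree tibble; genotyped members define the sample
#'   column order.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quartet_vcf <- function(variants, pedigree, path) {
  samples <- pedigree$sample_id[pedigree$genotyped]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=DOMAIN,Number=0,Type=Flag,Description=\"In critical functional domain\">",
    "##INFO=<ID=REPEAT,Number=0,Type=Flag,Description=\"In repeat region\">",
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"In known-mutation catalog\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS coding\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein\">",
    unlist(lapply(sort(unique(unlist(lapply(
      variants$pop_freqs, function(pf) pf$population
    )))), function(p) sprintf(
      "##INFO=<ID=AF_%s,Number=2,Type=Integer,Description=\"Allele count,number in %s\">",
      p, p
    ))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  variants <- sort_variants(variants)
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- c(
      sprintf("GENE=%s", v$gene),
      sprintf("CSQCLASS=%s", v$consequence),
      if (isTRUE(v$in_functional_domain)) "DOMAIN",
      if (isTRUE(v$in_repeat_region)) "REPEAT",
      if (isTRUE(v$known_catalog)) "KNOWN",
      if (!is.na(v$hgvs_c)) sprintf("HGVSC=%s", v$hgvs_c),
      if (!is.na(v$hgvs_p)) sprintf("HGVSP=%s", v$hgvs_p)
    )
    pf <- v$pop_freqs[[1]]
    if (!is.null(pf) && nrow(pf) > 0) {
      info <- c(info, sprintf(
        "AF_%s=%d,%d", pf$population, pf$allele_count, pf$allele_number
      ))
    }
    paste(c(
      v$chrom, v$pos, ifelse(is.na(v$var_id), ".", v$var_id), v$ref, v$alt,
      ".", "PASS", paste(info, collapse = ";"), "GT",
      vapply(samples, function(s) v[[paste0("gt_", s)]], character(1))
    ), collapse = "\t")
  }, character(1))

  writeLines(c(header, body), path)
  invisible(path)
}
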