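#' Read an annotated multi-sample VCF into a variant table
#'
#' Parses a VCF v4.x file (plain or bgzipped; low-level parsing by
#' \pkg{vcfR}) whose INFO field follows the pipeline's annotation
#' convention:
#'
#' * `GENE=<symbol>` — gene symbol,
#' * `CSQCLASS=<class>` — one of [consequence_classes()]; comma-separated
#'   per-ALT list allowed at multi-allelic sites,
#' * `AF_<pop>=<count>,<total>` — population allele count and number, one
#'   key per population (e.g. `AF_GnomAD=2,140214`),
#' * `DOMAIN`, `REPEAT`, `KNOWN` — presence flags for functional-domain,
#'   repeat-region and known-catalog membership,
#' * `HGVSC=`, `HGVSP=` — optional HGVS strings.
#'
#' Multi-allelic sites are split into one biallelic record per ALT allele;
#' genotype allele indices are remapped so the ALT of the record is allele 1
#' and any *other* ALT allele counts as non-carriage (0). Indel allele pairs
#' are left-normalized (shared suffix then shared prefix trimmed). Records
#' are returned sorted by `(chrom, pos, ref, alt)`.
#'
#' @param path Path to the VCF file.
#' @param pedigree Pedigree tibble from [read_pedigree()]; every genotyped
#'   member must be a sample column of the VCF (fatal otherwise, naming the
#'   missing sample).
#' @return A variant table (see [variant-table]).
#' @export
read_quartet_vcf <- function(path, pedigree) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- colnames(gt)[-1]

  need <- pedigree$sample_id[pedigree$genotyped]
  missing <- setdiff(need, samples)
  if (length(missing) > 0) {
    abort(sprintf(
      "pedigree sample(s) absent from VCF header: %s",
      paste(missing, collapse = ", ")
    ))
  }

  n <- nrow(fix)
  if (is.null(n) || n == 0) {
    abort("VCF contains no variant records")
  }

  gt_idx <- match("GT", strsplit(gt[1, "FORMAT"], ":", fixed = TRUE)[[1]])
  if (is.na(gt_idx)) abort("VCF FORMAT lacks a GT field")
  gt_strings <- function(i, s) {
    v <- strsplit(gt[i, s], ":", fixed = TRUE)[[1]]
    if (length(v) < gt_idx) "." else v[gt_idx]
  }

  rows <- vector("list", n)
  n_malformed <- 0L
  for (i in seq_len(n)) {
    info <- parse_info(fix[i, "INFO"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    csq <- rep_len(info$csqclass, length(alts))
    raw_gt <- vapply(need, function(s) gt_strings(i, s), character(1))

    sub <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      remapped <- vapply(raw_gt, remap_gt, character(1), alt_index = k)
      bad <- attr_malformed(raw_gt)
      n_malformed <- n_malformed + sum(bad)
      norm <- normalize_allele_pair(
        as.integer(unname(fix[i, "POS"])), unname(fix[i, "REF"]), alts[k]
      )
      vid <- unname(fix[i, "ID"])
      row <- tibble(
        chrom = normalize_chrom(unname(fix[i, "CHROM"])),
        pos = norm$pos, ref = norm$ref, alt = norm$alt,
        var_id = if (is.na(vid) || vid == ".") NA_character_ else vid,
        gene = info$gene,
        consequence = csq[k],
        in_functional_domain = info$domain,
        in_repeat_region = info$repeat_region,
        known_catalog = info$known,
        hgvs_c = info$hgvs_c, hgvs_p = info$hgvs_p,
        pop_freqs = list(info$pop_freqs)
      )
      for (s in need) row[[paste0("gt_", s)]] <- unname(remapped[s])
      sub[[k]] <- row
    }
    rows[[i]] <- dplyr::bind_rows(sub)
  }
  if (n_malformed > 0) {
    warn(sprintf("%d malformed genotype call(s) set to missing", n_malformed))
  }
  sort_variants(dplyr::bind_rows(rows))
}

# Parse one INFO string under the documented key convention.
parse_info <- function(info) {
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else NA_character_, character(1))
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_

  af_keys <- keys[startsWith(keys, "AF_")]
  pf <- if (length(af_keys) > 0) {
    purrr::map_dfr(af_keys, function(k) {
      ct <- as.numeric(strsplit(vals[match(k, keys)], ",", fixed = TRUE)[[1]])
      tibble(
        population = sub("^AF_", "", k),
        allele_count = as.integer(ct[1]),
        allele_number = as.integer(ct[2]),
        frequency = ct[1] / ct[2]
      )
    })
  } else {
    empty_pop_freqs()
  }

  list(
    gene = get("GENE"),
    csqclass = strsplit(get("CSQCLASS") %||% "other", ",", fixed = TRUE)[[1]],
    domain = "DOMAIN" %in% keys,
    repeat_region = "REPEAT" %in% keys,
    known = "KNOWN" %in% keys,
    hgvs_c = get("HGVSC"),
    hgvs_p = get("HGVSP"),
    pop_freqs = pf
  )
}

# Remap a genotype string so `alt_index` becomes allele 1 and any other ALT
# counts as 0 (non-carriage of this record's ALT). Malformed -> "./.".
remap_gt <- function(g, alt_index) {
  if (is.na(g) || g == "") return("./.")
  parts <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
  if (length(parts) < 1 || length(parts) > 2) return("./.")
  mapped <- vapply(parts, function(a) {
    if (a == ".") return(".")
    ai <- suppressWarnings(as.integer(a))
    if (is.na(ai) || ai < 0) return("BAD")
    if (ai == alt_index) "1" else "0"
  }, character(1))
  if (any(mapped == "BAD")) return("./.")
  if (all(mapped == ".")) return("./.")  # canonical missing spelling
  if (length(mapped) == 2 && all(mapped != ".")) {
    mapped <- as.character(sort(as.integer(mapped)))
  }
  paste(mapped, collapse = "/")
}

# Which raw genotype strings are malformed (non-numeric, wrong arity).
# A missing call (NA from the parser, or "." spellings) is valid, not
# malformed.
attr_malformed <- function(raw_gt) {
  vapply(raw_gt, function(g) {
    if (is.na(g)) return(FALSE)
    if (g == "") return(TRUE)
    parts <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(parts) < 1 || length(parts) > 2) return(TRUE)
    any(vapply(parts, function(a) {
      a != "." && is.na(suppressWarnings(as.integer(a)))
    }, logical(1)))
  }, logical(1))
}

# Left-normalize an allele pair: trim shared suffix, then shared prefix
# (keeping at least one base each), adjusting pos for trimmed prefix.
normalize_allele_pair <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}
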