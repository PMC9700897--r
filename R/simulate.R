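#' Simulation configuration for a synthetic quartet exome
#'
#' Defines the study conditions emulated by the generator: a family quartet
#' (two affected brothers, unaffected father and sister) whose mother is
#' simulated explicitly but withheld from output (her genotypes live only in
#' the truth table), with a spiked heterozygous in-frame deletion carried by
#' the affected brothers only and transmitted maternally.
#'
#' @param n_sites Number of background variant sites (default 2000).
#' @param n_genes Number of gene labels (default 200).
#' @param seed Root seed; per-component substreams are derived from it by
#'   fixed labels, so each generator is a pure function of (config, seed).
#' @param x_fraction Fraction of sites on the X chromosome (default 0.05).
#' @param p_common Mixture weight of common sites (default 0.7); common
#'   allele frequencies are Beta(2,2) scaled into \[0.1, 0.5\], rare ones
#'   log-uniform in \[1e-5, 0.005\].
#' @param consequence_mix Named probability vector over
#'   [consequence_classes()] (must sum to 1).
#' @param p_domain,p_repeat Per-site probabilities of the functional-domain
#'   and repeat-region annotation flags.
#' @param causal Causal-variant specification: gene label, chromosome,
#'   position, ref/alt alleles, consequence class, and population counts
#'   (defaults give a GnomAD-style frequency below 1e-5).
#' @param erythroid Erythroid library sizing as fractions of `n_genes`
#'   (defaults mirror libraries of 701 and 654 genes sharing 201 out of a
#'   ~2000-gene background: 0.35, 0.33, 0.10).
#' @param assay Assay simulation parameters: `control_activity` (pmol
#'   phosphate / mg Hb / min), `patient_fold_change` (named vector for the
#'   two patients), `hb_mg_per_ml` (undiluted hemolysate), `noise_sd`
#'   (absorbance noise), `dilution_factor`, `baseline_nmol` (zero-time
#'   background phosphate per reaction), `slope` and `blank_abs` of the
#'   detection chemistry.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 2000,
                       n_genes = 200,
                       seed = 1,
                       x_fraction = 0.05,
                       p_common = 0.7,
                       consequence_mix = c(
                         missense = 0.30, synonymous = 0.30, utr5 = 0.04,
                         utr3 = 0.08, upstream = 0.05, splice_site = 0.02,
                         nonsense = 0.02, frameshift = 0.02,
                         inframe_indel = 0.02, other = 0.15
                       ),
                       p_domain = 0.05,
                       p_repeat = 0.10,
                       causal = list(
                         gene = "NT5C3A", chrom = "7", pos = 33017549L,
                         ref = "TGTT", alt = "T",
                         consequence = "inframe_indel",
                         hgvs_c = "c.444_446delGTT", hgvs_p = "p.Phe149del",
                         gnomad_count = 1L, gnomad_number = 140214L
                       ),
                       erythroid = list(
                         early_frac = 0.35, late_frac = 0.33, overlap_frac = 0.10
                       ),
                       assay = list(
                         control_activity = 130,
                         patient_fold_change = c(RK = 0.21, MK = 0.07),
                         relative_activity = c(AK = 0.95, EK = 1.0),
                         hb_mg_per_ml = 160,
                         dilution_factor = 2.5,
                         baseline_nmol = 20,
                         slope = 0.05,
                         blank_abs = 0.045,
                         noise_sd = 0
                       )) {
  stopifnot(n_sites >= 1, n_genes >= 10)
  if (abs(sum(consequence_mix) - 1) > 1e-8) {
    abort("consequence_mix probabilities must sum to 1")
  }
  if (!all(names(consequence_mix) %in% consequence_classes())) {
    abort("consequence_mix has labels outside consequence_classes()")
  }
  structure(
    list(
      n_sites = n_sites, n_genes = n_genes, seed = seed,
      x_fraction = x_fraction, p_common = p_common,
      consequence_mix = consequence_mix,
      p_domain = p_domain, p_repeat = p_repeat,
      causal = causal, erythroid = erythroid, assay = assay
    ),
    class = "sim_config"
  )
}

# The fixed quartet pedigree: brothers RK and MK affected, father AK and
# sister EK unaffected, mother present but ungenotyped.
quartet_pedigree <- function() {
  tibble(
    sample_id = c("RK", "MK", "EK", "AK", "FAM.mother"),
    sex = c("male", "male", "female", "male", "female"),
    affected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    father_id = c("AK", "AK", "AK", NA, NA),
    mother_id = c("FAM.mother", "FAM.mother", "FAM.mother", NA, NA),
    genotyped = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Simulate a quartet exome with a spiked causal deletion
#'
#' Founder genotypes are drawn under Hardy-Weinberg equilibrium at each
#' site's simulated allele frequency; children are produced by Mendelian
#' transmission (sons inherit their single X allele from the latent
#' mother). The causal in-frame deletion is spiked heterozygous into both
#' affected brothers with maternal transmission, absent from the father and
#' sister, annotated as located in a functional domain outside a repeat,
#' and given a population frequency below 1e-5.
#'
#' @param config A [sim_config()].
#' @return A `quartet_sim` list: `variants` (variant table, sorted),
#'   `pedigree`, `truth` (per-site tibble with true allele frequency, the
#'   withheld maternal genotype, and `causal` flag), `catalog` (known-site
#'   catalog tibble drawn from the simulated sites), and `causal_key`.
#' @export
simulate_quartet <- function(config = sim_config()) {
  n <- config$n_sites
  set.seed(derive_seed(config$seed, "sites"))

  on_x <- stats::runif(n) < config$x_fraction
  chrom <- ifelse(on_x, "X", as.character(sample(1:22, n, replace = TRUE)))
  pos <- integer(n)
  for (c_lab in unique(chrom)) {
    i <- chrom == c_lab
    pos[i] <- sort(sample.int(5e7, sum(i)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  common <- stats::runif(n) < config$p_common
  af <- ifelse(
    common,
    0.1 + 0.4 * stats::rbeta(n, 2, 2),
    10^stats::runif(n, log10(1e-5), log10(0.005))
  )

  set.seed(derive_seed(config$seed, "genotypes"))
  draw <- function(p) stats::rbinom(n, 1, p)
  fa1 <- draw(af); fa2 <- draw(af)   # father (fa1 is his X allele on X)
  ma1 <- draw(af); ma2 <- draw(af)   # latent mother
  pick <- function(a1, a2) ifelse(stats::runif(n) < 0.5, a1, a2)
  rk_pat <- pick(fa1, fa2); rk_mat <- pick(ma1, ma2)
  mk_pat <- pick(fa1, fa2); mk_mat <- pick(ma1, ma2)
  ek_pat <- pick(fa1, fa2); ek_mat <- pick(ma1, ma2)
  # X: sons carry only the maternal allele, the daughter gets the paternal X
  ek_pat[on_x] <- fa1[on_x]

  gt_auto <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  gt_male <- function(pat, mat) ifelse(on_x, as.character(mat), gt_auto(pat, mat))
  gt_rk <- gt_male(rk_pat, rk_mat)
  gt_mk <- gt_male(mk_pat, mk_mat)
  gt_ek <- gt_auto(ek_pat, ek_mat)
  gt_ak <- ifelse(on_x, as.character(fa1), gt_auto(fa1, fa2))
  gt_mo <- gt_auto(ma1, ma2)

  set.seed(derive_seed(config$seed, "annotations"))
  gene_labels <- sprintf("GENE%03d", seq_len(config$n_genes))
  gene <- sample(gene_labels, n, replace = TRUE)
  consequence <- sample(
    names(config$consequence_mix), n, replace = TRUE,
    prob = config$consequence_mix
  )
  in_domain <- stats::runif(n) < config$p_domain
  in_repeat <- stats::runif(n) < config$p_repeat

  gnomad_an <- 140214L
  kg_an <- 5008L
  gnomad_ac <- pmin(stats::rbinom(n, gnomad_an, af), gnomad_an)
  kg_ac <- pmin(stats::rbinom(n, kg_an, af), kg_an)
  pop_freqs <- purrr::map(seq_len(n), function(i) {
    tibble(
      population = c("GnomAD", "1000G"),
      allele_count = c(gnomad_ac[i], kg_ac[i]),
      allele_number = c(gnomad_an, kg_an),
      frequency = c(gnomad_ac[i] / gnomad_an, kg_ac[i] / kg_an)
    )
  })

  variants <- tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    var_id = NA_character_,
    gene = gene, consequence = consequence,
    in_functional_domain = in_domain, in_repeat_region = in_repeat,
    known_catalog = FALSE,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    pop_freqs = pop_freqs,
    gt_RK = gt_rk, gt_MK = gt_mk, gt_EK = gt_ek, gt_AK = gt_ak
  )

  cz <- config$causal
  if (cz$gene %in% gene_labels) {
    abort("causal gene label collides with a background gene label")
  }
  causal_row <- tibble(
    chrom = normalize_chrom(cz$chrom), pos = as.integer(cz$pos),
    ref = cz$ref, alt = cz$alt, var_id = NA_character_,
    gene = cz$gene, consequence = cz$consequence,
    in_functional_domain = TRUE, in_repeat_region = FALSE,
    known_catalog = FALSE,
    hgvs_c = cz$hgvs_c, hgvs_p = cz$hgvs_p,
    pop_freqs = list(tibble(
      population = "GnomAD",
      allele_count = cz$gnomad_count, allele_number = cz$gnomad_number,
      frequency = cz$gnomad_count / cz$gnomad_number
    )),
    gt_RK = "0/1", gt_MK = "0/1", gt_EK = "0/0", gt_AK = "0/0"
  )
  if (is_x_chrom(cz$chrom)) {
    abort("causal spec must be autosomal: brothers are het, not hemizygous")
  }

  truth <- tibble(
    chrom = c(chrom, causal_row$chrom), pos = c(pos, causal_row$pos),
    ref = c(ref, causal_row$ref), alt = c(alt, causal_row$alt),
    af = c(af, cz$gnomad_count / cz$gnomad_number),
    mother_gt = c(gt_mo, "0/1"),
    causal = c(rep(FALSE, n), TRUE)
  )

  set.seed(derive_seed(config$seed, "catalog"))
  known_idx <- sample.int(n, max(1, round(0.05 * n)))
  catalog <- tibble(
    chrom = chrom[known_idx], pos = pos[known_idx],
    ref = ref[known_idx], alt = alt[known_idx],
    rsid = sprintf("rs%07d", known_idx), label = "simulated_known_site"
  )

  variants <- sort_variants(dplyr::bind_rows(variants, causal_row))
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  dup <- duplicated(key)
  if (any(dup)) {
    variants <- variants[!dup, , drop = FALSE]
  }

  structure(
    list(
      variants = variants,
      pedigree = quartet_pedigree(),
      truth = truth,
      catalog = catalog,
      causal_key = variant_key(
        causal_row$chrom, causal_row$pos, causal_row$ref, causal_row$alt
      )
    ),
    class = "quartet_sim"
  )
}

#' Simulate panels, erythroid libraries and a pathway table
#'
#' Constructs clinical gene panels (the causal gene sits in the
#' enzymopathy panel), early/late erythroid expression libraries with an
#' exact configured overlap containing the causal gene, and a pathway
#' table whose pyrimidine-metabolism pathway contains the causal gene plus
#' decoys.
#'
#' @param config A [sim_config()].
#' @return List with `panels` (named list of [gene_set()]s), `early`,
#'   `late`, `pathways` ([pathway_table()]), `universe`.
#' @export
simulate_gene_sets <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, "gene_sets"))
  gene_labels <- sprintf("GENE%03d", seq_len(config$n_genes))
  causal <- config$causal$gene
  universe <- c(gene_labels, causal)

  n_early <- round(config$erythroid$early_frac * config$n_genes)
  n_late <- round(config$erythroid$late_frac * config$n_genes)
  n_both <- round(config$erythroid$overlap_frac * config$n_genes)
  if (n_both > min(n_early, n_late)) {
    abort("requested erythroid overlap exceeds a library size")
  }

  pool <- sample(gene_labels)
  both <- c(causal, pool[seq_len(n_both - 1)])
  pool <- pool[-seq_len(n_both - 1)]
  early_only <- pool[seq_len(n_early - n_both)]
  pool <- pool[-seq_len(n_early - n_both)]
  late_only <- pool[seq_len(n_late - n_both)]

  early <- gene_set(c(both, early_only), "erythroid_early")
  late <- gene_set(c(both, late_only), "erythroid_late")

  panels <- list(
    enzymopathy = gene_set(c(causal, sample(gene_labels, 13)), "enzymopathy"),
    membranopathy = gene_set(sample(gene_labels, 9), "membranopathy"),
    hemoglobinopathy = gene_set(sample(gene_labels, 3), "hemoglobinopathy")
  )

  pyr <- c(causal, sample(gene_labels, 9))
  other_paths <- purrr::map(seq_len(19), function(i) {
    tibble(
      pathway = sprintf("pathway_%02d", i),
      gene = sample(gene_labels, sample(5:20, 1))
    )
  })
  pathways <- pathway_table(
    dplyr::bind_rows(
      tibble(pathway = "pyrimidine_metabolism", gene = pyr),
      dplyr::bind_rows(other_paths)
    ),
    universe = universe
  )

  list(
    panels = panels, early = early, late = late,
    pathways = pathways, universe = universe
  )
}

#' Simulate an assay plate with programmed activities
#'
#' Forward-computes well absorbances from programmed specific activities
#' (control group at `assay$control_activity`; the patients at their
#' programmed fold changes; other family members near 1), the hemoglobin
#' mass and volume bookkeeping, and the detection chemistry (blank +
#' linear phosphate response), plus optional Gaussian absorbance noise.
#' At zero noise the activity pipeline inverts this construction exactly.
#'
#' @param config A [sim_config()].
#' @return List: `plate` (well tibble for [specific_activity()]), `hb`
#'   (named mg/mL vector), `truth` (programmed activities and fold
#'   changes), `volumes`, `incubation_minutes`.
#' @export
simulate_assay_plate <- function(config = sim_config()) {
  a <- config$assay
  set.seed(derive_seed(config$seed, "assay"))
  volumes <- assay_volumes()
  incubation <- 120
  scale <- well_to_reaction_factor(volumes)

  controls <- stats::setNames(
    rep(a$control_activity, 4), paste0("Ctrl", 1:4)
  )
  family <- c(
    a$control_activity * a$patient_fold_change,
    a$control_activity * a$relative_activity
  )
  activities <- c(controls, family)
  samples <- names(activities)

  hb <- stats::setNames(rep(a$hb_mg_per_ml, length(samples)), samples)
  hb_mg_rxn <- hb * (volumes$hemolysate_uL / 1000) / a$dilution_factor

  released_nmol <- activities * hb_mg_rxn * incubation / 1000
  zero_well_nmol <- a$baseline_nmol / scale
  rxn_well_nmol <- (a$baseline_nmol + released_nmol) / scale

  noise <- function(k) stats::rnorm(k, 0, a$noise_sd)
  cal_pi <- c(0, 2, 4, 6, 8, 10)
  plate <- dplyr::bind_rows(
    tibble(
      well = sprintf("BL%d", 1:2), sample_id = NA_character_, role = "blank",
      absorbance_750 = a$blank_abs + noise(2),
      dilution_factor = NA_real_, pi_nmol = NA_real_
    ),
    tibble(
      well = sprintf("CAL%d", seq_along(cal_pi)), sample_id = NA_character_,
      role = "calibration",
      absorbance_750 = a$blank_abs + a$slope * cal_pi + noise(length(cal_pi)),
      dilution_factor = NA_real_, pi_nmol = cal_pi
    ),
    tibble(
      well = sprintf("R%02d", seq_along(samples)), sample_id = samples,
      role = "reaction",
      absorbance_750 = a$blank_abs + a$slope * rxn_well_nmol + noise(length(samples)),
      dilution_factor = a$dilution_factor, pi_nmol = NA_real_
    ),
    tibble(
      well = sprintf("Z%02d", seq_along(samples)), sample_id = samples,
      role = "zero_time",
      absorbance_750 = a$blank_abs + a$slope * zero_well_nmol + noise(length(samples)),
      dilution_factor = a$dilution_factor, pi_nmol = NA_real_
    )
  )

  truth <- tibble(
    sample_id = samples,
    programmed_activity = unname(activities),
    programmed_fold = unname(activities) / a$control_activity
  )
  list(
    plate = plate, hb = hb, truth = truth,
    volumes = volumes, incubation_minutes = incubation
  )
}

#' Write a simulated quartet to VCF and PED files
#'
#' @param sim A `quartet_sim` from [simulate_quartet()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the `vcf` and `ped` paths, invisibly.
#' @export
write_quartet <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, "sim.vcf")
  ped <- file.path(dir, "sim.ped")
  write_quartet_vcf(sim$variants, sim$pedigree, vcf)
  ped_rows <- sim$pedigree[sim$pedigree$genotyped, ]
  lines <- vapply(seq_len(nrow(ped_rows)), function(i) {
    r <- ped_rows[i, ]
    paste(
      "FAM",
      r$sample_id,
      ifelse(is.na(r$father_id), "0", r$father_id),
      "0",  # the mother is ungenotyped: unrecorded in PED
      ifelse(r$sex == "male", "1", "2"),
      ifelse(r$affected, "2", "1"),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, ped)
  invisible(c(vcf = vcf, ped = ped))
}
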