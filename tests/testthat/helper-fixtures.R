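# Fixtures and independent oracles. The oracles deliberately re-derive
# zygosity and predicates from genotype strings by direct per-site logic,
# independent of the package's vectorized code paths.

quartet_ped <- function() {
  tibble::tibble(
    sample_id = c("RK", "MK", "EK", "AK", "FAM.mother"),
    sex = c("male", "male", "female", "male", "female"),
    affected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    father_id = c("AK", "AK", "AK", NA, NA),
    mother_id = c("FAM.mother", "FAM.mother", "FAM.mother", NA, NA),
    genotyped = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

# A minimal variant row; genotypes given as named list, e.g.
# list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/0").
mk_variant <- function(chrom = "1", pos = 100, ref = "A", alt = "T",
                       gene = "GENE001", consequence = "missense",
                       domain = FALSE, rep_region = FALSE,
                       pop = NULL, gt = list(RK = "0/1", MK = "0/1",
                                             EK = "0/0", AK = "0/0"),
                       var_id = NA_character_) {
  pf <- if (is.null(pop)) {
    tibble::tibble(population = character(0), allele_count = integer(0),
                   allele_number = integer(0), frequency = numeric(0))
  } else {
    pop
  }
  row <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    var_id = var_id, gene = gene, consequence = consequence,
    in_functional_domain = domain, in_repeat_region = rep_region,
    known_catalog = FALSE, hgvs_c = NA_character_, hgvs_p = NA_character_,
    pop_freqs = list(pf)
  )
  for (s in names(gt)) row[[paste0("gt_", s)]] <- gt[[s]]
  row
}

pop_entry <- function(population, count, number) {
  tibble::tibble(
    population = population, allele_count = as.integer(count),
    allele_number = as.integer(number), frequency = count / number
  )
}

# Random quartet genotype table for oracle comparisons (male X kept clean:
# no heterozygous male X calls; those are tested separately).
rand_quartet_variants <- function(n, seed, p_x = 0.2, p_missing = 0.05,
                                  n_genes = 8) {
  set.seed(seed)
  on_x <- stats::runif(n) < p_x
  chrom <- ifelse(on_x, "X", as.character(sample(1:5, n, replace = TRUE)))
  auto_gt <- function(k) sample(
    c("0/0", "0/1", "1/1", "./."), k, replace = TRUE,
    prob = c(0.4, 0.3, 0.3 - p_missing, p_missing)
  )
  male_gt <- function(k) sample(
    c("0", "1", "./."), k, replace = TRUE, prob = c(0.5, 0.5 - p_missing, p_missing)
  )
  gts <- function(male) {
    g <- auto_gt(n)
    if (male) g[on_x] <- male_gt(sum(on_x))
    g
  }
  rows <- tibble::tibble(
    chrom = chrom, pos = seq_len(n) * 10L, ref = "A", alt = "T",
    var_id = NA_character_,
    gene = sample(sprintf("G%02d", seq_len(n_genes)), n, replace = TRUE),
    consequence = sample(consequence_classes(), n, replace = TRUE),
    in_functional_domain = stats::runif(n) < 0.2,
    in_repeat_region = stats::runif(n) < 0.2,
    known_catalog = FALSE, hgvs_c = NA_character_, hgvs_p = NA_character_,
    pop_freqs = replicate(n, pop_entry("GnomAD", sample(0:50, 1), 10000),
                          simplify = FALSE),
    gt_RK = gts(TRUE), gt_MK = gts(TRUE), gt_EK = gts(FALSE), gt_AK = gts(TRUE)
  )
  rows
}

# --- oracle zygosity / carriage, direct string logic --------------------

oracle_zyg <- function(g, male, on_x) {
  g <- gsub("|", "/", g, fixed = TRUE)
  if (male && on_x) {
    if (g %in% c("1", "1/1")) return("hemi_alt")
    if (g %in% c("0", "0/0")) return("hemi_ref")
    return("missing")
  }
  switch(g,
    "0/0" = "hom_ref", "0/1" = "het", "1/0" = "het", "1/1" = "hom_alt",
    "0" = "hom_ref", "1" = "het",
    "missing"
  )
}

oracle_site_zyg <- function(row, ped) {
  ped <- ped[ped$genotyped, ]
  z <- vapply(seq_len(nrow(ped)), function(i) {
    oracle_zyg(
      row[[paste0("gt_", ped$sample_id[i])]],
      ped$sex[i] == "male",
      row$chrom %in% c("X", "x")
    )
  }, character(1))
  names(z) <- ped$sample_id
  z
}

oracle_carries <- function(z) z %in% c("het", "hom_alt", "hemi_alt")

oracle_shared <- function(variants, ped) {
  aff <- ped$sample_id[ped$affected & ped$genotyped]
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    z <- oracle_site_zyg(variants[i, ], ped)
    all(oracle_carries(z[aff]))
  }, logical(1))
  variants[keep, , drop = FALSE]
}

oracle_rec_x_model <- function(variants, ped) {
  pedg <- ped[ped$genotyped, ]
  aff <- pedg$sample_id[pedg$affected]
  unaff <- pedg$sample_id[!pedg$affected]
  sex <- stats::setNames(pedg$sex, pedg$sample_id)
  vapply(seq_len(nrow(variants)), function(i) {
    z <- oracle_site_zyg(variants[i, ], ped)
    if (variants$chrom[i] %in% c("X", "x")) {
      ok_a <- all(vapply(aff, function(s) {
        if (sex[s] == "male") z[s] == "hemi_alt" else z[s] == "hom_alt"
      }, logical(1)))
      ok_u <- all(vapply(unaff, function(s) {
        if (sex[s] == "male") z[s] == "hemi_ref" else z[s] %in% c("het", "hom_ref")
      }, logical(1)))
      if (ok_a && ok_u) "x_linked" else NA_character_
    } else {
      if (all(z[aff] == "hom_alt") && all(z[unaff] %in% c("het", "hom_ref"))) {
        "recessive_hom"
      } else {
        NA_character_
      }
    }
  }, character(1))
}

# Pairwise-enumeration compound-het oracle: nested loops over all het-pair
# combinations per gene, applying the predicates verbatim.
oracle_comphet <- function(variants, ped, min_variants = 2) {
  pedg <- ped[ped$genotyped, ]
  aff <- pedg$sample_id[pedg$affected]
  unaff <- pedg$sample_id[!pedg$affected]
  aff_parents <- unique(stats::na.omit(unlist(
    ped[ped$affected & ped$genotyped, c("father_id", "mother_id")]
  )))
  parents <- intersect(aff_parents, pedg$sample_id)

  zl <- lapply(seq_len(nrow(variants)), function(i) oracle_site_zyg(variants[i, ], ped))
  het_all <- vapply(zl, function(z) all(z[aff] == "het"), logical(1))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")

  out <- NULL
  for (g in unique(variants$gene)) {
    gi <- which(variants$gene == g & het_all)
    gi <- gi[!duplicated(key[gi])]
    if (length(gi) < min_variants) next
    for (a in seq_along(gi)) {
      for (b in seq_along(gi)) {
        if (b <= a) next
        i1 <- gi[a]; i2 <- gi[b]
        carried <- function(i, s) oracle_carries(zl[[i]][s])
        combo <- any(vapply(unaff, function(s) carried(i1, s) && carried(i2, s), logical(1)))
        if (combo) next
        if (length(parents) == 1) {
          p <- parents
          if (carried(i1, p) && carried(i2, p)) {
            status <- "phase_unresolved"; note <- "unphased"
          } else if (xor(carried(i1, p), carried(i2, p))) {
            status <- "candidate"; note <- "one_parent_each"
          } else {
            status <- "phase_unresolved"; note <- "maternal_implied"
          }
        } else {
          status <- "candidate"; note <- "unphased"
        }
        out <- rbind(out, data.frame(
          gene = g, key1 = key[i1], key2 = key[i2],
          phase_note = note, status = status
        ))
      }
    }
  }
  out
}

# Exhaustive subset-enumeration hypergeometric oracle (universe <= 15):
# fraction of all query-sized subsets with overlap >= k.
oracle_hyper_enum <- function(universe_size, pathway_size, query_size, k) {
  sets <- utils::combn(universe_size, query_size)
  inside <- seq_len(pathway_size)  # wlog the first pathway_size elements
  hits <- apply(sets, 2, function(s) sum(s %in% inside) >= k)
  mean(hits)
}

# Summation oracle: sum of hypergeometric point masses from factorials.
oracle_hyper_sum <- function(universe_size, pathway_size, query_size, k) {
  kk <- max(0, k):min(pathway_size, query_size)
  sum(choose(pathway_size, kk) *
        choose(universe_size - pathway_size, query_size - kk)) /
    choose(universe_size, query_size)
}
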