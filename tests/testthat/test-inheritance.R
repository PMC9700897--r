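test_that("zygosity derives from genotype, sex and chromosome", {
  expect_equal(
    genotype_zygosity(c("0/0", "0/1", "1/1", "./."), "female", "7"),
    c("hom_ref", "het", "hom_alt", "missing")
  )
  expect_equal(genotype_zygosity("1", "male", "X"), "hemi_alt")
  expect_equal(genotype_zygosity("1/1", "male", "chrX"), "hemi_alt")
  expect_equal(genotype_zygosity("0", "male", "X"), "hemi_ref")
  expect_equal(genotype_zygosity("1", "male", "7"), "het")
})

test_that("heterozygous male X calls are coerced to missing with a warning", {
  expect_warning(z <- genotype_zygosity("0/1", "male", "X"), "male X")
  expect_equal(z, "missing")
})

test_that("a missing call in an affected member is not carriage", {
  ped <- quartet_ped()
  v <- mk_variant(gt = list(RK = "0/1", MK = "./.", EK = "0/0", AK = "0/0"))
  expect_equal(nrow(shared_variants(v, ped)), 0)
})

test_that("variants het in both brothers and absent elsewhere are shared", {
  ped <- quartet_ped()
  v <- mk_variant(gt = list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/0"))
  expect_equal(nrow(shared_variants(v, ped)), 1)
  m <- assign_inheritance(v, ped)
  expect_equal(m$model, "shared_het")
  expect_equal(m$phase_note, "maternal_implied")
})

test_that("shared_variants refuses a pedigree without affected members", {
  ped <- quartet_ped()
  ped$affected <- FALSE
  expect_error(shared_variants(mk_variant(), ped), "affected")
})

test_that("X-linked hemizygous pattern with a carrier sister is kept", {
  ped <- quartet_ped()
  v <- mk_variant(chrom = "X",
                  gt = list(RK = "1", MK = "1", EK = "0/1", AK = "0"))
  res <- recessive_or_xlinked(v, ped)
  expect_equal(nrow(res), 1)
  expect_equal(res$model, "x_linked")
})

test_that("an unaffected homozygote breaks the recessive model", {
  ped <- quartet_ped()
  v <- mk_variant(gt = list(RK = "1/1", MK = "1/1", EK = "1/1", AK = "0/1"))
  expect_equal(nrow(recessive_or_xlinked(v, ped)), 0)
  v2 <- mk_variant(gt = list(RK = "1/1", MK = "1/1", EK = "0/1", AK = "0/1"))
  res <- recessive_or_xlinked(v2, ped)
  expect_equal(res$model, "recessive_hom")
})

test_that("inheritance filters match the brute-force per-site oracle", {
  ped <- quartet_ped()
  for (seed in 1:10) {
    v <- rand_quartet_variants(100, seed = seed)
    sh <- shared_variants(v, ped)
    osh <- oracle_shared(v, ped)
    expect_equal(as.data.frame(sh), as.data.frame(osh), info = paste("seed", seed))

    rx <- recessive_or_xlinked(sh, ped)
    om <- oracle_rec_x_model(sh, ped)
    expect_equal(rx$model, om[!is.na(om)], info = paste("seed", seed))
    expect_equal(
      paste(rx$chrom, rx$pos), paste(sh$chrom, sh$pos)[!is.na(om)],
      info = paste("seed", seed)
    )
  }
})

test_that("the quartet compound-het pattern resolves one parent each", {
  ped <- quartet_ped()
  # v1 absent from the father (maternal-implied), v2 carried by the father
  v <- dplyr::bind_rows(
    mk_variant(chrom = "22", pos = 100, gene = "TYMP",
               gt = list(RK = "0/1", MK = "0/1", EK = "0/1", AK = "0/0")),
    mk_variant(chrom = "22", pos = 200, ref = "G", alt = "A", gene = "TYMP",
               gt = list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/1"))
  )
  ch <- compound_het_candidates(v, ped)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$gene, "TYMP")
  expect_equal(ch$status, "candidate")
  expect_equal(ch$phase_note, "one_parent_each")
})

test_that("a single het variant in a gene is not a compound-het candidate", {
  ped <- quartet_ped()
  v <- mk_variant(gene = "TYMP")
  expect_equal(nrow(compound_het_candidates(v, ped)), 0)
})

test_that("a pair fully carried by an unaffected member is excluded", {
  ped <- quartet_ped()
  # the unaffected father carries the full combination: under the compound
  # het model he would be affected, so the pair is rejected outright
  v <- dplyr::bind_rows(
    mk_variant(pos = 100, gene = "G1",
               gt = list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/1")),
    mk_variant(pos = 200, ref = "G", alt = "C", gene = "G1",
               gt = list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/1"))
  )
  expect_equal(nrow(compound_het_candidates(v, ped)), 0)
})

test_that("a pair absent from the genotyped father is cis-implied, phase-unresolved", {
  ped <- quartet_ped()
  # neither variant in the father: both must ride the single transmitted
  # maternal homolog, so the pair cannot be in trans
  v <- dplyr::bind_rows(
    mk_variant(pos = 100, gene = "G1",
               gt = list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/0")),
    mk_variant(pos = 200, ref = "G", alt = "C", gene = "G1",
               gt = list(RK = "0/1", MK = "0/1", EK = "0/0", AK = "0/0"))
  )
  ch <- compound_het_candidates(v, ped)
  expect_equal(ch$status, "phase_unresolved")
  expect_equal(ch$phase_note, "maternal_implied")
})

test_that("compound-het detection matches the pairwise-enumeration oracle", {
  ped <- quartet_ped()
  for (seed in 11:25) {
    v <- rand_quartet_variants(200, seed = seed, p_x = 0, n_genes = 20)
    got <- compound_het_candidates(v, ped)
    want <- oracle_comphet(v, ped)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = paste("seed", seed))
    } else {
      got_df <- as.data.frame(got[order(got$gene, got$key1, got$key2), ])
      want_df <- want[order(want$gene, want$key1, want$key2), ]
      rownames(got_df) <- rownames(want_df) <- NULL
      expect_equal(got_df, want_df, info = paste("seed", seed))
    }
  }
})

test_that("with both parents genotyped every candidate pair is one per parent", {
  # full trio-like family: both parents present, two affected children
  ped <- tibble::tibble(
    sample_id = c("C1", "C2", "FA", "MO"),
    sex = c("male", "male", "male", "female"),
    affected = c(TRUE, TRUE, FALSE, FALSE),
    father_id = c("FA", "FA", NA, NA),
    mother_id = c("MO", "MO", NA, NA),
    genotyped = TRUE
  )
  set.seed(99)
  for (rep in 1:20) {
    # Mendelian genotypes: each parent transmits one allele per child
    fa <- sample(0:1, 2, replace = TRUE)
    mo <- sample(0:1, 2, replace = TRUE)
    gt_of <- function(a, b) paste(min(a, b), max(a, b), sep = "/")
    n <- 6
    rows <- lapply(seq_len(n), function(i) {
      fa <- sample(0:1, 2, replace = TRUE)
      mo <- sample(0:1, 2, replace = TRUE)
      mk_variant(
        pos = i * 10, gene = "G1",
        gt = list(
          C1 = gt_of(sample(fa, 1), sample(mo, 1)),
          C2 = gt_of(sample(fa, 1), sample(mo, 1)),
          FA = gt_of(fa[1], fa[2]), MO = gt_of(mo[1], mo[2])
        )
      )
    })
    v <- dplyr::bind_rows(rows)
    ch <- compound_het_candidates(v, ped)
    cand <- ch[ch$status == "candidate", ]
    if (nrow(cand) > 0) {
      expect_true(all(cand$phase_note == "one_parent_each"))
    }
  }
})

test_that("filters are monotone and order-insensitive", {
  ped <- quartet_ped()
  v <- rand_quartet_variants(120, seed = 3)
  sh <- shared_variants(v, ped)
  expect_lte(nrow(sh), nrow(v))
  expect_true(all(
    paste(sh$chrom, sh$pos) %in% paste(v$chrom, v$pos)
  ))
  # shuffled input gives the same set after canonical sort
  shuf <- v[sample(nrow(v)), ]
  sh2 <- quartetvar:::sort_variants(shared_variants(shuf, ped))
  expect_equal(
    as.data.frame(quartetvar:::sort_variants(sh)), as.data.frame(sh2)
  )
})

test_that("homozygous and compound-het model labels are disjoint", {
  ped <- quartet_ped()
  v <- rand_quartet_variants(150, seed = 17, n_genes = 10)
  m <- assign_inheritance(v, ped)
  rx <- recessive_or_xlinked(shared_variants(v, ped), ped)
  rx_keys <- paste(rx$chrom, rx$pos)
  ch_keys <- paste(m$chrom, m$pos)[m$model == "compound_het"]
  expect_length(intersect(rx_keys, ch_keys), 0)
})
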