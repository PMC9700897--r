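test_that("panel intersection matches set membership", {
  panels <- list(
    enzymopathy = gene_set(c("G6PD", "PKLR", "NT5C3A"), "enzymopathy"),
    membranopathy = gene_set(c("ANK1", "SPTB"), "membranopathy")
  )
  v <- dplyr::bind_rows(
    mk_variant(pos = 1, gene = "NT5C3A"),
    mk_variant(pos = 2, gene = "ANK1"),
    mk_variant(pos = 3, gene = "ZZZ9")
  )
  tagged <- panel_intersect(v, panels)
  expect_equal(tagged$panel_hits[[1]], "enzymopathy")
  expect_equal(tagged$panel_hits[[2]], "membranopathy")
  expect_length(tagged$panel_hits[[3]], 0)
  summ <- attr(tagged, "panel_summary")
  expect_equal(summ$n_genes[summ$panel == "enzymopathy"], 1)

  # random oracle
  set.seed(4)
  genes <- sprintf("G%02d", 1:30)
  pan <- list(p1 = gene_set(sample(genes, 10)), p2 = gene_set(sample(genes, 5)))
  vr <- dplyr::bind_rows(lapply(1:25, function(i) {
    mk_variant(pos = i, gene = sample(genes, 1))
  }))
  got <- panel_intersect(vr, pan)
  for (i in seq_len(nrow(vr))) {
    expect_setequal(
      got$panel_hits[[i]],
      names(pan)[c(vr$gene[i] %in% pan$p1, vr$gene[i] %in% pan$p2)]
    )
  }
})

test_that("expression partition is a disjoint four-way split", {
  early <- gene_set(c("A", "B", "C"), "early")
  late <- gene_set(c("B", "C", "D"), "late")
  part <- partition_by_expression(c("A", "B", "D", "E"), early, late)
  expect_equal(part$partition, c("early_only", "both", "late_only", "neither"))
  # early == late puts everything shared into "both"
  same <- partition_by_expression(c("A", "B"), early, early)
  expect_true(all(same$partition == "both"))
  # random set algebra oracle
  set.seed(6)
  u <- sprintf("G%03d", 1:100)
  e <- sample(u, 40); l <- sample(u, 30)
  p <- partition_by_expression(u, gene_set(e), gene_set(l))
  expect_equal(sum(p$partition == "both"), length(intersect(e, l)))
  expect_equal(sum(p$partition == "early_only"), length(setdiff(e, l)))
  expect_equal(sum(p$partition == "late_only"), length(setdiff(l, e)))
})

test_that("synthetic library-sized sets report the forced overlap", {
  shared <- sprintf("S%03d", 1:201)
  early <- gene_set(c(shared, sprintf("E%03d", 1:500)))
  late <- gene_set(c(shared, sprintf("L%03d", 1:453)))
  v <- dplyr::bind_rows(lapply(seq_along(shared), function(i) {
    mk_variant(pos = i, gene = shared[i])
  }))
  tagged <- expression_intersect(v, early, late)
  counts <- attr(tagged, "partition_counts")
  expect_equal(counts$n_genes[counts$partition == "both"], 201)
})

test_that("hypergeometric p-values equal exhaustive subset enumeration", {
  # universe 10, pathway 5, query 3, overlap 3: p = C(5,3)/C(10,3)
  pw <- pathway_table(
    tibble::tibble(pathway = "P", gene = sprintf("G%02d", 1:5)),
    universe = sprintf("G%02d", 1:10)
  )
  res <- pathway_enrichment(sprintf("G%02d", 1:3), pw)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3))
  expect_equal(res$p_value, oracle_hyper_enum(10, 5, 3, 3))

  set.seed(13)
  for (i in 1:10) {
    u_size <- sample(6:15, 1)
    k_size <- sample(2:(u_size - 1), 1)
    q_size <- sample(1:(u_size - 1), 1)
    universe <- sprintf("U%02d", seq_len(u_size))
    pathway_genes <- universe[seq_len(k_size)]
    query <- sample(universe, q_size)
    pw <- pathway_table(
      tibble::tibble(pathway = "P", gene = pathway_genes),
      universe = universe
    )
    res <- pathway_enrichment(query, pw)
    k <- length(intersect(query, pathway_genes))
    expect_equal(res$p_value, oracle_hyper_enum(u_size, k_size, q_size, k),
                 tolerance = 1e-12)
  }
})

test_that("overlap 0 with an empty query has p = 1", {
  pw <- pathway_table(
    tibble::tibble(pathway = "P", gene = c("A", "B")),
    universe = c("A", "B", "C", "D")
  )
  res <- suppressWarnings(pathway_enrichment(character(0), pw))
  expect_equal(res$p_value, 1)
})

test_that("p-values on a random pathway table match the summation oracle", {
  set.seed(21)
  universe <- sprintf("G%03d", 1:200)
  memberships <- dplyr::bind_rows(lapply(1:50, function(i) {
    tibble::tibble(
      pathway = sprintf("pw%02d", i),
      gene = sample(universe, sample(3:40, 1))
    )
  }))
  pw <- pathway_table(memberships, universe = universe)
  query <- sample(universe, 25)
  res <- pathway_enrichment(query, pw)
  for (i in seq_len(nrow(res))) {
    expect_equal(
      res$p_value[i],
      oracle_hyper_sum(res$universe_size[i], res$pathway_size[i],
                       res$query_size[i], res$overlap[i]),
      tolerance = 1e-10
    )
  }
  # BH definition checks
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(all(diff(res$q_value) >= -1e-15))  # sorted by q
})

test_that("query genes outside the universe are dropped with a warning", {
  pw <- pathway_table(
    tibble::tibble(pathway = "P", gene = c("A", "B")),
    universe = c("A", "B", "C")
  )
  expect_warning(res <- pathway_enrichment(c("A", "ZZZ"), pw), "outside")
  expect_equal(res$query_size, 1)
})

test_that("the evidence combiner follows the published combining rules", {
  expect_equal(acmg_combine(pm = 3), "likely_pathogenic")
  expect_equal(acmg_combine(pm = 1), "vus")
  expect_equal(acmg_combine(), "vus")
  expect_equal(acmg_combine(pm = 2), "vus")
  expect_equal(acmg_combine(pm = 2, pp = 2), "likely_pathogenic")
  expect_equal(acmg_combine(pvs = 1, pm = 1), "likely_pathogenic")
  expect_equal(acmg_combine(pvs = 1, ps = 1), "pathogenic")
  expect_equal(acmg_combine(ps = 2), "pathogenic")
  expect_equal(acmg_combine(ps = 1, pm = 3), "pathogenic")
  expect_equal(acmg_combine(ps = 1, pm = 1), "likely_pathogenic")
  expect_equal(acmg_combine(ba = 1), "benign")
  expect_equal(acmg_combine(bs = 2), "benign")
  expect_equal(acmg_combine(bs = 1, bp = 1), "likely_benign")
  expect_equal(acmg_combine(bp = 2), "likely_benign")
  # conflicting evidence resolves to VUS
  expect_equal(acmg_combine(pm = 3, ba = 1), "vus")
})

test_that("the causal in-frame deletion classifies likely pathogenic via PM1+PM2+PM4", {
  v <- mk_variant(
    chrom = "7", pos = 33017549, ref = "TGTT", alt = "T",
    gene = "NT5C3A", consequence = "inframe_indel",
    domain = TRUE, rep_region = FALSE,
    pop = pop_entry("GnomAD", 2, 140214)
  )
  res <- acmg_classify(v)
  expect_equal(res$acmg_criteria, "PM1+PM2+PM4")
  expect_equal(res$acmg_class, "likely_pathogenic")
})

test_that("classification is total and deterministic over random bundles", {
  v <- rand_quartet_variants(60, seed = 30)
  r1 <- acmg_classify(v)
  r2 <- acmg_classify(v)
  expect_equal(r1$acmg_class, r2$acmg_class)
  expect_true(all(r1$acmg_class %in%
                    c("pathogenic", "likely_pathogenic", "vus",
                      "likely_benign", "benign")))
  # PM2-only records are VUS
  pm2_only <- r1$acmg_criteria == "PM2"
  expect_true(all(r1$acmg_class[pm2_only] == "vus"))
})

test_that("ranking is a permutation with coordinate tie-breaks", {
  ped <- quartet_ped()
  v <- dplyr::bind_rows(
    mk_variant(chrom = "2", pos = 50),
    mk_variant(chrom = "1", pos = 900),
    mk_variant(chrom = "1", pos = 100)
  )
  v$passed_stage <- TRUE  # identical scores everywhere
  names(v)[names(v) == "passed_stage"] <- "passed_shared"
  ranked <- rank_candidates(v)
  expect_equal(sort(ranked$rank), 1:3)
  expect_equal(ranked$chrom[ranked$rank], c("1", "1", "2"))
  expect_equal(ranked$pos[ranked$rank == 1], 100L)
  # single candidate gets rank 1
  single <- rank_candidates(mk_variant())
  expect_equal(single$rank, 1)
})

test_that("the full cascade traces stages and ranks the spiked causal first", {
  cfg <- sim_config(n_sites = 500, seed = 77)
  sim <- simulate_quartet(cfg)
  gs <- simulate_gene_sets(cfg)
  rep <- run_prioritization(
    sim$variants, sim$pedigree, gs$panels, gs$early, gs$late,
    pathways = gs$pathways, catalog = sim$catalog
  )
  expect_equal(sort(rep$rank), seq_len(nrow(rep)))
  key1 <- with(rep[rep$rank == 1, ], paste(chrom, pos, ref, alt, sep = ":"))
  expect_equal(key1, sim$causal_key)
  counts <- stage_counts(rep)
  expect_equal(counts$n[counts$stage == "input"], nrow(sim$variants))
  expect_true(all(diff(counts$n[counts$stage %in%
                                  c("shared", "rare")]) <= 0))
  # enrichment attached and the pyrimidine pathway is the top hit
  enr <- attr(rep, "enrichment")
  expect_s3_class(enr, "enrichment_result")
  # the stage trace covers every enabled stage for every record
  expect_true(all(c("passed_shared", "passed_large_effect", "passed_rare",
                    "passed_model", "passed_panel", "passed_erythroid")
                  %in% names(rep)))
})

test_that("candidate report files are written", {
  cfg <- sim_config(n_sites = 200, seed = 5)
  sim <- simulate_quartet(cfg)
  gs <- simulate_gene_sets(cfg)
  rep <- run_prioritization(
    sim$variants, sim$pedigree, gs$panels, gs$early, gs$late,
    pathways = gs$pathways
  )
  dir <- withr::local_tempdir()
  paths <- write_candidate_report(rep, dir)
  expect_true(file.exists(file.path(dir, "candidates.tsv")))
  expect_true(file.exists(file.path(dir, "run_log.json")))
  tsv <- utils::read.delim(file.path(dir, "candidates.tsv"))
  expect_equal(nrow(tsv), nrow(rep))
})
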