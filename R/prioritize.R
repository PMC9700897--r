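#' Tag records with the gene panels that contain their gene
#'
#' @param variants A variant table (see [variant-table]).
#' @param panels Named list of [gene_set()]s (or plain character vectors)
#'   of clinically curated genes, e.g. membranopathy / enzymopathy /
#'   hemoglobinopathy panels.
#' @return `variants` with a `panel_hits` list-column (character vector of
#'   panel names per record) and a `panel_summary` attribute counting
#'   distinct hit genes per panel.
#' @export
panel_intersect <- function(variants, panels) {
  if (is.null(names(panels)) || any(names(panels) == "")) {
    names(panels) <- vapply(seq_along(panels), function(i) {
      attr(panels[[i]], "name") %||% paste0("panel", i)
    }, character(1))
  }
  genes_up <- toupper(variants$gene)
  hits <- lapply(genes_up, function(g) {
    names(panels)[vapply(panels, function(p) g %in% toupper(p), logical(1))]
  })
  variants$panel_hits <- hits
  summary <- purrr::map_dfr(names(panels), function(nm) {
    tibble(
      panel = nm,
      n_genes = length(unique(genes_up[vapply(
        hits, function(h) nm %in% h, logical(1)
      )]))
    )
  })
  structure(variants, panel_summary = summary)
}

#' Partition genes by erythroid expression-library membership
#'
#' Splits genes into four disjoint classes by membership in the early
#' (CD71-high) and late (glycophorin-A-positive) erythroid expression
#' libraries: `early_only`, `late_only`, `both`, `neither`.
#'
#' @param genes Character vector of gene symbols.
#' @param early,late [gene_set()]s (or character vectors).
#' @return Tibble with `gene`, `partition`.
#' @export
partition_by_expression <- function(genes, early, late) {
  g <- toupper(genes)
  e <- g %in% toupper(early)
  l <- g %in% toupper(late)
  tibble(
    gene = genes,
    partition = dplyr::case_when(
      e & l ~ "both",
      e & !l ~ "early_only",
      !e & l ~ "late_only",
      .default = "neither"
    )
  )
}

#' Tag records with their erythroid expression partition
#'
#' @param variants A variant table.
#' @inheritParams partition_by_expression
#' @return `variants` with an `expression_partition` column and a
#'   `partition_counts` attribute (distinct genes per partition).
#' @export
expression_intersect <- function(variants, early, late) {
  part <- partition_by_expression(variants$gene, early, late)
  variants$expression_partition <- part$partition
  counts <- part |>
    dplyr::distinct(.data$gene, .data$partition) |>
    dplyr::count(.data$partition, name = "n_genes")
  structure(variants, partition_counts = counts)
}

#' Pathway over-representation by the hypergeometric test
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `query_size` genes are sampled
#' without replacement from a universe containing `pathway_size` pathway
#' members: `P[X >= overlap]`, `X ~ Hypergeom(universe, pathway, query)`.
#' P-values are Benjamini-Hochberg adjusted across all tested pathways and
#' results are stably sorted by `(q_value, p_value, pathway)`. This is a
#' documented open substitute for proprietary gene-set scoring: the
#' statistical intent (over-representation) is standard and testable.
#'
#' @param query_genes Character vector or [gene_set()] of query genes.
#'   Genes outside the universe are dropped with a warning.
#' @param pathways A [pathway_table()] (tibble `pathway`/`gene` with a
#'   `universe` attribute). An empty universe is fatal.
#' @return An `enrichment_result` tibble: `pathway`, `overlap`,
#'   `query_size`, `pathway_size`, `universe_size`, `p_value`, `q_value`.
#' @export
pathway_enrichment <- function(query_genes, pathways) {
  universe <- attr(pathways, "universe")
  if (is.null(universe) || length(universe) == 0) {
    abort("pathway table has an empty gene universe")
  }
  query <- unique(toupper(as.character(query_genes)))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf(
      "%d query gene(s) outside the universe dropped (e.g. %s)",
      length(outside), outside[1]
    ))
    query <- setdiff(query, outside)
  }

  res <- pathways |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      overlap = length(intersect(unique(.data$gene), query)),
      pathway_size = dplyr::n_distinct(.data$gene),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      query_size = length(query),
      universe_size = length(universe),
      # upper tail P[X >= overlap]
      p_value = stats::phyper(
        .data$overlap - 1, .data$pathway_size,
        .data$universe_size - .data$pathway_size,
        .data$query_size, lower.tail = FALSE
      ),
      q_value = stats::p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::select(
      "pathway", "overlap", "query_size", "pathway_size",
      "universe_size", "p_value", "q_value"
    ) |>
    dplyr::arrange(.data$q_value, .data$p_value, .data$pathway)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Default candidate-ranking weights
#'
#' The deterministic score of a candidate is the number of pipeline stages
#' it passed plus these bonuses: `panel` for membership of any clinical
#' panel, `erythroid_both` for expression in both erythroid libraries, and
#' a per-class ACMG bonus. The published workflow ranked by expert
#' judgment; fixed documented weights trade mimicry for determinism.
#'
#' @return Named list of weights.
#' @export
prioritization_weights <- function() {
  list(
    panel = 2,
    erythroid_both = 2,
    acmg = c(
      pathogenic = 4, likely_pathogenic = 3, vus = 0,
      likely_benign = -2, benign = -4
    )
  )
}

#' Rank candidate records deterministically
#'
#' @param report A variant table carrying the stage columns produced by
#'   [run_prioritization()] (`passed_*` logicals, `panel_hits`,
#'   `expression_partition`, `acmg_class`).
#' @param weights Weights from [prioritization_weights()].
#' @return `report` with `score` and unique `rank` (1..n) columns, sorted
#'   by rank; ties are broken by genomic coordinate `(chrom, pos, ref,
#'   alt)`.
#' @export
rank_candidates <- function(report, weights = prioritization_weights()) {
  stage_cols <- grep("^passed_", names(report), value = TRUE)
  stage_score <- if (length(stage_cols) > 0) {
    rowSums(as.matrix(as.data.frame(report[stage_cols])))
  } else {
    rep(0, nrow(report))
  }
  panel_bonus <- if ("panel_hits" %in% names(report)) {
    weights$panel * vapply(report$panel_hits, function(h) length(h) > 0, logical(1))
  } else 0
  ery_bonus <- if ("expression_partition" %in% names(report)) {
    weights$erythroid_both * (report$expression_partition == "both")
  } else 0
  acmg_bonus <- if ("acmg_class" %in% names(report)) {
    unname(weights$acmg[report$acmg_class])
  } else 0

  report$score <- stage_score + panel_bonus + ery_bonus + acmg_bonus
  ord <- order(
    -report$score, chrom_rank(report$chrom), report$pos,
    report$ref, report$alt
  )
  report <- report[ord, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  report
}

#' Run the full variant-prioritization cascade
#'
#' Applies every stage to the records shared by the affected members and
#' returns a per-variant trace (the machine-readable analogue of a
#' candidate table):
#'
#' 1. `shared` — carried by every affected member ([shared_variants()]);
#' 2. `large_effect` — potentially protein-altering consequence;
#' 3. `rare` — maximum population frequency at or below `threshold`;
#' 4. `model` — an inheritance model could be assigned
#'    ([assign_inheritance()]);
#' 5. `panel` — gene in at least one clinical panel;
#' 6. `erythroid` — gene expressed in both erythroid libraries.
#'
#' Records are ACMG-classified, scored and ranked ([rank_candidates()]).
#' Per-stage survivor counts (the run log) are attached as attribute
#' `stage_counts`; when a pathway table is supplied, the enrichment of the
#' surviving genes is attached as `enrichment`.
#'
#' @param variants A variant table.
#' @param pedigree Pedigree tibble.
#' @param panels Named list of panel [gene_set()]s.
#' @param early,late Erythroid expression-library [gene_set()]s.
#' @param pathways Optional [pathway_table()].
#' @param catalog Optional known-mutation catalog
#'   ([read_variant_catalog()]).
#' @param threshold Rarity threshold (default 0.005).
#' @param populations Optional population subset for the frequency stage.
#' @param weights Ranking weights ([prioritization_weights()]).
#' @return A `candidate_report` tibble of the shared records with
#'   `passed_*` stage columns, `model`, `phase_note`, `max_frequency`,
#'   `panel_hits`, `expression_partition`, `acmg_criteria`, `acmg_class`,
#'   `score`, `rank`.
#' @export
run_prioritization <- function(variants, pedigree, panels, early, late,
                               pathways = NULL, catalog = NULL,
                               threshold = 0.005, populations = NULL,
                               weights = prioritization_weights()) {
  n_total <- nrow(variants)
  if (!is.null(catalog)) variants <- known_catalog_flag(variants, catalog)

  shared <- shared_variants(variants, pedigree)
  report <- shared |>
    frequency_decision(threshold, populations) |>
    assign_inheritance(pedigree) |>
    panel_intersect(panels) |>
    expression_intersect(early, late) |>
    acmg_classify()

  report$passed_shared <- TRUE
  report$passed_large_effect <- report$consequence %in% large_effect_classes()
  report$passed_rare <- report$freq_passed
  report$passed_model <- report$model != "unassigned"
  report$passed_panel <- vapply(
    report$panel_hits, function(h) length(h) > 0, logical(1)
  )
  report$passed_erythroid <- report$expression_partition == "both"

  report <- rank_candidates(report, weights)

  stage_counts <- tibble(
    stage = c("input", "shared", "known_catalog", "large_effect", "rare",
              "model", "panel", "erythroid", "all_stages"),
    n = c(
      n_total, nrow(report), sum(report$known_catalog),
      sum(report$passed_large_effect),
      sum(report$passed_rare),
      sum(report$passed_model),
      sum(report$passed_panel),
      sum(report$passed_erythroid),
      sum(report$passed_large_effect & report$passed_rare &
            report$passed_model & report$passed_panel &
            report$passed_erythroid)
    )
  )
  attr(report, "stage_counts") <- stage_counts

  if (!is.null(pathways)) {
    surv <- unique(report$gene[
      report$passed_large_effect & report$passed_rare & report$passed_model
    ])
    surv <- intersect(toupper(surv), attr(pathways, "universe"))
    if (length(surv) > 0) {
      attr(report, "enrichment") <- pathway_enrichment(surv, pathways)
    }
  }
  class(report) <- c("candidate_report", class(report))
  report
}

#' Stage survivor counts of a prioritization run
#'
#' @param report A `candidate_report` from [run_prioritization()].
#' @return Tibble with `stage`, `n`.
#' @export
stage_counts <- function(report) {
  attr(report, "stage_counts")
}

#' Write a candidate table and run log to disk
#'
#' `candidates.tsv` holds the per-variant report (gene, identifiers, HGVS,
#' inheritance model, maximum frequency, ACMG class, rank);
#' `run_log.json` the per-stage survivor counts.
#'
#' @param report A `candidate_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_candidate_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "candidates.tsv")
  flat <- report |>
    dplyr::mutate(
      panel_hits = vapply(
        .data$panel_hits, paste, character(1), collapse = ","
      ),
      pop_freqs = NULL
    )
  drop <- grep("^gt_", names(flat), value = TRUE)
  utils::write.table(
    as.data.frame(flat[setdiff(names(flat), drop)]),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  log_path <- file.path(dir, "run_log.json")
  counts <- stage_counts(report)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(
        stage_counts = counts,
        note = "pathway scores are upper-tail hypergeometric with BH adjustment"
      ),
      log_path, auto_unbox = TRUE, digits = NA
    )
  } else {
    utils::write.table(as.data.frame(counts), log_path, row.names = FALSE)
  }
  enr <- attr(report, "enrichment")
  paths <- c(tsv, log_path)
  if (!is.null(enr)) {
    enr_path <- file.path(dir, "enrichment.tsv")
    utils::write.table(
      as.data.frame(enr), enr_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, enr_path)
  }
  invisible(paths)
}
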