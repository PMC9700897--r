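#' Combine ACMG/AMP evidence counts into a classification
#'
#' Implements the published evidence-combining rules over counts of
#' triggered criteria at each strength: PVS (very strong), PS (strong), PM
#' (moderate), PP (supporting) for pathogenic evidence; BA (stand-alone),
#' BS (strong), BP (supporting) for benign evidence. Conflicting evidence
#' (both a pathogenic-side and a benign-side rule satisfied) yields
#' `"vus"`.
#'
#' @param pvs,ps,pm,pp Counts of pathogenic-side criteria.
#' @param ba,bs,bp Counts of benign-side criteria.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"vus"`,
#'   `"likely_benign"`, `"benign"`.
#' @examples
#' acmg_combine(pm = 3)              # likely_pathogenic
#' acmg_combine(pm = 1)              # vus
#' acmg_combine(pvs = 1, ps = 1)     # pathogenic
#' @export
acmg_combine <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                         ba = 0, bs = 0, bp = 0) {
  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs == 1 && pm == 1) ||
    (ps == 1 && pm >= 1) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp == 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("vus")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "vus"
}

#' ACMG-style classification from the annotation bundle
#'
#' Auto-triggers the three moderate criteria that can be evaluated from the
#' parsed annotation bundle:
#'
#' * **PM1** — located in a critical, well-established functional domain
#'   (`in_functional_domain`);
#' * **PM2** — absent from population controls or at extremely low
#'   frequency for a recessive phenotype (maximum population frequency
#'   below `pm2_max_af`, default 1%; no frequency data counts as absent);
#' * **PM4** — protein length change from an in-frame indel in a
#'   non-repeat region (`consequence == "inframe_indel"` and
#'   `!in_repeat_region`).
#'
#' Evidence is combined with [acmg_combine()]; additional manually curated
#' criteria can be supplied as extra strength counts.
#'
#' @param variants A variant table (see [variant-table]).
#' @param pm2_max_af PM2 frequency bound (default 0.01 for a recessive
#'   phenotype).
#' @param extra Optional named list of additional evidence counts applied
#'   to every record, e.g. `list(ps = 1)`.
#' @return `variants` with added `acmg_criteria` (e.g. `"PM1+PM2+PM4"`,
#'   `""` when none) and `acmg_class` columns.
#' @export
acmg_classify <- function(variants, pm2_max_af = 0.01, extra = list()) {
  maxf <- max_pop_frequency(variants$pop_freqs)
  pm1 <- variants$in_functional_domain %in% TRUE
  pm2 <- maxf < pm2_max_af
  pm4 <- variants$consequence == "inframe_indel" &
    !(variants$in_repeat_region %in% TRUE)

  crit <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c("PM1", "PM2", "PM4")[c(pm1[i], pm2[i], pm4[i])], collapse = "+")
  }, character(1))
  cls <- vapply(seq_len(nrow(variants)), function(i) {
    args <- utils::modifyList(
      list(pm = sum(pm1[i], pm2[i], pm4[i])),
      as.list(extra), keep.null = FALSE
    )
    if (length(extra) > 0 && "pm" %in% names(extra)) {
      args$pm <- sum(pm1[i], pm2[i], pm4[i]) + extra$pm
    }
    do.call(acmg_combine, args)
  }, character(1))

  variants$acmg_criteria <- crit
  variants$acmg_class <- cls
  variants
}
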