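#' Variants shared by all affected members
#'
#' Keeps records in which every genotyped affected member carries at least
#' one ALT allele (het, hom_alt or hemi_alt). A missing genotype in an
#' affected member disqualifies the record: every candidate is expected to
#' be orthogonally validated, so silent pass-through of no-calls would
#' fabricate candidates.
#'
#' @param variants A variant table (see [variant-table]).
#' @param pedigree Pedigree tibble; must contain at least one affected
#'   member (fatal otherwise).
#' @return The subset of `variants` shared by all affected members, input
#'   order preserved.
#' @export
shared_variants <- function(variants, pedigree) {
  aff <- affected_ids(pedigree)
  if (length(aff) == 0) abort("pedigree has no genotyped affected member")
  if (nrow(variants) == 0) return(variants)
  zm <- zygosity_matrix(variants, pedigree)
  keep <- apply(carries_mat(zm[, aff, drop = FALSE]), 1, all)
  variants[keep, , drop = FALSE]
}

carries_mat <- function(zm) {
  matrix(carries_alt(zm), nrow = nrow(zm), dimnames = dimnames(zm))
}

#' Recessive-homozygous and X-linked hemizygous filter
#'
#' Applied after [shared_variants()]. Keeps records matching either model:
#'
#' * `recessive_hom` (autosomes): every genotyped affected member is
#'   hom_alt and every genotyped unaffected member is het or hom_ref;
#' * `x_linked` (X chromosome): every affected male is hemi_alt, affected
#'   females (if any) are hom_alt, unaffected males are hemi_ref, and
#'   unaffected females are carriers at most (het or hom_ref).
#'
#' A missing genotype in any genotyped member fails the predicate (the
#' constraint cannot be verified).
#'
#' @inheritParams shared_variants
#' @return Kept records with an added `model` column
#'   (`"recessive_hom"` or `"x_linked"`).
#' @export
recessive_or_xlinked <- function(variants, pedigree) {
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, model = character(0)))
  }
  zm <- zygosity_matrix(variants, pedigree)
  model <- recessive_xlinked_model(variants$chrom, zm, pedigree)
  out <- variants[!is.na(model), , drop = FALSE]
  out$model <- model[!is.na(model)]
  out
}

# Per-record model label ("recessive_hom" / "x_linked") or NA.
recessive_xlinked_model <- function(chrom, zm, pedigree) {
  aff <- affected_ids(pedigree)
  unaff <- unaffected_ids(pedigree)
  ped_g <- pedigree[pedigree$genotyped, ]
  sex_of <- stats::setNames(ped_g$sex, ped_g$sample_id)
  on_x <- is_x_chrom(chrom)

  vapply(seq_along(chrom), function(i) {
    z <- zm[i, ]
    if (on_x[i]) {
      ok_aff <- all(vapply(aff, function(s) {
        if (sex_of[s] == "male") z[s] == "hemi_alt" else z[s] == "hom_alt"
      }, logical(1)))
      ok_unaff <- all(vapply(unaff, function(s) {
        if (sex_of[s] == "male") z[s] == "hemi_ref" else z[s] %in% c("het", "hom_ref")
      }, logical(1)))
      if (ok_aff && ok_unaff) "x_linked" else NA_character_
    } else {
      ok_aff <- all(z[aff] == "hom_alt")
      ok_unaff <- all(z[unaff] %in% c("het", "hom_ref"))
      if (ok_aff && ok_unaff) "recessive_hom" else NA_character_
    }
  }, character(1))
}

#' Compound-heterozygote candidate genes
#'
#' Searches each gene for combinations of `min_variants` or more distinct
#' records that are heterozygous in *every* genotyped affected member, such
#' that
#'
#' 1. no genotyped unaffected member carries the full combination, and
#' 2. when exactly one parent of the affected members is genotyped, at
#'    least one record of the pair is absent from that parent, implying
#'    transmission of it from the ungenotyped parent.
#'
#' Pairs failing (2) are reported with `status = "phase_unresolved"` (both
#' alleles could sit on one parental haplotype). The `phase_note` is
#' `one_parent_each` when each variant of the pair can be assigned to a
#' different parent, `maternal_implied` when one variant is absent from the
#' single genotyped parent (so must come from the ungenotyped one) but the
#' other's origin is ambiguous, and `unphased` otherwise.
#'
#' @inheritParams shared_variants
#' @param min_variants Minimum number of qualifying het variants per gene
#'   (default 2).
#' @return Tibble with one row per evaluated pair: `gene`, `key1`, `key2`
#'   (positional variant keys), `phase_note`, `status`
#'   (`"candidate"` or `"phase_unresolved"`). Genes qualify when they have
#'   at least one candidate pair and at least `min_variants` het variants.
#' @export
compound_het_candidates <- function(variants, pedigree, min_variants = 2) {
  empty <- tibble(
    gene = character(0), key1 = character(0), key2 = character(0),
    phase_note = character(0), status = character(0)
  )
  if (nrow(variants) == 0) return(empty)
  aff <- affected_ids(pedigree)
  if (length(aff) == 0) abort("pedigree has no genotyped affected member")
  unaff <- unaffected_ids(pedigree)
  parents <- genotyped_parents(pedigree)

  zm <- zygosity_matrix(variants, pedigree)
  cm <- carries_mat(zm)
  het_all_aff <- apply(zm[, aff, drop = FALSE] == "het", 1, all)
  idx <- which(het_all_aff)
  if (length(idx) == 0) return(empty)

  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  genes <- variants$gene[idx]

  out <- list()
  for (g in unique(genes[!is.na(genes)])) {
    gi <- idx[which(genes == g)]
    gi <- gi[!duplicated(keys[gi])]
    if (length(gi) < min_variants) next
    pairs <- utils::combn(gi, 2)
    for (p in seq_len(ncol(pairs))) {
      i1 <- pairs[1, p]; i2 <- pairs[2, p]
      # (1) no genotyped unaffected member carries the full combination
      combo_in_unaff <- length(unaff) > 0 &&
        any(cm[i1, unaff] & cm[i2, unaff])
      if (combo_in_unaff) next
      note_status <- phase_pair(
        cm[i1, , drop = TRUE], cm[i2, , drop = TRUE], parents
      )
      out[[length(out) + 1]] <- tibble(
        gene = g, key1 = keys[i1], key2 = keys[i2],
        phase_note = note_status$note, status = note_status$status
      )
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

# Phase assessment of a candidate pair given carriage vectors and the ids of
# the genotyped parents.
phase_pair <- function(c1, c2, parents) {
  if (length(parents) >= 2) {
    in1 <- parents[c1[parents]]
    in2 <- parents[c2[parents]]
    trans <- length(in1) > 0 && length(in2) > 0 &&
      any(outer(in1, in2, FUN = Vectorize(function(a, b) a != b)))
    if (trans) {
      list(note = "one_parent_each", status = "candidate")
    } else {
      list(note = "unphased", status = "phase_unresolved")
    }
  } else if (length(parents) == 1) {
    p <- parents
    if (c1[p] && c2[p]) {
      # both could come from the genotyped parent: phase unresolved
      list(note = "unphased", status = "phase_unresolved")
    } else if (xor(c1[p], c2[p])) {
      # one from the genotyped parent, the other absent from them, hence
      # from the ungenotyped parent
      list(note = "one_parent_each", status = "candidate")
    } else {
      # absent from the genotyped parent in both: both maternal-implied,
      # which a single transmitted homolog cannot make trans
      list(note = "maternal_implied", status = "phase_unresolved")
    }
  } else {
    list(note = "unphased", status = "candidate")
  }
}

#' Assign an inheritance model to every record
#'
#' Combines the genotype-pattern filters into a single per-record model
#' label: `recessive_hom` / `x_linked` (homozygous patterns), `compound_het`
#' (member of a candidate pair from [compound_het_candidates()]),
#' `shared_het` (het in all affected, absent from every genotyped
#' unaffected), or `unassigned`. Homozygous and compound-het labels are
#' disjoint by construction (hom_alt vs het in the affected members).
#'
#' @inheritParams shared_variants
#' @return `variants` with added `model` and `phase_note` columns.
#' @export
assign_inheritance <- function(variants, pedigree) {
  if (nrow(variants) == 0) {
    return(dplyr::mutate(
      variants, model = character(0), phase_note = character(0)
    ))
  }
  zm <- zygosity_matrix(variants, pedigree)
  aff <- affected_ids(pedigree)
  unaff <- unaffected_ids(pedigree)
  cm <- carries_mat(zm)

  model <- recessive_xlinked_model(variants$chrom, zm, pedigree)
  phase <- rep(NA_character_, nrow(variants))

  ch <- compound_het_candidates(variants, pedigree)
  ch_cand <- ch[ch$status == "candidate", , drop = FALSE]
  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  in_pair <- keys %in% c(ch_cand$key1, ch_cand$key2)
  model[is.na(model) & in_pair] <- "compound_het"
  for (i in which(model == "compound_het")) {
    notes <- ch_cand$phase_note[ch_cand$key1 == keys[i] | ch_cand$key2 == keys[i]]
    phase[i] <- notes[1]
  }

  het_aff <- apply(zm[, aff, drop = FALSE] == "het" |
                     zm[, aff, drop = FALSE] == "hemi_alt", 1, all)
  abs_unaff <- if (length(unaff) > 0) {
    !apply(cm[, unaff, drop = FALSE], 1, any)
  } else {
    rep(TRUE, nrow(variants))
  }
  model[is.na(model) & het_aff & abs_unaff] <- "shared_het"
  # an ungenotyped parent means transmission is inferred, never observed
  has_ungenotyped_parent <- any(!pedigree$genotyped)
  phase[model == "shared_het"] <-
    if (has_ungenotyped_parent) "maternal_implied" else "unphased"
  model[is.na(model)] <- "unassigned"

  variants$model <- model
  variants$phase_note <- phase
  variants
}
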