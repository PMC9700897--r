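#' Read a 6-column PED pedigree file
#'
#' Parses the standard whitespace-delimited PED dialect (family, individual,
#' father, mother, sex, phenotype). Sex codes: 1 = male, 2 = female.
#' Phenotype codes: 2 = affected; 0 and 1 = unaffected. Any other sex or
#' phenotype code is an error.
#'
#' A parent coded `"0"` is an unrecorded parent. When the *other* parent of
#' the same individual is a named member, the missing parent is a real but
#' ungenotyped individual of the nuclear family (the study design here: the
#' mother's genetic material was unavailable), so one shared placeholder
#' member with `genotyped = FALSE` is created per family and parent slot.
#' Individuals with both parents coded `"0"` are founders and get no
#' placeholders.
#'
#' @param path Path to a PED file.
#' @return A pedigree tibble with columns `sample_id`, `sex`, `affected`,
#'   `father_id`, `mother_id`, `genotyped`.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c(
#'   "FAM1 AK 0 0 1 1",
#'   "FAM1 EK AK 0 2 1",
#'   "FAM1 RK AK 0 1 2",
#'   "FAM1 MK AK 0 1 2"
#' ), ped)
#' read_pedigree(ped)
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(
    path, header = FALSE, comment.char = "#",
    colClasses = "character", col.names = c(
      "family_id", "sample_id", "father_id", "mother_id", "sex", "phenotype"
    )
  )
  if (!all(raw$sex %in% c("1", "2"))) {
    abort(sprintf(
      "unknown sex code(s) in PED: %s (expected 1 = male, 2 = female)",
      paste(unique(setdiff(raw$sex, c("1", "2"))), collapse = ", ")
    ))
  }
  if (!all(raw$phenotype %in% c("0", "1", "2"))) {
    abort(sprintf(
      "unknown phenotype code(s) in PED: %s (expected 0/1 = unaffected, 2 = affected)",
      paste(unique(setdiff(raw$phenotype, c("0", "1", "2"))), collapse = ", ")
    ))
  }

  ped <- tibble(
    family_id = raw$family_id,
    sample_id = raw$sample_id,
    sex = ifelse(raw$sex == "1", "male", "female"),
    affected = raw$phenotype == "2",
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    genotyped = TRUE
  )

  # Placeholders for half-specified parentage (one per family and slot).
  placeholders <- list()
  for (fam in unique(ped$family_id)) {
    fam_rows <- ped$family_id == fam
    for (slot in c("father_id", "mother_id")) {
      other <- if (slot == "father_id") "mother_id" else "father_id"
      need <- fam_rows & is.na(ped[[slot]]) & !is.na(ped[[other]])
      if (any(need)) {
        pid <- paste0(fam, if (slot == "father_id") ".father" else ".mother")
        ped[[slot]][need] <- pid
        placeholders[[pid]] <- tibble(
          family_id = fam, sample_id = pid,
          sex = if (slot == "father_id") "male" else "female",
          affected = FALSE,
          father_id = NA_character_, mother_id = NA_character_,
          genotyped = FALSE
        )
      }
    }
  }
  # Named parents without their own row are also ungenotyped placeholders.
  referenced <- setdiff(
    unique(stats::na.omit(c(ped$father_id, ped$mother_id))), ped$sample_id
  )
  for (pid in setdiff(referenced, names(placeholders))) {
    is_father <- pid %in% ped$father_id
    placeholders[[pid]] <- tibble(
      family_id = ped$family_id[match(
        pid, ifelse(rep(is_father, nrow(ped)), ped$father_id, ped$mother_id)
      )][1],
      sample_id = pid,
      sex = if (is_father) "male" else "female",
      affected = FALSE,
      father_id = NA_character_, mother_id = NA_character_,
      genotyped = FALSE
    )
  }
  out <- dplyr::bind_rows(ped, purrr::list_rbind(unname(placeholders)))
  validate_pedigree(out)
  dplyr::select(out, -"family_id")
}

validate_pedigree <- function(ped) {
  if (!any(ped$affected)) {
    warn("pedigree has no affected member; inheritance filters will refuse it")
  }
  # No cycles: an individual may not be its own ancestor.
  parent_of <- function(id) {
    r <- ped[ped$sample_id == id, ]
    stats::na.omit(c(r$father_id, r$mother_id))
  }
  for (id in ped$sample_id) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier) > 0) {
      if (id %in% frontier) abort(sprintf("pedigree cycle involving '%s'", id))
      seen <- union(seen, frontier)
      frontier <- setdiff(
        unique(unlist(lapply(frontier, parent_of))), seen
      )
    }
  }
  invisible(ped)
}

# Genotyped affected / unaffected member ids.
affected_ids <- function(ped) ped$sample_id[ped$affected & ped$genotyped]
unaffected_ids <- function(ped) ped$sample_id[!ped$affected & ped$genotyped]

# Genotyped parents of the affected members.
genotyped_parents <- function(ped) {
  aff <- ped[ped$affected & ped$genotyped, ]
  pids <- unique(stats::na.omit(c(aff$father_id, aff$mother_id)))
  ped$sample_id[ped$sample_id %in% pids & ped$genotyped]
}
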