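#' Construct a gene set
#'
#' Symbols are uppercased and deduplicated.
#'
#' @param genes Character vector of gene symbols.
#' @param name Label for the set.
#' @return A `gene_set`: a character vector with a `name` attribute.
#' @export
gene_set <- function(genes, name = "gene_set") {
  g <- unique(toupper(trimws(as.character(genes))))
  g <- g[g != ""]
  structure(g, name = name, class = c("gene_set", "character"))
}

#' @export
#' @method print gene_set
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", attr(x, "name"), length(x)))
  print(unclass(x)[seq_len(min(10, length(x)))])
  if (length(x) > 10) cat(sprintf("... and %d more\n", length(x) - 10))
  invisible(x)
}

#' Read a gene set from a plain-text file
#'
#' One symbol per line; `#` starts a comment. Symbols are uppercased and
#' deduplicated. An empty file (no symbols after comment stripping) is an
#' error.
#'
#' @param path Path to the file.
#' @param name Label for the set (defaults to the file name).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- trimws(lines)
  genes <- genes[genes != ""]
  if (length(genes) == 0) {
    abort(sprintf("gene-set file '%s' contains no gene symbols", path))
  }
  gene_set(genes, name)
}

#' Write a gene set to a plain-text file
#'
#' @param x A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' Read a pathway membership table
#'
#' Two-column TSV with a header (`pathway`, `gene`). The gene universe
#' defaults to the union of all member genes but may be supplied explicitly
#' (the universe of an over-representation test should be every gene that
#' *could* have been observed, not only pathway members).
#'
#' @param path Path to the TSV.
#' @param universe Optional character vector of universe gene symbols.
#' @return Tibble with columns `pathway`, `gene` and a `universe` attribute.
#' @export
read_pathway_table <- function(path, universe = NULL) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("pathway", "gene") %in% names(df))) {
    abort("pathway table needs columns 'pathway' and 'gene'")
  }
  pathway_table(
    tibble(pathway = df$pathway, gene = toupper(df$gene)),
    universe = universe
  )
}

#' @rdname read_pathway_table
#' @param memberships Tibble with columns `pathway`, `gene`.
#' @export
pathway_table <- function(memberships, universe = NULL) {
  memberships <- dplyr::distinct(
    tibble(
      pathway = as.character(memberships$pathway),
      gene = toupper(as.character(memberships$gene))
    )
  )
  universe <- if (is.null(universe)) {
    sort(unique(memberships$gene))
  } else {
    sort(unique(toupper(universe)))
  }
  outside <- setdiff(memberships$gene, universe)
  if (length(outside) > 0) {
    abort(sprintf(
      "%d pathway gene(s) outside the declared universe (e.g. %s)",
      length(outside), outside[1]
    ))
  }
  structure(memberships, universe = universe, class = class(memberships))
}

#' Read a known-mutation catalog
#'
#' Headered TSV with columns `chrom`, `pos`, `ref`, `alt`, `rsid`, `label`
#' (a variant-keyed stand-in for a curated mutation database). Duplicate
#' keys raise a warning; the first entry wins.
#'
#' @param path Path to the TSV.
#' @return Tibble of catalog entries.
#' @export
read_variant_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  names(df) <- tolower(names(df))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    abort("catalog needs columns chrom, pos, ref, alt (plus optional rsid, label)")
  }
  cat_tbl <- tibble(
    chrom = normalize_chrom(df$chrom),
    pos = as.integer(df$pos),
    ref = df$ref, alt = df$alt,
    rsid = if ("rsid" %in% names(df)) df$rsid else NA_character_,
    label = if ("label" %in% names(df)) df$label else NA_character_
  )
  key <- variant_key(cat_tbl$chrom, cat_tbl$pos, cat_tbl$ref, cat_tbl$alt)
  if (anyDuplicated(key)) {
    warn(sprintf(
      "%d duplicate catalog key(s); first entry wins", sum(duplicated(key))
    ))
    cat_tbl <- cat_tbl[!duplicated(key), ]
  }
  cat_tbl
}
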