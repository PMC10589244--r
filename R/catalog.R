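#' Read gene sets from a GMT file
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more member gene symbols. Duplicate
#' member symbols within a line are collapsed; blank lines are skipped.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (one per set), with the
#'   per-set descriptions in `attr(, "descriptions")`.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tA\tB\tB", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  descs <- character()
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    nm <- fields[[1]]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("malformed GMT line %d: no members", i))
    sets[[nm]] <- members
    descs[[nm]] <- fields[[2]]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors of gene symbols.
#' @param path output path.
#' @param descriptions optional named character of set descriptions;
#'   defaults to the `descriptions` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Curated pyroptosis-regulator symbols. The source reviews describe the
# catalog as 57 genes, but the enumerated positive (46) and negative (12)
# lists total 58 symbols; the lists, not the count, are the operative input,
# so both lists are transcribed verbatim. CD274 (PD-L1) is listed as a
# positive regulator and also appears among the immune checkpoint genes.
.PRG_POSITIVE <- c(
  "AIM2", "CASP1", "CASP3", "CASP4", "CASP5", "CASP6", "CASP8", "CASP9",
  "ELANE", "GPX4", "GSDMA", "GSDMB", "GSDMC", "GSDMD", "GSDME", "IL18",
  "IL1B", "NLRC4", "NLRP1", "NLRP2", "NLRP3", "NLRP6", "NLRP7", "NOD1",
  "NOD2", "PJVK", "PLCG1", "PYCARD", "SCAF11", "TNF", "P2RX7", "STAT3",
  "CD274", "MEFV", "GZMA", "GZMB", "TP53", "MAPK8", "MAPK9", "ROS1",
  "NAIP", "TLR2", "TRIM21", "CARD8", "TIRAP", "TICAM1")

.PRG_NEGATIVE <- c(
  "PRKACA", "PANX1", "BRAF", "MAP2K1", "EEF2K", "EGFR", "SIRT1", "XIST",
  "IFI16", "DPP8", "DPP9", "NEK7")

#' Packaged pyroptosis-regulator gene catalog
#'
#' The curated catalog of pyroptosis regulator genes (PRGs): 46 positive
#' (pro-pyroptosis) regulators, from AIM2 through TICAM1, and 12 negative
#' (anti-pyroptosis) regulators, from PRKACA through NEK7. The source
#' literature summarizes the catalog as "57 PRGs" while enumerating 58
#' distinct symbols; this function returns the enumerated lists verbatim
#' and leaves the count discrepancy documented rather than resolved.
#' Symbols are stored under the name used in the enumeration (e.g. GSDME,
#' not its alias DFNA5) and matched case-sensitively.
#'
#' @return A [DirectionalCatalog-class] with 46 positive and 12 negative
#'   regulator symbols.
#' @examples
#' cat58 <- prgCatalog()
#' "GSDMD" %in% positiveRegulators(cat58)
#' @export
prgCatalog <- function() {
  DirectionalCatalog(.PRG_POSITIVE, .PRG_NEGATIVE)
}

#' Restrict a directional catalog to measured genes
#'
#' Intersects both directions with the set of measured gene symbols and
#' reports what was dropped. Errors if either direction loses all members,
#' since the directional index is then undefined.
#'
#' @param catalog a [DirectionalCatalog-class].
#' @param measured character vector of measured gene symbols.
#' @return List with elements `catalog` (the restricted
#'   `DirectionalCatalog`) and `dropped` (list of dropped symbols per
#'   direction).
#' @export
restrictToMeasured <- function(catalog, measured) {
  stopifnot(is(catalog, "DirectionalCatalog"))
  if (length(measured) == 0L) stop("measured gene set is empty")
  measured <- trimws(as.character(measured))
  pos <- intersect(catalog@positive, measured)
  neg <- intersect(catalog@negative, measured)
  if (length(pos) == 0L)
    stop("catalog coverage error: no positive-regulator genes are measured")
  if (length(neg) == 0L)
    stop("catalog coverage error: no negative-regulator genes are measured")
  list(catalog = new("DirectionalCatalog", positive = pos, negative = neg),
       dropped = list(positive = setdiff(catalog@positive, measured),
                      negative = setdiff(catalog@negative, measured)))
}

#' Export a directional catalog as a two-column table
#'
#' @param catalog a [DirectionalCatalog-class].
#' @param path optional TSV output path; when `NULL` the data.frame is
#'   returned without writing.
#' @return data.frame with columns `symbol` and `direction`
#'   (`"positive"`/`"negative"`), invisibly when written.
#' @export
catalogAsTable <- function(catalog, path = NULL) {
  stopifnot(is(catalog, "DirectionalCatalog"))
  df <- data.frame(
    symbol = c(catalog@positive, catalog@negative),
    direction = rep(c("positive", "negative"),
                    c(length(catalog@positive), length(catalog@negative))),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    .writeTsv(df, path)
    return(invisible(df))
  }
  df
}
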