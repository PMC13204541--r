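# Bilateral region table and composite ROIs.
#
# The parcellation is a 72-region bilateral table (36 regions per hemisphere).
# Hemisphere is encoded by the leading L/R character of each abbreviation
# (LSS / RSS style) unless an explicit `hemisphere` column overrides it, and
# left/right homologs are paired by their shared abbreviation stem.

#' Load a bilateral region table
#'
#' Reads a tab-separated region table with columns `id`, `abbreviation`,
#' `name`, and optionally `hemisphere`. When `hemisphere` is absent it is
#' taken from the first character of the abbreviation (`L` or `R`). Homologs
#' are paired by matching abbreviation stems across hemispheres; every region
#' must have a mirror partner.
#'
#' @param path Path to a TSV file. `NULL` (default) loads the packaged
#'   72-region table. The packaged table names the regions the analysis uses
#'   (CA1--CA3, DG, EC, TH, ICtx, COA, SS, MO, SUC, HY, CB, MY, ...) and pads
#'   each hemisphere to 36 regions with synthetic placeholder parcels; supply
#'   your own TSV to use a different parcellation.
#' @param strict If `TRUE`, a table without exactly 72 rows is an error;
#'   otherwise a warning.
#' @return A `region_table`: data frame with columns `id`, `abbreviation`,
#'   `name`, `hemisphere`, `stem`, `homolog_id`.
#' @export
load_region_table <- function(path = NULL, strict = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_table_default.tsv",
                        package = "hdbn", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("region table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "abbreviation", "name")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("region table is missing column(s): ", paste(missing, collapse = ", "))
  }
  build_region_table(tab, strict = strict)
}

# Validates and completes a raw region data frame into a region_table.
build_region_table <- function(tab, strict = FALSE) {
  tab$abbreviation <- as.character(tab$abbreviation)
  if (anyDuplicated(tab$abbreviation)) {
    dup <- unique(tab$abbreviation[duplicated(tab$abbreviation)])
    stop("duplicate abbreviation(s) in region table: ",
         paste(dup, collapse = ", "))
  }
  if (!("hemisphere" %in% names(tab))) {
    tab$hemisphere <- substr(tab$abbreviation, 1L, 1L)
  }
  tab$hemisphere <- as.character(tab$hemisphere)
  bad_hemi <- !tab$hemisphere %in% c("L", "R")
  if (any(bad_hemi)) {
    stop("hemisphere must be 'L' or 'R'; offending region(s): ",
         paste(tab$abbreviation[bad_hemi], collapse = ", "))
  }
  if (nrow(tab) != 72L) {
    msg <- sprintf("region table has %d rows (the standard parcellation has 72)",
                   nrow(tab))
    if (strict) stop(msg) else warning(msg)
  }
  # Stem = abbreviation minus a leading hemisphere prefix when it carries one.
  tab$stem <- ifelse(substr(tab$abbreviation, 1L, 1L) == tab$hemisphere,
                     substring(tab$abbreviation, 2L), tab$abbreviation)
  tab$id <- as.integer(tab$id)
  if (anyDuplicated(tab$id)) stop("duplicate region ids in region table")

  # Homolog pairing: same stem, opposite hemisphere.
  other <- ifelse(tab$hemisphere == "L", "R", "L")
  key <- paste(tab$stem, tab$hemisphere)
  mirror_key <- paste(tab$stem, other)
  idx <- match(mirror_key, key)
  if (anyNA(idx)) {
    orphan <- tab$abbreviation[is.na(idx)]
    stop("region(s) without a contralateral homolog: ",
         paste(orphan, collapse = ", "))
  }
  tab$homolog_id <- tab$id[idx]
  tab <- tab[, c("id", "abbreviation", "name", "hemisphere", "stem",
                 "homolog_id")]
  class(tab) <- c("region_table", "data.frame")
  tab
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("region_table: %d regions (%d L / %d R)\n", nrow(x),
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Id of the mirror-hemisphere homolog
#'
#' @param table A `region_table`.
#' @param region_id Integer region id(s).
#' @return Integer id(s) of the homologous region(s) in the other hemisphere.
#' @export
homolog_of <- function(table, region_id) {
  idx <- match(region_id, table$id)
  if (anyNA(idx)) stop("unknown region id(s): ",
                       paste(region_id[is.na(idx)], collapse = ", "))
  table$homolog_id[idx]
}

#' Composite region of interest
#'
#' A labelled set of region abbreviation stems that are analysed as one node,
#' e.g. the hippocampus as the union of CA1, CA2, CA3 and DG.
#'
#' @param label ROI label.
#' @param members Character vector of abbreviation stems (no hemisphere
#'   prefix), non-empty and without duplicates.
#' @return A `composite_roi` object.
#' @export
composite_roi <- function(label, members) {
  members <- as.character(members)
  if (length(members) == 0L) stop("composite ROI needs at least one member")
  if (anyDuplicated(members)) stop("duplicate members in composite ROI '",
                                   label, "'")
  structure(list(label = label, members = members), class = "composite_roi")
}

# The ten predetermined ROIs, in the study's order. The hippocampus is the
# CA1+CA2+CA3+DG union; the isocortex region stands in for the visual cortex.
.predetermined <- list(
  "cerebellum"           = "CB",
  "entorhinal cortex"    = "EC",
  "hippocampus"          = c("CA1", "CA2", "CA3", "DG"),
  "hypothalamus"         = "HY",
  "medulla"              = "MY",
  "somatomotor cortex"   = "MO",
  "somatosensory cortex" = "SS",
  "superior colliculus"  = "SUC",
  "thalamus"             = "TH",
  "visual cortex"        = "ICtx"
)

#' Predetermined regions of interest
#'
#' The ten composite ROIs examined region-by-region: cerebellum, entorhinal
#' cortex, hippocampus, hypothalamus, medulla, somatomotor cortex,
#' somatosensory cortex, superior colliculus, thalamus, and visual cortex.
#'
#' @return Character vector of the ten ROI labels, in that fixed order.
#' @seealso [roi_definition()] for a label's member regions.
#' @export
predetermined_rois <- function() names(.predetermined)

#' Definition of a predetermined ROI
#'
#' @param label One of [predetermined_rois()].
#' @return A [composite_roi()] with the label's member abbreviation stems.
#' @export
roi_definition <- function(label) {
  if (!label %in% names(.predetermined)) {
    stop("unknown predetermined ROI '", label, "'; available: ",
         paste(names(.predetermined), collapse = ", "))
  }
  composite_roi(label, .predetermined[[label]])
}

#' Resolve a composite ROI to region ids in one hemisphere
#'
#' @param table A `region_table`.
#' @param roi A `composite_roi`, or a label accepted by [roi_definition()].
#' @param hemisphere `"L"` or `"R"`.
#' @return Integer vector of region ids, ascending.
#' @export
resolve_composite <- function(table, roi, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  if (is.character(roi)) roi <- roi_definition(roi)
  stopifnot(inherits(roi, "composite_roi"))
  half <- table[table$hemisphere == hemisphere, ]
  idx <- match(roi$members, half$stem)
  if (anyNA(idx)) {
    stop("ROI '", roi$label, "' member(s) not in hemisphere ", hemisphere,
         ": ", paste(roi$members[is.na(idx)], collapse = ", "))
  }
  sort(half$id[idx])
}
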