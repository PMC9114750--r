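#' @keywords internal
"_PACKAGE"

# Closed vocabularies for the study roster.
ETHNICITIES <- c("Asian", "Caucasian", "African")
SOURCES <- c("HB", "PB")
SUBGROUP_AXES <- c("total", "hwe_subset", "cancer_type", "system",
                   "ethnicity", "source")

REQUIRED_COLS <- c("study_id", "first_author", "year", "origin",
                   "cancer_type", "system", "ethnicity", "source",
                   "n_case", "n_control", "hwe_p", "method")
COUNT_COLS <- c("case_AA", "case_AG", "case_GG",
                "ctrl_AA", "ctrl_AG", "ctrl_GG")

#' Path to a packaged data file
#'
#' Convenience wrapper around [system.file()] for the files shipped under
#' `extdata/`: the 87-row study roster (`table1_studies.tsv`) and the
#' cancer-type to organ-system mapping (`system_map.tsv`).
#'
#' @param file File name under `extdata/`.
#' @return Absolute path to the file.
#' @export
snpmeta_extdata <- function(file) {
  path <- system.file("extdata", file, package = "snpmeta", mustWork = FALSE)
  if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Read and validate a study roster
#'
#' Reads a tab-separated study table in the roster schema: one row per
#' case-control study with metadata (author, year, origin, cancer type, organ
#' system, ethnicity, control source), arm sizes, the control-group
#' Hardy-Weinberg p-value as reported, the genotyping method, and optional
#' per-arm genotype counts (`case_AA` ... `ctrl_GG`; empty fields mean the
#' counts were not reported).
#'
#' An `hwe_p` entry of the form `"<x"` (below detection, e.g. `"<0.001"`) is
#' stored as `x / 2` and flagged in the logical column `hwe_below_detection`;
#' only the comparison against the screening threshold is ever consumed
#' downstream, so the placeholder value is inert.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A validated `data.frame` with one row per study, columns
#'   `study_id, first_author, year, origin, cancer_type, system, ethnicity,
#'   source, n_case, n_control, hwe_p, hwe_below_detection, method` and the
#'   six genotype-count columns (`NA` when absent). Row order is preserved.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = TRUE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  missing <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in COUNT_COLS) if (!col %in% names(raw)) raw[[col]] <- ""

  parse_int <- function(col, allow_na = FALSE) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) & nzchar(x))
    if (length(bad) > 0)
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           call. = FALSE)
    if (!allow_na && anyNA(out))
      stop("empty value in required column '", col, "'", call. = FALSE)
    out
  }

  hwe_raw <- trimws(raw$hwe_p)
  below <- grepl("^<", hwe_raw)
  hwe_num <- suppressWarnings(as.numeric(sub("^<", "", hwe_raw)))
  bad <- which(is.na(hwe_num))
  if (length(bad) > 0)
    stop("unparseable hwe_p at row ", bad[1], ": '", hwe_raw[bad[1]], "'",
         call. = FALSE)
  hwe_num[below] <- hwe_num[below] / 2

  studies <- data.frame(
    study_id = trimws(raw$study_id),
    first_author = trimws(raw$first_author),
    year = parse_int("year"),
    origin = trimws(raw$origin),
    cancer_type = trimws(raw$cancer_type),
    system = ifelse(nzchar(trimws(raw$system)), trimws(raw$system),
                    NA_character_),
    ethnicity = trimws(raw$ethnicity),
    source = trimws(raw$source),
    n_case = parse_int("n_case"),
    n_control = parse_int("n_control"),
    hwe_p = hwe_num,
    hwe_below_detection = below,
    method = trimws(raw$method),
    stringsAsFactors = FALSE
  )
  for (col in COUNT_COLS) studies[[col]] <- parse_int(col, allow_na = TRUE)
  validate_studies(studies)
}

#' Validate a study roster data frame
#'
#' Enforces the roster invariants: unique study ids, positive arm sizes,
#' closed ethnicity/source vocabularies, `hwe_p` in `[0, 1]`, non-negative
#' genotype counts that are either all present or all absent per arm, and
#' genotype-count totals equal to the declared arm sizes.
#'
#' @param studies A roster `data.frame` in the [read_study_table()] schema.
#' @return The input, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_studies <- function(studies) {
  stopifnot(is.data.frame(studies))
  if (anyDuplicated(studies$study_id))
    stop("duplicate study_id: ",
         studies$study_id[duplicated(studies$study_id)][1], call. = FALSE)
  if (any(studies$n_case < 1) || any(studies$n_control < 1))
    stop("n_case and n_control must be >= 1 (row ",
         which(studies$n_case < 1 | studies$n_control < 1)[1], ")",
         call. = FALSE)
  bad_eth <- !studies$ethnicity %in% ETHNICITIES
  if (any(bad_eth))
    stop("unknown ethnicity '", studies$ethnicity[bad_eth][1],
         "' (expected ", paste(ETHNICITIES, collapse = "/"), ")",
         call. = FALSE)
  bad_src <- !studies$source %in% SOURCES
  if (any(bad_src))
    stop("unknown source '", studies$source[bad_src][1],
         "' (expected HB/PB)", call. = FALSE)
  if (any(studies$hwe_p < 0 | studies$hwe_p > 1))
    stop("hwe_p outside [0, 1]", call. = FALSE)

  for (arm in c("case", "ctrl")) {
    cols <- paste0(arm, c("_AA", "_AG", "_GG"))
    present <- rowSums(!is.na(as.matrix(studies[cols]))) # 0 or 3
    if (any(!present %in% c(0L, 3L)))
      stop("partial genotype counts for study ",
           studies$study_id[present %in% c(1L, 2L)][1], call. = FALSE)
    full <- present == 3L
    if (any(full)) {
      m <- as.matrix(studies[full, cols])
      if (any(m < 0)) stop("negative genotype count", call. = FALSE)
      n <- if (arm == "case") studies$n_case[full] else studies$n_control[full]
      off <- rowSums(m) != n
      if (any(off))
        stop("genotype counts do not sum to the ", arm, " arm size for study ",
             studies$study_id[full][off][1], call. = FALSE)
    }
  }
  invisible(studies)
}

#' Does each study carry genotype counts?
#'
#' @param studies A roster `data.frame`.
#' @return Logical vector, `TRUE` where both arms have complete counts.
#' @export
has_genotype_counts <- function(studies) {
  rowSums(!is.na(as.matrix(studies[COUNT_COLS]))) == length(COUNT_COLS)
}

#' Map a cancer type to its organ system
#'
#' The roster taxonomy groups cancer types into five organ systems (digestive
#' tract, orthopedic, urinary tract, gynecological, hematological); types
#' outside the taxonomy (e.g. breast, lung) map to `NA`. The mapping is
#' shipped as an editable data file (`system_map.tsv`), not hard-coded.
#'
#' @param cancer_type Character vector of cancer-type labels.
#' @param map Optional mapping `data.frame` with columns `cancer_type` and
#'   `system`; defaults to the packaged mapping.
#' @return Character vector of system labels, `NA` where unmapped.
#' @export
classify_system <- function(cancer_type, map = NULL) {
  stopifnot(all(nzchar(cancer_type)))
  if (is.null(map))
    map <- utils::read.delim(snpmeta_extdata("system_map.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  map$system[match(cancer_type, map$cancer_type)]
}

#' Group studies by cancer type, lumping singletons into "others"
#'
#' Each cancer type represented by at least two studies forms its own group;
#' all types contributed by exactly one study are merged into a single group
#' labelled `"others"`. Every study lands in exactly one group.
#'
#' @param studies A roster `data.frame`.
#' @return Named list of roster subsets, one per group; empty list for empty
#'   input.
#' @export
group_cancer_types <- function(studies) {
  if (nrow(studies) == 0) return(list())
  counts <- table(studies$cancer_type)
  multi <- names(counts)[counts >= 2]
  groups <- lapply(multi, function(ct) studies[studies$cancer_type == ct, ,
                                               drop = FALSE])
  names(groups) <- multi
  singles <- studies[studies$cancer_type %in% names(counts)[counts == 1], ,
                     drop = FALSE]
  if (nrow(singles) > 0) groups$others <- singles
  groups
}

#' Filter a roster to one subgroup
#'
#' Subgroup axes mirror the stratified analysis: `total` (identity),
#' `hwe_subset` (controls consistent with Hardy-Weinberg at the threshold),
#' `cancer_type`, `system`, `ethnicity` and `source`. Row order is preserved.
#'
#' @param studies A roster `data.frame`.
#' @param axis One of `r paste0('\x60', SUBGROUP_AXES, '\x60', collapse = ", ")`.
#' @param level Subgroup level for the field axes; ignored (must be `NULL`)
#'   for `total` and `hwe_subset`.
#' @param hwe_threshold Controls with `hwe_p >=` this value are retained on
#'   the `hwe_subset` axis (default 0.05).
#' @return The filtered roster `data.frame`.
#' @export
filter_subgroup <- function(studies, axis, level = NULL,
                            hwe_threshold = 0.05) {
  axis <- match.arg(axis, SUBGROUP_AXES)
  if (axis %in% c("total", "hwe_subset")) {
    if (!is.null(level))
      stop("axis '", axis, "' carries no level", call. = FALSE)
    if (axis == "total") return(studies)
    return(studies[studies$hwe_p >= hwe_threshold, , drop = FALSE])
  }
  if (is.null(level)) stop("axis '", axis, "' requires a level", call. = FALSE)
  if (axis == "ethnicity" && !level %in% ETHNICITIES)
    stop("invalid ethnicity level '", level, "'", call. = FALSE)
  if (axis == "source" && !level %in% SOURCES)
    stop("invalid source level '", level, "'", call. = FALSE)
  field <- studies[[axis]]
  studies[!is.na(field) & field == level, , drop = FALSE]
}

#' Study count and arm totals for a roster subset
#'
#' @param studies A roster `data.frame` (possibly empty).
#' @return Named list `k` (number of studies), `case_total`, `control_total`.
#' @export
aggregate_counts <- function(studies) {
  list(k = nrow(studies),
       case_total = sum(studies$n_case),
       control_total = sum(studies$n_control))
}
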