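#' Construct the four binary maternal-health outcomes
#'
#' Builds the outcome indicators from their service-component fields:
#' \describe{
#'   \item{early_anc}{1 iff the first antenatal-care visit was with a
#'     skilled provider and began within the first three months of
#'     pregnancy.}
#'   \item{anc4plus}{1 iff at least four skilled ANC visits were received.}
#'   \item{quality_anc}{1 iff all three of blood-pressure measurement,
#'     blood test and urine test were received during ANC.}
#'   \item{pnc2days}{1 iff a skilled postnatal contact occurred within two
#'     days of delivery.}
#' }
#' Components coded `NA` (service not applicable, e.g. no birth in the
#' recall window) yield `NA` outcomes, so each outcome keeps its own
#' analysis denominator.
#'
#' @param data a data frame of woman-level records.
#' @param mapping named list of column names:
#'   `anc_skilled` (0/1 first ANC with skilled provider),
#'   `anc_timing_months` (month of pregnancy at first ANC),
#'   `anc_visits` (number of skilled ANC visits),
#'   `bp_check`, `blood_test`, `urine_test` (0/1 service receipt),
#'   `pnc_skilled` (0/1 skilled PNC), `pnc_timing_days` (days from
#'   delivery to PNC).
#' @return `data` with columns `early_anc`, `anc4plus`, `quality_anc`,
#'   `pnc2days` appended.
#' @export
build_outcomes <- function(data, mapping) {
  need <- c("anc_skilled", "anc_timing_months", "anc_visits",
            "bp_check", "blood_test", "urine_test",
            "pnc_skilled", "pnc_timing_days")
  missing_keys <- setdiff(need, names(mapping))
  if (length(missing_keys)) {
    stop("mapping lacks component fields: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  cols <- unlist(mapping[need])
  absent <- setdiff(cols, names(data))
  if (length(absent)) stop("columns not in data: ", paste(absent, collapse = ", "),
                           call. = FALSE)

  g <- function(key) data[[mapping[[key]]]]
  timing <- g("anc_timing_months")
  visits <- g("anc_visits")
  pnc_days <- g("pnc_timing_days")
  if (any(timing < 0, na.rm = TRUE) || any(pnc_days < 0, na.rm = TRUE)) {
    stop("negative service timing", call. = FALSE)
  }
  if (any(visits < 0, na.rm = TRUE)) stop("negative visit count", call. = FALSE)

  for (key in c("anc_skilled", "bp_check", "blood_test", "urine_test", "pnc_skilled")) {
    v <- g(key)
    if (!all(v %in% c(0, 1, NA))) {
      stop("component `", mapping[[key]], "` must be coded 0/1", call. = FALSE)
    }
  }

  data$early_anc <- as.integer(g("anc_skilled") == 1 & timing >= 1 & timing <= 3)
  data$anc4plus <- as.integer(g("anc_skilled") == 1 & visits >= 4)
  data$quality_anc <- as.integer(g("bp_check") == 1 & g("blood_test") == 1 &
                                   g("urine_test") == 1)
  data$pnc2days <- as.integer(g("pnc_skilled") == 1 & pnc_days <= 2)
  data
}

#' Recode missing / "don't know" covariate responses
#'
#' Replaces sentinel responses in each covariate by that covariate's
#' designated least-advantaged category (e.g. "don't know" occupation
#' becomes "no occupation"). Rows are never dropped: the recoded women stay
#' in every denominator.
#'
#' @param data a data frame.
#' @param recode_map named list: covariate column -> replacement category.
#' @param sentinels values treated as missing; `NA` is always treated as a
#'   sentinel.
#' @return `data` with recoded covariates; the total number of replaced
#'   cells is attached as attribute `"n_recoded"`.
#' @export
recode_missing <- function(data, recode_map,
                           sentinels = c("dont_know", "don't know", "missing", "")) {
  if (!length(recode_map)) return(structure(data, n_recoded = 0L))
  absent <- setdiff(names(recode_map), names(data))
  if (length(absent)) stop("recode_map names not in data: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  bad <- vapply(recode_map, function(v) !is.character(v) || length(v) != 1L || is.na(v),
                logical(1))
  if (any(bad)) {
    stop("covariate(s) lacking a designated replacement category: ",
         paste(names(recode_map)[bad], collapse = ", "), call. = FALSE)
  }
  n_rec <- 0L
  for (col in names(recode_map)) {
    v <- data[[col]]
    was_factor <- is.factor(v)
    v <- as.character(v)
    hit <- is.na(v) | v %in% sentinels
    v[hit] <- recode_map[[col]]
    n_rec <- n_rec + sum(hit)
    data[[col]] <- if (was_factor) factor(v) else v
  }
  structure(data, n_recoded = n_rec)
}

#' Pool surveys and rescale weights so each survey counts equally
#'
#' Appends per-survey tables (or takes an already-appended table), rescales
#' the sampling weights within each survey so that every survey's weights
#' sum to a common `target_total`, and builds design identifiers that are
#' unique across surveys (the same stratum or cluster label appearing in
#' two surveys must not be treated as one design unit).
#'
#' @param tables a list of per-survey data frames, or a single pooled data
#'   frame containing `survey_col`.
#' @param survey_col,weight_col,stratum_col,cluster_col column names.
#' @param survey_labels labels for the surveys when `tables` is a list
#'   without a survey column (defaults to list names or 1..k).
#' @param target_total the common per-survey weight total (default 1; any
#'   common constant satisfies "each survey counts equally").
#' @return The pooled data frame with columns `rescaled_weight`,
#'   `unique_stratum` and `unique_cluster` appended.
#' @export
pool_and_rescale <- function(tables, survey_col = "survey_year",
                             weight_col = "weight", stratum_col = "stratum",
                             cluster_col = "cluster", survey_labels = NULL,
                             target_total = 1) {
  if (!is.numeric(target_total) || length(target_total) != 1L || target_total <= 0) {
    stop("`target_total` must be a positive scalar", call. = FALSE)
  }
  if (is.data.frame(tables)) {
    if (!survey_col %in% names(tables)) {
      stop("pooled table lacks survey column `", survey_col, "`", call. = FALSE)
    }
    pooled <- tables
  } else {
    stopifnot(is.list(tables), length(tables) >= 1L)
    labs <- survey_labels %||% names(tables) %||% as.character(seq_along(tables))
    if (is.null(names(tables)) && is.null(survey_labels)) labs <- as.character(seq_along(tables))
    if (length(labs) != length(tables)) stop("one survey label per table required", call. = FALSE)
    tables <- Map(function(tb, lab) {
      if (!survey_col %in% names(tb)) tb[[survey_col]] <- lab
      tb
    }, tables, labs)
    pooled <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  }
  for (col in c(weight_col, stratum_col, cluster_col)) {
    if (!col %in% names(pooled)) stop("column `", col, "` not found", call. = FALSE)
  }
  w <- pooled[[weight_col]]
  if (anyNA(w) || any(w <= 0)) stop("weights must be positive and complete", call. = FALSE)

  survey <- as.character(pooled[[survey_col]])
  totals <- tapply(w, survey, sum)
  if (any(totals <= 0)) stop("a survey has zero total weight", call. = FALSE)
  pooled$rescaled_weight <- as.numeric(w * target_total / totals[survey])
  pooled$unique_stratum <- paste(survey, pooled[[stratum_col]], sep = ":")
  pooled$unique_cluster <- paste(survey, pooled[[cluster_col]], sep = ":")
  pooled
}

#' Read a woman-level table from delimited text
#'
#' Thin wrapper over [utils::read.csv()] (comma-separated, header row,
#' UTF-8), the canonical input dialect.
#'
#' @param path file path.
#' @param ... passed to [utils::read.csv()].
#' @return A data frame.
#' @export
read_woman_table <- function(path, ...) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8", ...)
}

#' Read a woman-level table from a Stata file
#'
#' Convenience reader for the Stata format in which DHS recode files ship;
#' requires the suggested \pkg{foreign} package.
#'
#' @param path path to a `.dta` file.
#' @return A data frame.
#' @export
read_woman_table_dta <- function(path) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("reading Stata files requires the `foreign` package", call. = FALSE)
  }
  foreign::read.dta(path, convert.factors = TRUE)
}
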