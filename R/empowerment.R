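# SWPER-style empowerment scoring. The three domains (attitude to violence,
# social independence, decision-making) are linear scores over 14 DHS items
# with externally supplied loadings; the package consumes loadings, item
# centering/scaling constants and two cutpoints per domain as configuration
# and never re-estimates them.

#' The 14 empowerment items, in canonical order
#' @return Character vector of item names.
#' @export
swper_items <- function() {
  c("beat_goes_out", "beat_neglects_children", "beat_argues",
    "beat_refuses_sex", "beat_burns_food",
    "freq_reading", "education_years", "age_first_cohabitation",
    "age_first_birth", "age_difference", "education_difference",
    "decide_healthcare", "decide_purchases", "decide_visits")
}

#' Empowerment-domain names
#' @return Character vector of the three domain names.
#' @export
swper_domains <- function() {
  c("attitude_to_violence", "social_independence", "decision_making")
}

#' Assemble an empowerment scoring configuration
#'
#' @param loadings named list, one element per domain, each a named numeric
#'   vector of 14 item loadings (names = [swper_items()]).
#' @param centers,scales named numeric vectors of 14 item centering and
#'   scaling constants; scores use `(item - center) / scale`.
#' @param cutpoints named list, one element per domain, each a strictly
#'   increasing numeric vector of 2 cutpoints separating low / medium /
#'   high.
#' @param ranges optional named list of `c(min, max)` coded ranges per item,
#'   used for input validation.
#' @return An object of class `swper_weights`.
#' @export
swper_weights <- function(loadings, centers, scales, cutpoints, ranges = NULL) {
  items <- swper_items()
  doms <- names(loadings)
  if (is.null(doms) || !length(doms)) stop("`loadings` must be a named list per domain",
                                           call. = FALSE)
  for (d in doms) {
    l <- loadings[[d]]
    if (length(l) != 14L || is.null(names(l)) || !setequal(names(l), items)) {
      stop("domain `", d, "` must have exactly 14 named loadings (see swper_items())",
           call. = FALSE)
    }
    loadings[[d]] <- l[items]
  }
  for (nm in c("centers", "scales")) {
    v <- get(nm)
    if (length(v) != 14L || is.null(names(v)) || !setequal(names(v), items)) {
      stop("`", nm, "` must be a named numeric vector over the 14 items", call. = FALSE)
    }
  }
  if (any(scales[items] <= 0)) stop("item scales must be positive", call. = FALSE)
  if (!setequal(names(cutpoints), doms)) {
    stop("`cutpoints` must name the same domains as `loadings`", call. = FALSE)
  }
  for (d in doms) {
    cp <- cutpoints[[d]]
    if (length(cp) != 2L || diff(cp) <= 0) {
      stop("cutpoints for `", d, "` must be 2 strictly increasing values", call. = FALSE)
    }
  }
  structure(list(loadings = loadings, centers = centers[items],
                 scales = scales[items], cutpoints = cutpoints,
                 ranges = ranges),
            class = "swper_weights")
}

#' Read an empowerment scoring configuration from JSON
#'
#' The JSON file holds `loadings` (object per domain), `centers`, `scales`
#' (objects keyed by item), `cutpoints` (length-2 array per domain) and
#' optionally `ranges`. A synthetic placeholder asset is shipped at
#' `system.file("extdata", "swper_weights_synthetic.json", package =
#' "svyconc")`; replace its values with the published SWPER Global
#' constants for real analyses.
#'
#' @param path path to the JSON configuration.
#' @return An `swper_weights` object.
#' @export
read_swper_weights <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  swper_weights(loadings = lapply(cfg$loadings, function(l) unlist(l)),
                centers = unlist(cfg$centers),
                scales = unlist(cfg$scales),
                cutpoints = lapply(cfg$cutpoints, function(cp) as.numeric(unlist(cp))),
                ranges = if (!is.null(cfg$ranges)) lapply(cfg$ranges, as.numeric))
}

#' Score the empowerment domains and categorize women
#'
#' Computes, for every woman, each domain score
#' \eqn{\sum_j \lambda_j (x_j - c_j)/s_j} over the 14 items and the ordinal
#' low / medium / high category implied by the domain cutpoints.
#'
#' @param items data frame (or matrix) containing the 14 item columns named
#'   as in [swper_items()].
#' @param weights an [swper_weights] configuration.
#' @return A data frame with two columns per domain:
#'   `<domain>_score` (numeric) and `<domain>_category` (ordered factor
#'   low < medium < high).
#' @export
score_domains <- function(items, weights) {
  stopifnot(inherits(weights, "swper_weights"))
  nm <- swper_items()
  absent <- setdiff(nm, colnames(items))
  if (length(absent)) stop("missing item columns: ", paste(absent, collapse = ", "),
                           call. = FALSE)
  x <- as.matrix(as.data.frame(items)[nm])
  if (!is.numeric(x)) stop("items must be numeric per the coding book", call. = FALSE)
  if (anyNA(x)) stop("items contain missing values; recode them first", call. = FALSE)
  if (!is.null(weights$ranges)) {
    for (j in nm) {
      rg <- weights$ranges[[j]]
      if (is.null(rg)) next
      if (any(x[, j] < rg[1] | x[, j] > rg[2])) {
        stop("item `", j, "` outside its coded range [", rg[1], ", ", rg[2], "]",
             call. = FALSE)
      }
    }
  }
  z <- sweep(sweep(x, 2, weights$centers, "-"), 2, weights$scales, "/")
  out <- data.frame(row.names = seq_len(nrow(x)))
  for (d in names(weights$loadings)) {
    score <- drop(z %*% weights$loadings[[d]])
    out[[paste0(d, "_score")]] <- score
    out[[paste0(d, "_category")]] <- categorize(score, weights$cutpoints[[d]])
  }
  out
}

#' Categorize a domain score into low / medium / high
#'
#' Boundary convention (documented, left-closed on the upper side): a score
#' exactly at a cutpoint is promoted to the higher category, i.e.
#' `score < c1` is low, `c1 <= score < c2` is medium, `score >= c2` is
#' high.
#'
#' @param score numeric vector of domain scores.
#' @param cutpoints strictly increasing numeric vector of length 2.
#' @return Ordered factor with levels low < medium < high.
#' @export
categorize <- function(score, cutpoints) {
  if (length(cutpoints) != 2L || diff(cutpoints) <= 0) {
    stop("`cutpoints` must be 2 strictly increasing values", call. = FALSE)
  }
  lab <- c("low", "medium", "high")[1L + (score >= cutpoints[1]) + (score >= cutpoints[2])]
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}
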