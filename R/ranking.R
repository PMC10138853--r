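#' Weighted fractional ranks on an ordinal stratifier
#'
#' Ranks observations by an ordinal equity stratifier (e.g. empowerment
#' tertiles low < medium < high) using weighted fractional ranks with
#' category-midpoint tie handling: every member of a tied category \eqn{c}
#' with weighted population share \eqn{w_c} and cumulative share below it
#' \eqn{W_c} receives the rank \eqn{r = W_c + w_c/2}. The weighted mean rank
#' is exactly 0.5, the identity on which the concentration index relies.
#'
#' @param x the stratifier: an ordered factor, a factor whose level order is
#'   the advantage order, a numeric vector, or a character vector together
#'   with `levels` giving the ascending (least- to most-advantaged) order.
#' @param weights positive sampling weights, one per observation. Rescaling
#'   all weights by a constant leaves the ranks unchanged.
#' @param levels optional character vector of category labels in ascending
#'   order of advantage; required when `x` is character.
#'
#' @return An object of class `ranked_sample`: a list with elements
#'   `rank` (fractional rank per observation), `weight` (normalized weights
#'   summing to 1), `category` (ordered factor), `n`, and `categories`, a
#'   data frame of per-category weighted shares and midpoint ranks.
#'
#' @details A single observed category makes the ranking degenerate (every
#'   rank is 0.5 and the concentration index is undefined); this errors.
#'
#' @examples
#' rs <- fractional_rank(c("low", "medium", "high", "high"),
#'                       weights = rep(1, 4),
#'                       levels = c("low", "medium", "high"))
#' rs$rank                      # 0.125, 0.375, 0.75, 0.75
#' sum(rs$weight * rs$rank)     # 0.5
#' @export
fractional_rank <- function(x, weights, levels = NULL) {
  n <- length(x)
  if (n == 0L) stop("empty stratifier", call. = FALSE)
  check_weights(weights, n)
  if (anyNA(x)) stop("stratifier contains missing values; drop or recode them first",
                     call. = FALSE)

  if (is.character(x)) {
    if (is.null(levels)) {
      stop("character stratifier needs explicit `levels` in ascending order",
           call. = FALSE)
    }
    bad <- setdiff(unique(x), levels)
    if (length(bad)) stop("stratifier values not in `levels`: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    x <- factor(x, levels = levels, ordered = TRUE)
  } else if (is.factor(x)) {
    if (!is.null(levels)) x <- factor(as.character(x), levels = levels, ordered = TRUE)
    else x <- factor(x, levels = base::levels(x), ordered = TRUE)
  } else if (is.numeric(x)) {
    x <- factor(x, levels = sort(unique(x)), ordered = TRUE)
  } else {
    stop("unsupported stratifier type: ", class(x)[1L], call. = FALSE)
  }

  x <- droplevels(x)
  if (nlevels(x) < 2L) {
    stop("degenerate ranking: stratifier has a single observed category, ",
         "the concentration index is undefined", call. = FALSE)
  }

  wn <- weights / sum(weights)
  share <- vapply(split(wn, x), sum, numeric(1))      # level order
  cum_below <- cumsum(c(0, share[-length(share)]))
  midrank <- cum_below + share / 2

  structure(list(
    rank = unname(midrank[as.integer(x)]),
    weight = wn,
    category = x,
    n = n,
    categories = data.frame(category = base::levels(x),
                            share = unname(share),
                            rank = unname(midrank),
                            row.names = NULL)
  ), class = "ranked_sample")
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat("Weighted fractional ranking of", x$n, "observations on",
      nrow(x$categories), "ordinal categories\n")
  print(x$categories, row.names = FALSE)
  invisible(x)
}

#' Reverse the advantage order of a ranking
#'
#' Recomputes fractional ranks with the category order reversed. Reversing
#' the order flips the sign of any concentration index computed from the
#' ranking exactly.
#'
#' @param rs a `ranked_sample`.
#' @return A new `ranked_sample`.
#' @export
reverse_ranking <- function(rs) {
  stopifnot(inherits(rs, "ranked_sample"))
  fractional_rank(factor(as.character(rs$category),
                         levels = rev(base::levels(rs$category)), ordered = TRUE),
                  weights = rs$weight)
}
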