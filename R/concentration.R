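#' Standard concentration index
#'
#' The standard (relative) concentration index of a health variable `h`
#' against a weighted fractional ranking:
#' \deqn{CI = \frac{2}{\bar h} \mathrm{cov}_w(h, r)}
#' where the covariance is weighted with normalized weights and \eqn{\bar h}
#' is the weighted mean of `h`. Positive values indicate concentration of
#' `h` among the higher (more advantaged) stratifier categories.
#'
#' @param h numeric outcome, binary or non-negative, one value per
#'   observation in `rs`.
#' @param rs a [ranked_sample] from [fractional_rank()].
#' @return The concentration index, a scalar in \eqn{[-1, 1]}.
#' @export
concentration_index <- function(h, rs) {
  stopifnot(inherits(rs, "ranked_sample"))
  if (length(h) != rs$n) stop("`h` and ranking differ in length", call. = FALSE)
  if (anyNA(h)) stop("`h` contains missing values", call. = FALSE)
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  hbar <- sum(rs$weight * h)
  if (hbar <= 0) stop("mean of `h` is zero: concentration index undefined", call. = FALSE)
  2 * wtd_cov(h, rs$rank, rs$weight) / hbar
}

#' Erreygers-normalized concentration index for a binary outcome
#'
#' For a binary outcome the standard concentration index has bounds that
#' depend on the prevalence; the Erreygers correction
#' \deqn{ECI = \frac{4\hat y}{y_{max}-y_{min}} CI = 8\,\mathrm{cov}_w(h, r)}
#' (range 1 for binary outcomes) restores the \eqn{[-1, 1]} bounds, measures
#' absolute inequality, and satisfies the mirror property
#' \eqn{ECI(1-h) = -ECI(h)}. Positive values mean the outcome is
#' concentrated among the advantaged (higher) stratifier categories.
#'
#' @param h binary (0/1) outcome vector.
#' @param rs a [ranked_sample].
#' @param design optional list with elements `cluster` (primary sampling
#'   unit IDs) and optionally `strata`; enables design-based uncertainty.
#'   With `design = NULL` each observation is its own cluster in one
#'   stratum (plain heteroskedasticity-robust inference).
#' @param se_method `"linearized"` (default; cluster-robust convenient
#'   regression, the Taylor-linearization analogue), `"bootstrap"`
#'   (stratified cluster bootstrap, percentile interval), or `"none"`.
#' @param conf_level confidence level, default 0.95.
#' @param boot_reps bootstrap replicates (default 1000).
#' @param boot_seed seed for the bootstrap resampling.
#'
#' @return An object of class `concentration_result`: list with
#'   `prevalence`, `ci_standard`, `eci`, `se`, `ci95` (a length-2 vector),
#'   `n`, `method`, `conf_level`, `outcome_range` (fixed at 1), `df`.
#'
#' @details The point estimate is always the weighted-covariance formula
#'   \eqn{8\,\mathrm{cov}_w(h,r)}. The linearized SE comes from the
#'   "convenient regression" identity: the weighted least-squares slope of
#'   `h` on `r` equals \eqn{\mathrm{cov}_w(h,r)/\sigma_r^2}, so
#'   \eqn{ECI = 8\sigma_r^2 b} and \eqn{se(ECI) = 8\sigma_r^2\,se(b)} with a
#'   stratified cluster-robust variance for \eqn{b} and a t reference
#'   distribution on (clusters - strata) degrees of freedom. Strata
#'   containing a single cluster are collapsed into one pseudo-stratum with
#'   a warning (bootstrap instead errors, since within-stratum resampling
#'   needs at least two clusters).
#' @export
erreygers_index <- function(h, rs, design = NULL,
                            se_method = c("linearized", "bootstrap", "none"),
                            conf_level = 0.95, boot_reps = 1000, boot_seed = NULL) {
  stopifnot(inherits(rs, "ranked_sample"))
  se_method <- match.arg(se_method)
  if (length(h) != rs$n) stop("`h` and ranking differ in length", call. = FALSE)
  check_binary(h)

  w <- rs$weight
  r <- rs$rank
  yhat <- sum(w * h)
  if (yhat <= 0) stop("prevalence is zero: index undefined", call. = FALSE)
  eci <- 8 * wtd_cov(h, r, w)
  ci_std <- eci / (4 * yhat)

  unc <- switch(se_method,
    none = list(se = NA_real_, ci95 = c(NA_real_, NA_real_), df = NA_real_),
    linearized = eci_linearized(h, rs, design, conf_level),
    bootstrap = eci_bootstrap(h, rs, design, conf_level, boot_reps, boot_seed)
  )

  structure(list(
    prevalence = yhat,
    ci_standard = ci_std,
    eci = eci,
    se = unc$se,
    ci95 = unc$ci95,
    n = rs$n,
    method = se_method,
    conf_level = conf_level,
    outcome_range = 1,
    df = unc$df
  ), class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, digits = 3, ...) {
  cat("Erreygers-normalized concentration index\n")
  cat(sprintf("  n = %d, prevalence = %.*f\n", x$n, digits, x$prevalence))
  cat(sprintf("  standard CI = %.*f\n", digits, x$ci_standard))
  if (is.na(x$se)) {
    cat(sprintf("  ECI = %.*f\n", digits, x$eci))
  } else {
    cat(sprintf("  ECI = %.*f (SE %.*f, %g%% CI %.*f, %.*f; %s)\n",
                digits, x$eci, digits, x$se, 100 * x$conf_level,
                digits, x$ci95[1], digits, x$ci95[2], x$method))
  }
  invisible(x)
}

# --- design handling ---------------------------------------------------------

normalize_design <- function(design, n) {
  if (is.null(design)) {
    return(list(cluster = as.character(seq_len(n)), strata = rep("1", n)))
  }
  cl <- design$cluster %||% design$unique_cluster
  if (is.null(cl)) stop("`design` must provide `cluster` IDs", call. = FALSE)
  if (length(cl) != n) stop("design cluster IDs differ in length from the data", call. = FALSE)
  st <- design$strata %||% design$unique_stratum %||% rep("1", n)
  if (length(st) != n) stop("design strata differ in length from the data", call. = FALSE)
  list(cluster = as.character(cl), strata = as.character(st))
}

# Collapse strata that contain a single cluster into one pseudo-stratum
# (they carry no between-cluster information on their own).
collapse_singleton_strata <- function(cluster, strata, warn = TRUE) {
  tab <- tapply(cluster, strata, function(z) length(unique(z)))
  singletons <- names(tab)[tab < 2]
  if (length(singletons)) {
    if (length(singletons) == 1 && length(tab) > 1) {
      # merge the lone singleton into the largest remaining stratum
      target <- names(tab)[which.max(ifelse(names(tab) %in% singletons, -1, tab))]
      strata[strata %in% singletons] <- target
    } else {
      strata[strata %in% singletons] <- ".collapsed"
    }
    if (warn) warning(length(singletons),
                      " stratum(s) with a single cluster collapsed for variance estimation",
                      call. = FALSE)
  }
  strata
}

# Stratified cluster-robust variance of the WLS slope of h on r
# (Taylor linearization). Influence values are summed within clusters;
# per-stratum with n_h clusters the contribution is
# n_h/(n_h-1) * sum_c (z_hc - zbar_h)^2.
eci_linearized <- function(h, rs, design, conf_level) {
  d <- normalize_design(design, rs$n)
  w <- rs$weight
  r <- rs$rank
  rbar <- sum(w * r)
  srr <- sum(w * (r - rbar)^2)            # sigma_r^2 (weights sum to 1)
  b <- wtd_cov(h, r, w) / srr
  a <- sum(w * h) - b * rbar
  e <- h - a - b * r
  infl <- w * e * (r - rbar) / srr        # influence values for the slope

  strata <- collapse_singleton_strata(d$cluster, d$strata,
                                      warn = length(unique(d$strata)) > 1)
  key <- paste(strata, d$cluster, sep = "\r")
  z <- tapply(infl, key, sum)
  zs <- sub("\r.*$", "", names(z))
  var_b <- 0
  for (s in unique(zs)) {
    zh <- z[zs == s]
    nh <- length(zh)
    if (nh < 2) next                      # no between-cluster information
    var_b <- var_b + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  se <- 8 * srr * sqrt(var_b)
  n_clusters <- length(z)
  n_strata <- length(unique(zs))
  df <- max(n_clusters - n_strata, 1)
  eci <- 8 * srr * b
  half <- stats::qt(1 - (1 - conf_level) / 2, df) * se
  list(se = se, ci95 = c(eci - half, eci + half), df = df)
}

# Stratified cluster bootstrap: resample clusters with replacement within
# strata, rebuild ranks and weights on the resample, recompute the ECI.
eci_bootstrap <- function(h, rs, design, conf_level, reps, seed) {
  d <- normalize_design(design, rs$n)
  by_stratum <- split(seq_len(rs$n), d$strata)
  for (s in names(by_stratum)) {
    if (length(unique(d$cluster[by_stratum[[s]]])) < 2) {
      stop("stratified cluster bootstrap needs >= 2 clusters per stratum ",
           "(stratum '", s, "' has fewer); collapse strata first", call. = FALSE)
    }
  }
  cluster_rows <- lapply(by_stratum, function(idx) split(idx, d$cluster[idx]))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  cat_chr <- as.character(rs$category)
  lev <- base::levels(rs$category)
  stat <- function(idx) {
    rsb <- fractional_rank(cat_chr[idx], weights = rs$weight[idx], levels = lev)
    8 * wtd_cov(h[idx], rsb$rank, rsb$weight)
  }
  boots <- vapply(seq_len(reps), function(i) {
    idx <- unlist(lapply(cluster_rows, function(cls) {
      unlist(cls[sample.int(length(cls), replace = TRUE)], use.names = FALSE)
    }), use.names = FALSE)
    tryCatch(stat(idx), error = function(e) NA_real_)
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf_level) / 2
  list(se = stats::sd(boots),
       ci95 = unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7)),
       df = NA_real_)
}

#' Concentration curve coordinates
#'
#' The concentration curve plots \eqn{L(p)}, the cumulative weighted share
#' of the outcome held by the bottom-ranked population share \eqn{p},
#' against \eqn{p}. For an ordinal stratifier the curve is piecewise linear
#' with vertices at the cumulative category boundaries. A curve below the
#' diagonal means the outcome is concentrated among the advantaged
#' (positive index); the standard concentration index equals twice the
#' signed area between the diagonal and the curve.
#'
#' @param h binary or non-negative outcome.
#' @param rs a [ranked_sample].
#' @return An object of class `concentration_curve`: a data frame with
#'   columns `p` and `L` (vertices, starting at (0,0) and ending at (1,1)).
#' @export
concentration_curve <- function(h, rs) {
  stopifnot(inherits(rs, "ranked_sample"))
  if (length(h) != rs$n) stop("`h` and ranking differ in length", call. = FALSE)
  if (anyNA(h) || any(h < 0)) stop("`h` must be non-negative and complete", call. = FALSE)
  tot <- sum(rs$weight * h)
  if (tot <= 0) stop("outcome total is zero: curve undefined", call. = FALSE)
  wc <- vapply(split(rs$weight, rs$category), sum, numeric(1))
  hc <- vapply(split(rs$weight * h, rs$category), sum, numeric(1))
  out <- data.frame(p = c(0, cumsum(unname(wc))),
                    L = c(0, cumsum(unname(hc)) / tot))
  out$p[nrow(out)] <- 1   # guard rounding in the last cumulative sum
  out$L[nrow(out)] <- 1
  class(out) <- c("concentration_curve", "data.frame")
  out
}

#' Concentration index implied by a curve
#'
#' Twice the signed area between the line of equality and the concentration
#' curve, by exact trapezoidal integration of the piecewise-linear curve.
#' Agrees with the covariance-based [concentration_index()] and provides an
#' independent route to the same quantity.
#'
#' @param curve a [concentration_curve].
#' @return The implied standard concentration index.
#' @export
curve_implied_ci <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  p <- curve$p
  d <- p - curve$L
  2 * sum(diff(p) * (d[-1] + d[-length(d)]) / 2)
}

#' Plot a concentration curve
#'
#' @param x a [concentration_curve].
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.concentration_curve <- function(x, main = "Concentration curve", ...) {
  graphics::plot(x$p, x$L, type = "l", lwd = 2, col = "steelblue",
                 xlab = "Cumulative population share (ranked low to high)",
                 ylab = "Cumulative outcome share L(p)", main = main,
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}
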