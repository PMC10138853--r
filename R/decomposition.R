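# Regression-based decomposition of the Erreygers index: a survey-weighted
# binomial-logit model supplies derivative-form average marginal effects
# ME_k = beta_k * mean_w[p(1-p)]; the contribution of dummy k to the
# outcome's concentration index is elasticity_k * CI_k / CI, with
# elasticity_k = ME_k * xbar_k / yhat and CI_k the standard concentration
# index of the dummy against the same empowerment ranking. The derivative
# (not discrete-change) marginal effect is what makes the contributions an
# exact linear decomposition of the index approximation, so contributions
# plus the residual (generalized concentration of the approximation error)
# always total 100%.

#' Fit the survey-weighted binomial-logit outcome model
#'
#' Maximum-likelihood logit fit with normalized sampling weights
#' (quasibinomial family, identical point estimates to a design-weighted
#' logit). Categorical covariates are dummy-coded against declared
#' reference categories.
#'
#' @param data data frame holding the outcome and covariates.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate column names (coerced to
#'   factors).
#' @param weights positive sampling weights (vector or column name).
#' @param reference optional named list covariate -> reference category
#'   (default: first level).
#' @param maxit IRLS iteration cap.
#' @return Object of class `outcome_glm_fit`: coefficients, fitted
#'   probabilities `p`, derivative average marginal effects `me`, weighted
#'   dummy means `xbar`, the model matrix column <-> covariate map,
#'   `converged`, `dropped` (aliased dummies, if any), `n`, and the data
#'   pieces needed by [decompose_inequality()].
#' @export
fit_outcome_model <- function(data, outcome, covariates, weights,
                              reference = NULL, maxit = 100) {
  if (is.character(weights) && length(weights) == 1L) weights <- data[[weights]]
  h <- data[[outcome]]
  if (is.null(h)) stop("outcome column `", outcome, "` not found", call. = FALSE)
  keep <- !is.na(h)
  for (cv in covariates) {
    if (is.null(data[[cv]])) stop("covariate `", cv, "` not found", call. = FALSE)
    keep <- keep & !is.na(data[[cv]])
  }
  data <- data[keep, , drop = FALSE]
  h <- data[[outcome]]
  w <- weights[keep]
  check_binary(h, outcome)
  check_weights(w, nrow(data))

  for (cv in covariates) {
    f <- factor(as.character(data[[cv]]))
    ref <- reference[[cv]]
    if (!is.null(ref)) {
      if (!ref %in% levels(f)) stop("reference `", ref, "` not a level of `", cv, "`",
                                    call. = FALSE)
      f <- stats::relevel(f, ref = ref)
    }
    data[[cv]] <- f
  }

  fml <- stats::as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  wn <- w / mean(w)   # mean-1 normalization: scale-invariant fit, sane dispersion
  fit <- stats::glm(fml, family = stats::quasibinomial("logit"), data = data,
                    weights = wn, control = stats::glm.control(maxit = maxit))
  if (!fit$converged) {
    # retry from a damped start before giving up (sparse dummies can make
    # plain IRLS wander)
    start <- ifelse(is.na(stats::coef(fit)), 0, stats::coef(fit)) * 0.5
    fit <- stats::glm(fml, family = stats::quasibinomial("logit"), data = data,
                      weights = wn, start = start,
                      control = stats::glm.control(maxit = maxit * 4))
    if (!fit$converged) {
      stop("logit fit failed to converge (possible separation); simplify the model",
           call. = FALSE)
    }
  }
  beta <- stats::coef(fit)
  dropped <- names(beta)[is.na(beta)]
  if (length(dropped)) {
    warning("aliased (collinear) dummies dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  X <- stats::model.matrix(fit)
  ok <- !is.na(beta)
  beta <- beta[ok]
  X <- X[, names(beta), drop = FALSE]
  p <- stats::fitted(fit)

  slope <- wtd_mean(p * (1 - p), w)        # common derivative factor
  terms_k <- setdiff(names(beta), "(Intercept)")
  me <- beta[terms_k] * slope
  xbar <- vapply(terms_k, function(k) wtd_mean(X[, k], w), numeric(1))
  assign_map <- attr(stats::model.matrix(fit), "assign")
  names(assign_map) <- colnames(stats::model.matrix(fit))
  term_labels <- attr(stats::terms(fit), "term.labels")
  covar_of <- vapply(terms_k, function(k) term_labels[assign_map[[k]]], character(1))

  structure(list(
    coefficients = beta, p = p, me = me, xbar = xbar,
    covariate = covar_of, X = X, h = h, w = w,
    prevalence = wtd_mean(h, w), converged = TRUE, dropped = dropped,
    n = nrow(data), formula = fml, keep = keep
  ), class = "outcome_glm_fit")
}

#' @export
print.outcome_glm_fit <- function(x, digits = 3, ...) {
  cat("Survey-weighted logit fit: ", deparse(x$formula), "\n",
      "  n = ", x$n, ", prevalence = ", round(x$prevalence, digits), "\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Decompose the Erreygers index into covariate contributions
#'
#' For each non-reference dummy k of the fitted model:
#' elasticity \eqn{= ME_k \bar x_k / \hat y}, concentration index
#' \eqn{CI_k = (2/\bar x_k)\,\mathrm{cov}_w(x_k, r)}, and percent
#' contribution \eqn{= 100\, \mathrm{elasticity} \times CI_k / CI} where
#' \eqn{CI} is the outcome's standard concentration index. The residual
#' percentage (the generalized concentration of the approximation error)
#' is `100 - sum(contributions)`. Contributions are identical whether the
#' standard or the Erreygers index is decomposed, since the Erreygers
#' normalization cancels from the ratio.
#'
#' @param fit an [fit_outcome_model()] result.
#' @param rs a [ranked_sample] over the same rows (same order) as the fit.
#' @param result the outcome's [erreygers_index()] result on the same rows
#'   and ranking.
#' @return Object of class `decomposition_table`: data frame `rows` with
#'   columns `term`, `covariate`, `elasticity`, `conc_index`,
#'   `contribution_pct`, plus fields `residual_pct`, `eci`, `ci_standard`,
#'   `prevalence`, `n`.
#' @export
decompose_inequality <- function(fit, rs, result) {
  stopifnot(inherits(fit, "outcome_glm_fit"), inherits(rs, "ranked_sample"),
            inherits(result, "concentration_result"))
  if (rs$n != fit$n) stop("ranking and fit cover different rows", call. = FALSE)
  ci_std <- result$ci_standard
  if (!is.finite(ci_std) || ci_std == 0) {
    stop("outcome concentration index is zero: percent contributions are undefined; ",
         "report absolute contributions (elasticity x CI_k) instead",
         call. = FALSE)
  }
  r <- rs$rank
  w <- fit$w
  yhat <- fit$prevalence
  terms_k <- names(fit$me)

  elasticity <- conc_k <- contribution <- numeric(length(terms_k))
  for (i in seq_along(terms_k)) {
    k <- terms_k[i]
    xk <- fit$X[, k]
    xb <- fit$xbar[[k]]
    elasticity[i] <- fit$me[[k]] * xb / yhat
    conc_k[i] <- if (xb > 0) 2 * wtd_cov(xk, r, w) / xb else NA_real_
    contribution[i] <- if (xb > 0) 100 * elasticity[i] * conc_k[i] / ci_std else 0
  }
  rows <- data.frame(term = terms_k, covariate = unname(fit$covariate[terms_k]),
                     elasticity = elasticity, conc_index = conc_k,
                     contribution_pct = contribution, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(rows = rows,
                 residual_pct = 100 - sum(rows$contribution_pct),
                 eci = result$eci, ci_standard = ci_std,
                 prevalence = yhat, n = fit$n),
            class = "decomposition_table")
}

#' Annotate a decomposition with sign interpretations
#'
#' Adds `elasticity_direction` ("increases" / "decreases" / "no effect on"
#' service use) and `inequality_effect` ("widening" / "narrowing" /
#' "neutral") columns: a positive percent contribution widens, a negative
#' one narrows, the measured inequality.
#'
#' @param x a `decomposition_table`.
#' @param tol absolute tolerance below which a value counts as zero.
#' @return The table with annotation columns appended to `x$rows`.
#' @export
interpret_signs <- function(x, tol = 0) {
  stopifnot(inherits(x, "decomposition_table"))
  e <- x$rows$elasticity
  cpc <- x$rows$contribution_pct
  x$rows$elasticity_direction <- ifelse(abs(e) <= tol, "no effect on",
                                        ifelse(e > 0, "increases", "decreases"))
  x$rows$inequality_effect <- ifelse(abs(cpc) <= tol, "neutral",
                                     ifelse(cpc > 0, "widening", "narrowing"))
  x
}

#' @export
print.decomposition_table <- function(x, digits = 3, ...) {
  cat(sprintf("Decomposition of ECI = %.*f (standard CI %.*f, prevalence %.*f, n = %d)\n",
              digits, x$eci, digits, x$ci_standard, digits, x$prevalence, x$n))
  out <- x$rows
  for (cl in c("elasticity", "conc_index", "contribution_pct")) {
    out[[cl]] <- round(out[[cl]], digits)
  }
  print(out, row.names = FALSE)
  cat(sprintf("Residual: %.*f%%\n", digits, x$residual_pct))
  invisible(x)
}

#' Serialize a decomposition table
#'
#' Writes the table in the covariate / elasticity / CI / percent column
#' order with a trailing residual row.
#'
#' @param x a `decomposition_table`.
#' @param path output CSV path.
#' @param digits decimal places (default 3).
#' @return Invisibly, the data frame written.
#' @export
write_decomposition <- function(x, path, digits = 3) {
  stopifnot(inherits(x, "decomposition_table"))
  out <- data.frame(covariate = c(x$rows$term, "(residual)"),
                    elasticity = c(round(x$rows$elasticity, digits), NA),
                    CI = c(round(x$rows$conc_index, digits), NA),
                    percent = round(c(x$rows$contribution_pct, x$residual_pct), digits))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
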