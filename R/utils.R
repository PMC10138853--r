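# Internal weighted-statistics helpers. All covariances/variances are
# population-style (normalized weights, no n-1 correction), which is the
# convention under which CI = 2 cov_w(h, r) / mean_w(h) holds exactly.

wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_var <- function(x, w) {
  wn <- w / sum(w)
  m <- sum(wn * x)
  sum(wn * (x - m)^2)
}

wtd_cov <- function(x, y, w) {
  wn <- w / sum(w)
  mx <- sum(wn * x)
  my <- sum(wn * y)
  sum(wn * (x - mx) * (y - my))
}

check_weights <- function(w, n) {
  if (!is.numeric(w) || length(w) != n) {
    stop("`weights` must be a numeric vector of length ", n, call. = FALSE)
  }
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("all weights must be positive and finite", call. = FALSE)
  }
  invisible(w)
}

check_binary <- function(h, what = "h") {
  if (anyNA(h)) stop("`", what, "` contains missing values; subset to applicable rows first",
                     call. = FALSE)
  if (!all(h %in% c(0, 1))) {
    stop("`", what, "` must be binary (0/1); for non-binary outcomes use the standard ",
         "concentration index, not the Erreygers index", call. = FALSE)
  }
  invisible(h)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit
# integer range so set.seed() accepts it on all platforms.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 100003) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
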