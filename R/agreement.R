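#' Squared Pearson correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite.
#' @return r-squared in [0, 1]; `NA` when either input has zero variance.
#' @export
pearson_r2 <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Root-mean-square error between paired measurements
#'
#' @param x,y Equal-length numeric vectors.
#' @return `sqrt(mean((x - y)^2))`, in the units of the inputs.
#' @export
rmse <- function(x, y) {
  check_paired(x, y, min_n = 1L)
  sqrt(mean((x - y)^2))
}

check_paired <- function(x, y, min_n) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < min_n) {
    abort(paste0("Need at least ", min_n, " paired observations."))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Inputs must be finite.")
  }
  invisible(TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; bias is their mean, the 95% limits of agreement
#' are bias +/- 1.96 x sample SD of d, the reproducibility coefficient (RPC)
#' is 1.96 x SD, and the coefficient of variation is 100 x SD over the
#' overall mean of all observations from both methods. Sample (n-1) SDs
#' throughout.
#'
#' @param x,y Equal-length numeric vectors (n >= 3); `x` is the test method,
#'   `y` the reference.
#' @return A `gcg_bland_altman` object with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  overall <- mean(c(x, y))
  structure(list(
    data = tibble(x = x, y = y, mean = (x + y) / 2, diff = d),
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    rpc = 1.96 * s,
    cv_pct = if (overall == 0) NA_real_ else 100 * s / overall,
    n = length(x)
  ), class = "gcg_bland_altman")
}

#' @export
print.gcg_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n=%d  bias=%.3f  LoA=[%.3f, %.3f]  RPC=%.3f  CV=%s%%\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$rpc,
    ifelse(is.na(x$cv_pct), "NA", sprintf("%.2f", x$cv_pct))))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `gcg_bland_altman` object.
#' @param ... Unused.
#' @export
tidy.gcg_bland_altman <- function(x, ...) {
  tibble(term = c("bias", "sd_diff", "loa_low", "loa_high", "rpc", "cv_pct"),
         estimate = c(x$bias, x$sd_diff, x$loa_low, x$loa_high, x$rpc,
                      x$cv_pct))
}

#' @rdname bland_altman
#' @export
glance.gcg_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, rpc = x$rpc, cv_pct = x$cv_pct, n = x$n)
}

#' Paired-method agreement report over interval tables
#'
#' Inner-joins two per-beat (or per-subject) interval tables on the key
#' columns and computes, for every shared measurement column, the squared
#' Pearson correlation, RMSE and Bland-Altman statistics of
#' `measured - reference`.
#'
#' @param reference Reference table (e.g. ground truth).
#' @param measured Measured table.
#' @param keys Join keys (default `"beat"`).
#' @param vars Measurement columns; defaults to all shared numeric non-key
#'   columns.
#' @return Tibble with one row per measurement: `metric`, `n`, `r2`, `rmse`,
#'   `bias`, `sd_diff`, `loa_low`, `loa_high`, `rpc`, `cv_pct`.
#' @export
agreement_report <- function(reference, measured, keys = "beat",
                             vars = NULL) {
  joined <- inner_join(as_tibble(reference), as_tibble(measured), by = keys,
                       suffix = c("_ref", "_meas"))
  if (nrow(joined) == 0L) abort("Empty join: the tables share no keys.")
  shared <- intersect(setdiff(names(reference), keys),
                      setdiff(names(measured), keys))
  shared <- shared[vapply(shared, function(v) {
    is.numeric(reference[[v]]) && is.numeric(measured[[v]])
  }, logical(1))]
  vars <- vars %||% shared
  if (length(vars) == 0L) abort("No shared measurement columns.")
  rows <- purrr::map(vars, function(v) {
    xr <- joined[[paste0(v, "_ref")]]
    xm <- joined[[paste0(v, "_meas")]]
    ok <- is.finite(xr) & is.finite(xm)
    if (sum(ok) < 3L) {
      return(tibble(metric = v, n = sum(ok), r2 = NA_real_, rmse = NA_real_,
                    bias = NA_real_, sd_diff = NA_real_, loa_low = NA_real_,
                    loa_high = NA_real_, rpc = NA_real_, cv_pct = NA_real_))
    }
    ba <- bland_altman(xm[ok], xr[ok])
    tibble(metric = v, n = ba$n, r2 = pearson_r2(xm[ok], xr[ok]),
           rmse = rmse(xm[ok], xr[ok]), bias = ba$bias, sd_diff = ba$sd_diff,
           loa_low = ba$loa_low, loa_high = ba$loa_high, rpc = ba$rpc,
           cv_pct = ba$cv_pct)
  })
  bind_rows(rows)
}
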