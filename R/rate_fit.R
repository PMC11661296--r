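#' Estimate the binding rate on the linear part of a time series
#'
#' The "linear part" is located by sliding a window of
#' `ceiling(window_fraction * n)` frames over the series and selecting the
#' window that maximizes `slope * sign(net change)` among windows with
#' OLS r-squared of at least `min_r2` (falling back to the maximum-r-squared
#' window when none qualifies). Slope, intercept and standard error are the
#' closed-form ordinary-least-squares estimates on that window. The chosen
#' window is reported so rates stay auditable.
#'
#' @param ts A `binding_time_series` (or any data.frame with a time column
#'   and the value column named by `value`), at least 5 frames.
#' @param window_fraction Window length as a fraction of the series length.
#' @param min_r2 r-squared threshold defining an acceptably linear window.
#' @param value Name of the value column (default `"ratio"`).
#' @return An object of class `rate_fit`: `slope` (value units/min),
#'   `intercept`, `window` (start and end frame indices), `r2`, `se`, `n`.
#' @examples
#' ts <- simulate_rate_timeseries(slope = 0.1, t_linear_start = 5,
#'                                t_plateau = 15, n_frames = 20)
#' estimate_rate(ts)
#' @export
estimate_rate <- function(ts, window_fraction = 0.3, min_r2 = 0.9,
                          value = "ratio") {
  stopifnot(is.data.frame(ts), "time" %in% names(ts), value %in% names(ts))
  y <- ts[[value]]
  tt <- ts$time
  ok <- is.finite(y) & is.finite(tt)
  y <- y[ok]; tt <- tt[ok]
  n <- length(y)
  if (n < 5) stop("need at least 5 frames to estimate a rate")
  w <- ceiling(window_fraction * n)
  if (w < 3) w <- 3L
  if (w > n) stop("window longer than the series")
  net_sign <- sign(y[n] - y[1])
  if (net_sign == 0) net_sign <- 1
  stats_w <- lapply(seq_len(n - w + 1L), function(s) {
    idx <- s:(s + w - 1L)
    ols_closed_form(tt[idx], y[idx])
  })
  r2s <- vapply(stats_w, `[[`, numeric(1), "r2")
  slopes <- vapply(stats_w, `[[`, numeric(1), "slope")
  cand <- which(r2s >= min_r2)
  pick <- if (length(cand)) {
    cand[which.max(slopes[cand] * net_sign)]
  } else {
    which.max(r2s)
  }
  o <- stats_w[[pick]]
  structure(
    list(slope = o$slope, intercept = o$intercept,
         window = c(start = pick, end = pick + w - 1L),
         window_time = c(tt[pick], tt[pick + w - 1L]),
         r2 = o$r2, se = o$se, n = w),
    class = "rate_fit"
  )
}

# closed-form OLS of y on t with slope SE; r2 of a zero-variance residual
# (perfect fit, including a constant series) is defined as 1
ols_closed_form <- function(tt, y) {
  n <- length(y)
  tm <- mean(tt); ym <- mean(y)
  sxx <- sum((tt - tm)^2)
  slope <- sum((tt - tm) * (y - ym)) / sxx
  intercept <- ym - slope * tm
  res <- y - intercept - slope * tt
  rss <- sum(res^2)
  tss <- sum((y - ym)^2)
  r2 <- if (tss < .Machine$double.eps) {
    if (rss < .Machine$double.eps) 1 else 0
  } else {
    1 - rss / tss
  }
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, se = se)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "rate_fit: slope %.4g per min (SE %.3g), window frames %d-%d, r^2 = %.4f\n",
    x$slope, x$se, x$window["start"], x$window["end"], x$r2))
  invisible(x)
}
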