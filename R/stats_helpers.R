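#' Welch two-sample t-test with significance stars
#'
#' Two-tailed Student's t-test assuming unequal variances (Welch-
#' Satterthwaite degrees of freedom), with the conventional star categories:
#' `*` P <= 0.05, `**` P <= 0.01, `***` P <= 0.001, `****` P <= 0.0001,
#' `ns` P > 0.05. When both samples have zero variance and equal means the
#' result is t = 0, p = 1 rather than an error.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return An object of class `welch_test`: `t`, `df`, `p`, `stars`,
#'   `group_sizes`.
#' @examples
#' welch_ttest(c(1, 2, 3, 4), c(10, 11, 12, 13))
#' @export
welch_ttest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      out <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
    } else {
      out <- list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(
    list(t = out$t, df = out$df, p = out$p, stars = p_stars(out$p),
         group_sizes = c(length(a), length(b))),
    class = "welch_test"
  )
}

#' Star category for a p-value
#' @param p p-value in `[0, 1]`.
#' @return One of `"****"`, `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
p_stars <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.2f, p = %.4g (%s), n = %d/%d\n",
              x$t, x$df, x$p, x$stars, x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Join per-nucleus binding with per-FOV ER morphology
#'
#' ER metrics are quantified per field of view while binding is quantified
#' per nucleus; for correlation plots every nucleus in a FOV is therefore
#' assigned that FOV's ER value. A left join broadcasts the FOV columns to
#' each nucleus row; rows without a matching FOV are flagged and excluded
#' from the returned table (kept in the `excluded` attribute). Duplicate FOV
#' rows for the same key are an error.
#'
#' @param nucleus_table data.frame with a `fov` column (and optionally
#'   `time`), one row per nucleus (or nucleus-timepoint).
#' @param fov_table data.frame with a `fov` column (and optionally `time`)
#'   carrying the ER metrics.
#' @return The joined data.frame (matched rows only), with attribute
#'   `excluded` holding the unmatched nucleus rows.
#' @export
join_fov_correlation <- function(nucleus_table, fov_table) {
  stopifnot("fov" %in% names(nucleus_table), "fov" %in% names(fov_table))
  by <- intersect(c("fov", "time"), intersect(names(nucleus_table), names(fov_table)))
  key <- do.call(paste, c(fov_table[by], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate FOV rows for the same ", paste(by, collapse = "+"), " key")
  }
  joined <- merge(nucleus_table, fov_table, by = by, all.x = TRUE, sort = FALSE)
  value_cols <- setdiff(names(fov_table), by)
  unmatched <- !stats::complete.cases(joined[, value_cols, drop = FALSE])
  out <- joined[!unmatched, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- joined[unmatched, names(nucleus_table), drop = FALSE]
  if (any(unmatched)) {
    message(sum(unmatched), " nucleus row(s) had no matching FOV and were excluded")
  }
  out
}

#' Osmotic shock from a dilution step
#'
#' Final osmolarity of an ideal mixture,
#' `(v_start * start_osm + v_diluent * diluent_osm) / (v_start + v_diluent)`,
#' and the resulting osmotic differential `delta_pi = start_osm - final`.
#' The default diluent is double-distilled water supplemented with 1.26 mM
#' CaCl2, whose ideal full-dissociation osmolarity is 3 x 1.26 = 3.78 mOsm.
#'
#' @param start_osm Starting medium osmolarity (mOsm, >= 0).
#' @param v_start Starting volume (uL, > 0).
#' @param v_diluent Diluent volume (uL, >= 0).
#' @param diluent_osm Diluent osmolarity (mOsm, >= 0).
#' @return The osmotic differential delta-pi in mOsm (unrounded).
#' @examples
#' dilution_osmolarity(341, 80, 320) # mild shock, ~270 mOsm
#' dilution_osmolarity(341, 40, 360) # maximal shock, ~303 mOsm
#' @export
dilution_osmolarity <- function(start_osm, v_start, v_diluent,
                                diluent_osm = 3.78) {
  if (any(c(start_osm, v_start, v_diluent, diluent_osm) < 0)) {
    stop("osmolarities and volumes must be non-negative")
  }
  if (v_start <= 0) stop("starting volume must be positive")
  final <- (v_start * start_osm + v_diluent * diluent_osm) /
    (v_start + v_diluent)
  start_osm - final
}
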