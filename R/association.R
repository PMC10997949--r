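# Correlation analyses linking HRT to water-quality endpoints, written from
# first principles: product-moment correlation, simple least squares, a
# two-sided permutation test on |r|, and grouped mean +/- SD summaries.
# Pairs where either value is missing (e.g. a stagnant tap's undefined HRT)
# are dropped listwise and the exclusion count is reported.

drop_incomplete <- function(x, y) {
  if (length(x) != length(y)) {
    stop_swss("shape", sprintf("vector lengths differ: %d vs %d", length(x), length(y)))
  }
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep], n_dropped = sum(!keep))
}

check_nondegenerate <- function(x, y) {
  if (length(x) < 3L) {
    stop_swss("degenerate_input", "need at least 3 complete pairs")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_swss("degenerate_input", "a variable is constant; correlation undefined")
  }
}

# Product-moment correlation of two complete numeric vectors (no checks).
.r_raw <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped
#'   and counted.
#' @return The correlation, with attributes `n_used` and `n_dropped`.
#' @export
pearson_r <- function(x, y) {
  d <- drop_incomplete(x, y)
  check_nondegenerate(d$x, d$y)
  structure(.r_raw(d$x, d$y), n_used = length(d$x), n_dropped = d$n_dropped)
}

#' Simple least-squares line fit
#'
#' Ordinary least squares of `y` on `x` via the normal equations. For this
#' simple regression the coefficient of determination equals the squared
#' Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `slope`, `intercept`, `r2`, `n`, `n_dropped`.
#' @export
linfit <- function(x, y) {
  d <- drop_incomplete(x, y)
  check_nondegenerate(d$x, d$y)
  xc <- d$x - mean(d$x)
  yc <- d$y - mean(d$y)
  sxx <- sum(xc^2)
  sxy <- sum(xc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(d$y) - slope * mean(d$x),
       r2 = sxy^2 / (sxx * syy), n = length(d$x), n_dropped = d$n_dropped)
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided test of no association: `y` is randomly permuted `B` times and
#' the p-value is `(1 + b) / (B + 1)` where `b` counts permutations whose
#' |r| reaches the observed |r|. The add-one estimator keeps p strictly
#' positive and valid; the smallest attainable p is `1/(B+1)`. Deterministic
#' per seed.
#'
#' @param x,y Numeric vectors of equal length.
#' @param B Number of permutations, at least 99.
#' @param seed Integer seed.
#' @return p-value in (0, 1], with attribute `r_obs`.
#' @export
permutation_p <- function(x, y, B = 999L, seed = 1L) {
  if (B < 99L) stop_swss("invalid_input", "use at least B = 99 permutations")
  d <- drop_incomplete(x, y)
  check_nondegenerate(d$x, d$y)
  xc <- d$x - mean(d$x)
  yc <- d$y - mean(d$y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  r_obs <- sum(xc * yc) / denom
  set.seed(seed)
  n <- length(xc)
  b <- 0L
  for (i in seq_len(B)) {
    r_perm <- sum(xc * yc[sample.int(n)]) / denom
    if (abs(r_perm) >= abs(r_obs)) b <- b + 1L
  }
  structure((1 + b) / (B + 1), r_obs = r_obs)
}

#' Full association analysis of one variable pair
#'
#' Combines [pearson_r()], [linfit()] and [permutation_p()] into one record,
#' the package's standard report of an HRT-endpoint (or endpoint-endpoint)
#' relation. Both r and R-squared are always reported.
#'
#' @param data Data frame holding the variables (e.g. generated tap
#'   observations).
#' @param x,y Column names.
#' @param B Permutations for the p-value.
#' @param seed Integer seed for the permutation stream.
#' @return A `swss_association` list: `x`, `y`, `n`, `n_dropped`,
#'   `pearson_r`, `r2`, `slope`, `intercept`, `p_perm`, `B`, `seed`.
#' @export
associate <- function(data, x, y, B = 999L, seed = 1L) {
  for (v in c(x, y)) {
    if (!v %in% names(data)) stop_swss("schema", sprintf("no column '%s'", v))
  }
  xv <- data[[x]]
  yv <- data[[y]]
  r <- pearson_r(xv, yv)
  fit <- linfit(xv, yv)
  p <- permutation_p(xv, yv, B = B, seed = seed)
  structure(list(x = x, y = y, n = fit$n, n_dropped = fit$n_dropped,
                 pearson_r = as.numeric(r), r2 = fit$r2,
                 slope = fit$slope, intercept = fit$intercept,
                 p_perm = as.numeric(p), B = as.integer(B),
                 seed = as.integer(seed)),
            class = "swss_association")
}

#' @export
print.swss_association <- function(x, ...) {
  cat(sprintf("%s ~ %s  (n = %d%s)\n", x$y, x$x, x$n,
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  cat(sprintf("  r = %.3f, R2 = %.3f, slope = %.4g, intercept = %.4g\n",
              x$pearson_r, x$r2, x$slope, x$intercept))
  cat(sprintf("  permutation p = %.4f (B = %d)\n", x$p_perm, x$B))
  invisible(x)
}

#' Grouped mean and standard deviation summary
#'
#' Per-group n, mean, and sample (n-1) standard deviation, the standard
#' "mean +/- SD" table layout of water-quality reporting. The SD of a
#' single-observation group is undefined and reported as `NA`.
#'
#' @param table Non-empty data frame.
#' @param group_field,value_field Column names.
#' @return Data frame with `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(table, group_field, value_field) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_swss("schema", "table must be a non-empty data frame")
  }
  for (v in c(group_field, value_field)) {
    if (!v %in% names(table)) stop_swss("schema", sprintf("no column '%s'", v))
  }
  parts <- split(table[[value_field]], table[[group_field]])
  out <- data.frame(group = names(parts),
                    n = vapply(parts, length, 0L),
                    mean = vapply(parts, mean, 0),
                    sd = vapply(parts, function(v) {
                      if (length(v) < 2L) NA_real_ else stats::sd(v)
                    }, 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Format a grouped summary as "mean ± sd" strings
#'
#' @param summary Output of [group_summary()].
#' @param digits Decimal places.
#' @return Character vector named by group; an undefined SD prints as "NA".
#' @export
format_group_summary <- function(summary, digits = 2) {
  txt <- sprintf("%.*f ± %s", digits, summary$mean,
                 ifelse(is.na(summary$sd), "NA",
                        sprintf("%.*f", digits, summary$sd)))
  stats::setNames(txt, summary$group)
}
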