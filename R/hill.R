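#' Hill dose-response parameters
#'
#' Container for the four parameters of the Hill equation describing a
#' genetic-sensor dose-response curve: basal output `g0` (MEF), saturating
#' output `ginf` (MEF), half-maximal ligand concentration `ec50` (umol/L)
#' and Hill coefficient `n`. A variant is *inverted* when `ginf < g0`
#' (output decreases with ligand).
#'
#' @param g0 Basal output at zero ligand, MEF (> 0).
#' @param ginf Saturating output at high ligand, MEF (> 0).
#' @param ec50 Half-maximal ligand concentration, umol/L (> 0).
#' @param n Hill coefficient (> 0), dimensionless steepness.
#' @return An object of class `hill_params`.
#' @examples
#' wt <- hill_params(g0 = 158, ginf = 25000, ec50 = 95, n = 1.6)
#' hill_response(wt, c(0, 95, 1e5))
#' @export
hill_params <- function(g0, ginf, ec50, n) {
  for (nm in c("g0", "ginf", "ec50", "n")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("hill_params: '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  structure(list(g0 = g0, ginf = ginf, ec50 = ec50, n = n),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "Hill parameters: G0 = %.3g MEF, Ginf = %.3g MEF, EC50 = %.3g umol/L, n = %.3g%s\n",
    x$g0, x$ginf, x$ec50, x$n,
    if (x$ginf < x$g0) " [inverted]" else ""))
  invisible(x)
}

#' Evaluate the Hill equation
#'
#' Computes `G(L) = G0 + (Ginf - G0) * L^n / (L^n + EC50^n)`. At `L = 0`
#' the analytic limit `G0` is returned (the power form is never evaluated
#' at zero ligand). At `L = EC50` the output is exactly `(G0 + Ginf)/2`.
#'
#' @param params A [hill_params()] object.
#' @param L Ligand concentration(s), umol/L, non-negative; vectorized.
#' @return Output level(s) in MEF, same length as `L`.
#' @export
hill_response <- function(params, L) {
  if (!inherits(params, "hill_params")) params <- do.call(hill_params, as.list(params))
  if (any(!is.finite(L)) || any(L < 0))
    stop("hill_response: ligand concentrations must be finite and >= 0",
         call. = FALSE)
  out <- rep(params$g0, length(L))
  pos <- L > 0
  if (any(pos)) {
    Ln <- L[pos]^params$n
    out[pos] <- params$g0 + (params$ginf - params$g0) * Ln / (Ln + params$ec50^params$n)
  }
  out
}

#' Geometric mean and geometric standard deviation
#'
#' The geometric SD is returned as a fold factor, `exp(sd(log(values)))`
#' with the sample (n-1) standard deviation; it equals 1 for identical
#' values and is the natural replicate-variability summary for
#' multiplicative cytometry quantities.
#'
#' @param values Positive numeric vector, length >= 1.
#' @return List with `gmean` and `gsd` (gsd is `NA` for a single value).
#' @examples
#' geometric_stats(c(5, 5, 5))
#' @export
geometric_stats <- function(values) {
  if (length(values) < 1L || any(!is.finite(values)) || any(values <= 0))
    stop("geometric_stats: values must be positive and finite", call. = FALSE)
  lv <- log(values)
  list(gmean = exp(mean(lv)),
       gsd = if (length(values) > 1L) exp(stats::sd(lv)) else NA_real_)
}

#' Flag outlier replicates by saturating output
#'
#' A replicate is dropped when its `ginf` estimate differs from the
#' consensus by more than 1.25-fold in either direction. The consensus is
#' the geometric median (median on the log scale) of the replicate values;
#' after each pass the consensus is recomputed from the kept replicates and
#' the rule re-applied until the kept set is stable, which makes the filter
#' robust to large outliers and idempotent. At least one replicate is
#' always kept.
#'
#' @param ginf Per-replicate saturating-output estimates (MEF, > 0).
#' @param labels Optional replicate labels (default: indices).
#' @param fold Outlier threshold as a fold ratio (default 1.25).
#' @return List with character vectors `kept` and `dropped`.
#' @export
filter_outlier_replicates <- function(ginf, labels = NULL, fold = 1.25) {
  if (length(ginf) < 1L) stop("filter_outlier_replicates: no replicates", call. = FALSE)
  if (any(!is.finite(ginf)) || any(ginf <= 0))
    stop("filter_outlier_replicates: ginf values must be positive", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(ginf))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(ginf))

  pass <- function(keep) {
    consensus <- exp(stats::median(log(ginf[keep])))
    ratio <- pmax(ginf / consensus, consensus / ginf)
    keep & (ratio <= fold)
  }
  keep <- rep(TRUE, length(ginf))
  for (i in seq_len(length(ginf))) {     # drop-and-recompute to fixed point
    nxt <- pass(keep)
    if (!any(nxt) || identical(nxt, keep)) break
    keep <- nxt
  }
  if (!any(keep)) {                      # never drop everything
    consensus <- exp(stats::median(log(ginf)))
    keep[which.min(abs(log(ginf) - log(consensus)))] <- TRUE
  }
  list(kept = labels[keep], dropped = labels[!keep])
}
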