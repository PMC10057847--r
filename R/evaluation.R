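#' Fold-accuracy of predicted against actual values
#'
#' `exp(RMSE(ln x))`: the exponential of the root-mean-square difference
#' between the natural logs of actual and predicted (or targeted)
#' values. Equals 1 for perfect agreement, is symmetric in its
#' arguments, and is invariant to a common rescaling of both vectors -
#' the natural accuracy metric for parameters spanning orders of
#' magnitude.
#'
#' @param predicted,actual Positive numeric vectors of equal length >= 1.
#' @return Fold-accuracy, >= 1.
#' @examples
#' fold_accuracy(c(1, 4), c(2, 2))  # 2.0
#' @export
fold_accuracy <- function(predicted, actual) {
  check_pos_pair(predicted, actual, "fold_accuracy")
  exp(sqrt(mean((log(actual) - log(predicted))^2)))
}

check_pos_pair <- function(predicted, actual, fn) {
  if (length(predicted) != length(actual) || length(actual) < 1L)
    stop(fn, ": need equal-length vectors of length >= 1", call. = FALSE)
  if (any(!is.finite(predicted)) || any(!is.finite(actual)) ||
      any(predicted <= 0) || any(actual <= 0))
    stop(fn, ": values must be positive and finite", call. = FALSE)
}

#' Fraction of pairs agreeing within k-fold
#'
#' @param predicted,actual Positive numeric vectors of equal length.
#' @param k Fold threshold (>= 1).
#' @return Fraction in `[0, 1]` of pairs with `max(a/p, p/a) <= k`.
#' @export
within_fold_fraction <- function(predicted, actual, k = 2) {
  check_pos_pair(predicted, actual, "within_fold_fraction")
  if (k < 1) stop("within_fold_fraction: k must be >= 1", call. = FALSE)
  mean(pmax(actual / predicted, predicted / actual) <= k)
}

accuracy_row <- function(predicted, actual) {
  resid <- log(actual) - log(predicted)
  slope <- if (length(actual) >= 2L && stats::sd(log(predicted)) > 0)
    unname(stats::coef(stats::lm.fit(cbind(1, log(predicted)),
                                     log(actual)))[2L])
  else NA_real_
  list(fold_accuracy = fold_accuracy(predicted, actual),
       within_2fold = within_fold_fraction(predicted, actual, 2),
       residuals = resid, bias_slope = slope)
}

#' Evaluate a selection against measurements
#'
#' Compares measured Hill parameters of the selected variants either
#' with the specification targets (`mode = "selection"`: how close did
#' the engineered sensors land to the spec?) or with the landscape's own
#' point estimates (`mode = "validation"`: how accurate was the
#' landscape, after any EC50 correction carried by the selection?).
#' Point values are posterior medians when measurements are posteriors.
#'
#' @param result A [select_variants()] result.
#' @param measured Measurements for every selected variant: a named list
#'   of [hill_posterior()]s keyed by variant id, or a data frame with
#'   columns `variant`, `g0`, `ginf`, `ec50` (natural scales).
#' @param mode `"selection"` or `"validation"`.
#' @return Object of class `accuracy_report`: per-parameter
#'   fold-accuracy, within-2-fold fraction, log-ratio residuals, and the
#'   ln-ln regression slope of measured on predicted (systematic bias).
#'   Parameters without a reference value in the requested mode are
#'   omitted.
#' @export
evaluate_selection <- function(result, measured,
                               mode = c("selection", "validation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "selection_result"))
  tab <- result$table
  if (!nrow(tab)) stop("evaluate_selection: empty selection", call. = FALSE)
  if (is.data.frame(measured)) {
    miss <- setdiff(tab$variant, measured$variant)
    if (length(miss))
      stop("evaluate_selection: missing measurement(s) for: ",
           paste(miss, collapse = ", "), call. = FALSE)
    m <- measured[match(tab$variant, measured$variant), , drop = FALSE]
    meas <- data.frame(g0 = m$g0, ginf = m$ginf, ec50 = m$ec50)
  } else {
    miss <- setdiff(tab$variant, names(measured))
    if (length(miss))
      stop("evaluate_selection: missing measurement(s) for: ",
           paste(miss, collapse = ", "), call. = FALSE)
    meas <- do.call(rbind, lapply(tab$variant, function(v) {
      p <- posterior_point(measured[[v]])
      data.frame(g0 = p[["g0"]], ginf = p[["ginf"]], ec50 = p[["ec50"]])
    }))
  }
  spec <- result$spec
  ref <- switch(mode,
    selection = list(
      ec50 = if (!is.null(spec$ec50_target))
        rep(spec$ec50_target, nrow(tab)),
      ginf = if (!is.null(spec$ginf_target))
        rep(spec$ginf_target, nrow(tab)),
      g0 = NULL),
    validation = {
      ec50_ref <- if (is.null(result$correction)) tab$ec50 else
        predict(result$correction, tab$ec50)
      list(ec50 = ec50_ref, ginf = tab$ginf, g0 = tab$g0)
    })
  rows <- list()
  for (par in c("ec50", "ginf", "g0"))
    if (!is.null(ref[[par]]))
      rows[[par]] <- accuracy_row(ref[[par]], meas[[par]])
  structure(list(parameters = rows, mode = mode, n = nrow(tab),
                 variants = tab$variant), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy report (%s mode, n = %d):\n", x$mode, x$n))
  for (par in names(x$parameters)) {
    r <- x$parameters[[par]]
    cat(sprintf("  %-5s fold-accuracy %.3f, within 2-fold %.0f%%, bias slope %s\n",
                par, r$fold_accuracy, 100 * r$within_2fold,
                if (is.finite(r$bias_slope)) sprintf("%.3f", r$bias_slope) else "NA"))
  }
  invisible(x)
}
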