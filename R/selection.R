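#' Quantitative dose-response specification
#'
#' Multi-objective target bands for the Hill parameters of an engineered
#' sensor. At least one criterion must be present. Fold bands are
#' two-sided: a value `v` meets a target `t` with fold band `f` when
#' `t/f <= v <= t*f`.
#'
#' @param ec50_target Target EC50, umol/L (optional).
#' @param ec50_fold Fold band around `ec50_target` (>= 1).
#' @param ginf_target Target saturating output, MEF (optional).
#' @param ginf_fold Fold band around `ginf_target` (>= 1).
#' @param ginf_upper Upper bound on Ginf, MEF (optional).
#' @param g0_lower,g0_upper Bounds on basal output G0, MEF (optional;
#'   either may be given alone).
#' @param phenotype `"any"`, `"normal"` (Ginf > G0) or `"inverted"`
#'   (Ginf < G0).
#' @return Object of class `specification`.
#' @export
specification <- function(ec50_target = NULL, ec50_fold = 1.2,
                          ginf_target = NULL, ginf_fold = 1.1,
                          ginf_upper = NULL, g0_lower = NULL, g0_upper = NULL,
                          phenotype = c("any", "normal", "inverted")) {
  phenotype <- match.arg(phenotype)
  chk <- function(v, nm, lo = 0) {
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= lo))
      stop("specification: invalid ", nm, call. = FALSE)
  }
  chk(ec50_target, "ec50_target"); chk(ginf_target, "ginf_target")
  chk(ginf_upper, "ginf_upper"); chk(g0_lower, "g0_lower"); chk(g0_upper, "g0_upper")
  if (ec50_fold < 1 || ginf_fold < 1)
    stop("specification: fold bands must be >= 1", call. = FALSE)
  if (!is.null(g0_lower) && !is.null(g0_upper) && g0_lower >= g0_upper)
    stop("specification: g0_lower must be < g0_upper", call. = FALSE)
  any_crit <- !is.null(ec50_target) || !is.null(ginf_target) ||
    !is.null(ginf_upper) || !is.null(g0_lower) || !is.null(g0_upper) ||
    phenotype != "any"
  if (!any_crit) stop("specification: at least one criterion required", call. = FALSE)
  structure(list(ec50_target = ec50_target, ec50_fold = ec50_fold,
                 ginf_target = ginf_target, ginf_fold = ginf_fold,
                 ginf_upper = ginf_upper, g0_lower = g0_lower,
                 g0_upper = g0_upper, phenotype = phenotype),
            class = "specification")
}

#' @export
print.specification <- function(x, ...) {
  cat("Dose-response specification:\n")
  if (!is.null(x$ec50_target))
    cat(sprintf("  EC50 within %.3g-fold of %.4g umol/L (%.4g - %.4g)\n",
                x$ec50_fold, x$ec50_target,
                x$ec50_target / x$ec50_fold, x$ec50_target * x$ec50_fold))
  if (!is.null(x$ginf_target))
    cat(sprintf("  Ginf within %.3g-fold of %.4g MEF (%.4g - %.4g)\n",
                x$ginf_fold, x$ginf_target,
                x$ginf_target / x$ginf_fold, x$ginf_target * x$ginf_fold))
  if (!is.null(x$ginf_upper)) cat(sprintf("  Ginf < %.4g MEF\n", x$ginf_upper))
  if (!is.null(x$g0_lower) || !is.null(x$g0_upper))
    cat(sprintf("  G0 in (%.4g, %.4g) MEF\n",
                if (is.null(x$g0_lower)) 0 else x$g0_lower,
                if (is.null(x$g0_upper)) Inf else x$g0_upper))
  if (x$phenotype != "any") cat("  phenotype:", x$phenotype, "\n")
  invisible(x)
}

#' Preset selection specifications
#'
#' The two standard specification families for engineering LacI-like
#' sensors from a large-scale landscape:
#' * `"multiobjective"`: EC50 within 1.2-fold of the target, Ginf within
#'   1.1-fold of the target, and G0 < 2 kMEF.
#' * `"inverted"`: inverted phenotype with EC50 within 1.5-fold of the
#'   target, Ginf < 12.5 kMEF, and 19.2 kMEF < G0 < 32.5 kMEF.
#'
#' @param name Preset name.
#' @param target_ec50 Target EC50, umol/L (required by both presets).
#' @param target_ginf Target Ginf, MEF (required by `"multiobjective"`).
#' @return A [specification()].
#' @examples
#' preset_specs("multiobjective", target_ec50 = 30, target_ginf = 16000)
#' preset_specs("inverted", target_ec50 = 100)
#' @export
preset_specs <- function(name, target_ec50 = NULL, target_ginf = NULL) {
  presets <- c("multiobjective", "inverted")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop("preset_specs: unknown preset; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  if (is.null(target_ec50))
    stop("preset_specs: target_ec50 is required", call. = FALSE)
  if (name == "multiobjective") {
    if (is.null(target_ginf))
      stop("preset_specs: target_ginf is required for 'multiobjective'",
           call. = FALSE)
    specification(ec50_target = target_ec50, ec50_fold = 1.2,
                  ginf_target = target_ginf, ginf_fold = 1.1,
                  g0_upper = 2000)
  } else {
    specification(ec50_target = target_ec50, ec50_fold = 1.5,
                  ginf_upper = 12500, g0_lower = 19200, g0_upper = 32500,
                  phenotype = "inverted")
  }
}

# Vectorized: do parameter values satisfy every active criterion?
spec_satisfied <- function(spec, g0, ginf, ec50, n = NULL) {
  ok <- rep(TRUE, length(g0))
  if (!is.null(spec$ec50_target))
    ok <- ok & ec50 >= spec$ec50_target / spec$ec50_fold &
      ec50 <= spec$ec50_target * spec$ec50_fold
  if (!is.null(spec$ginf_target))
    ok <- ok & ginf >= spec$ginf_target / spec$ginf_fold &
      ginf <= spec$ginf_target * spec$ginf_fold
  if (!is.null(spec$ginf_upper)) ok <- ok & ginf < spec$ginf_upper
  if (!is.null(spec$g0_lower)) ok <- ok & g0 > spec$g0_lower
  if (!is.null(spec$g0_upper)) ok <- ok & g0 < spec$g0_upper
  if (spec$phenotype == "inverted") ok <- ok & ginf < g0
  if (spec$phenotype == "normal") ok <- ok & ginf > g0
  ok
}

#' Systematic-error correction for landscape EC50 values
#'
#' Large-scale landscape EC50 estimates show a compressive systematic
#' error relative to direct cytometry measurement: at low EC50 the
#' cytometry value tends to be higher, at high EC50 lower. The correction
#' is an ordinary least-squares fit of `ln(measured)` on `ln(dataset)`;
#' a corrected prediction for a dataset value `e` is
#' `exp(intercept + slope * ln(e))`.
#'
#' @param dataset_ec50 EC50 values from the landscape, umol/L (> 0).
#' @param measured_ec50 Matched direct-measurement EC50 values (> 0).
#' @return Object of class `ec50_correction` with `slope`, `intercept`
#'   (natural-log scale) and the number of points.
#' @export
fit_ec50_correction <- function(dataset_ec50, measured_ec50) {
  if (length(dataset_ec50) != length(measured_ec50) || length(dataset_ec50) < 2L)
    stop("fit_ec50_correction: need matched vectors of length >= 2", call. = FALSE)
  if (any(dataset_ec50 <= 0) || any(measured_ec50 <= 0) ||
      any(!is.finite(dataset_ec50)) || any(!is.finite(measured_ec50)))
    stop("fit_ec50_correction: EC50 values must be positive and finite",
         call. = FALSE)
  x <- log(dataset_ec50); y <- log(measured_ec50)
  if (stats::sd(x) == 0)
    stop("fit_ec50_correction: degenerate fit (all dataset values equal)",
         call. = FALSE)
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  structure(list(intercept = unname(co[1L]), slope = unname(co[2L]),
                 n = length(x)), class = "ec50_correction")
}

#' @export
print.ec50_correction <- function(x, ...) {
  cat(sprintf("EC50 correction (ln-ln OLS, n = %d): slope %.4f, intercept %.4f\n",
              x$n, x$slope, x$intercept))
  invisible(x)
}

#' @param object An `ec50_correction`.
#' @param ec50 Landscape EC50 value(s) to correct, umol/L.
#' @param ... Unused.
#' @return `predict`: corrected EC50 value(s), umol/L.
#' @rdname fit_ec50_correction
#' @export
predict.ec50_correction <- function(object, ec50, ...) {
  stopifnot(all(ec50 > 0))
  exp(object$intercept + object$slope * log(ec50))
}

#' Posterior probability that a variant meets a specification
#'
#' The fraction of posterior draws that jointly satisfy every active
#' criterion of the specification. When a correction model is supplied it
#' is applied to each draw's EC50 (not only the point estimate), so band
#' membership and probability stay coherent.
#'
#' @param posterior A [hill_posterior()].
#' @param spec A [specification()].
#' @param correction Optional [fit_ec50_correction()] model.
#' @return Probability in `[0, 1]`.
#' @export
success_probability <- function(posterior, spec, correction = NULL) {
  stopifnot(inherits(posterior, "hill_posterior"), inherits(spec, "specification"))
  s <- posterior$samples
  ec50 <- 10^s[, "log_ec50"]
  if (!is.null(correction)) ec50 <- predict(correction, ec50)
  mean(spec_satisfied(spec, 10^s[, "log_g0"], 10^s[, "log_ginf"], ec50,
                      s[, "n"]))
}

#' Select landscape variants against a specification
#'
#' The in silico selection method: candidate variants are pre-filtered on
#' posterior medians meeting every criterion (with corrected EC50 when a
#' correction is supplied), then ranked by their posterior probability of
#' jointly satisfying the specification; up to `top_k` variants with
#' probability at least `min_prob` are returned. Ties in probability are
#' broken in favour of fewer mutations, then lexicographic genotype.
#'
#' @param x A [landscape()].
#' @param spec A [specification()].
#' @param top_k Maximum number of variants returned (>= 1).
#' @param min_prob Minimum success probability (default 0).
#' @param correction Optional [fit_ec50_correction()] model applied to
#'   EC50 draws and medians.
#' @return Object of class `selection_result`: a data frame `table`
#'   (`variant`, `mutation_codes`, `n_mut`, `probability`, posterior
#'   medians), the matching `records`, and the `spec`/`correction` used.
#' @examples
#' \donttest{
#' ls <- simulate_landscape(simulate_library(2000, seed = 7), seed = 7)
#' sel <- select_variants(ls, preset_specs("multiobjective", 30, 16000))
#' sel
#' }
#' @export
select_variants <- function(x, spec, top_k = 3L, min_prob = 0,
                            correction = NULL) {
  stopifnot(inherits(x, "landscape"), inherits(spec, "specification"),
            top_k >= 1, min_prob >= 0, min_prob <= 1)
  empty <- function() {
    structure(list(table = data.frame(variant = character(),
                                      mutation_codes = character(),
                                      n_mut = integer(), probability = numeric(),
                                      g0 = numeric(), ginf = numeric(),
                                      ec50 = numeric(), n = numeric()),
                   records = list(), spec = spec, correction = correction),
              class = "selection_result")
  }
  if (!length(x$records)) {
    warning("select_variants: empty landscape", call. = FALSE)
    return(empty())
  }
  s <- x$summary
  med_ec50 <- if (is.null(correction)) s$ec50 else predict(correction, s$ec50)
  cand <- which(spec_satisfied(spec, s$g0, s$ginf, med_ec50, s$n))
  if (!length(cand)) return(empty())
  prob <- vapply(cand, function(i)
    success_probability(x$records[[i]]$posterior, spec, correction), 0)
  keep <- prob >= min_prob
  cand <- cand[keep]; prob <- prob[keep]
  if (!length(cand)) return(empty())
  ord <- order(-prob, s$n_mut[cand], s$mutation_codes[cand])
  ord <- ord[seq_len(min(top_k, length(ord)))]
  cand <- cand[ord]; prob <- prob[ord]
  structure(list(
    table = data.frame(variant = s$variant[cand],
                       mutation_codes = s$mutation_codes[cand],
                       n_mut = s$n_mut[cand], probability = prob,
                       g0 = s$g0[cand], ginf = s$ginf[cand],
                       ec50 = s$ec50[cand], n = s$n[cand],
                       row.names = NULL),
    records = x$records[cand], spec = spec, correction = correction),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("In silico selection: %d variant(s)\n", nrow(x$table)))
  if (nrow(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' Read / write specification YAML files
#'
#' @param path YAML file path.
#' @return `read_specification`: a [specification()].
#' @export
read_specification <- function(path) {
  if (!file.exists(path))
    stop("read_specification: file not found: ", path, call. = FALSE)
  do.call(specification, yaml::read_yaml(path))
}

#' @rdname read_specification
#' @param spec A [specification()].
#' @export
write_specification <- function(spec, path) {
  stopifnot(inherits(spec, "specification"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(spec)), path)
  invisible(path)
}
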