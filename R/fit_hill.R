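#' Posterior over Hill parameters
#'
#' Wraps a matrix of posterior draws over the Hill parameters on the
#' scales used throughout the package and in landscape files: base-10
#' logarithms for `g0`, `ginf` and `ec50`, linear for `n`. The stored
#' summary (posterior mean and SD per parameter) is always recomputed
#' from the draws, so the two can never disagree.
#'
#' @param samples Numeric matrix with S >= 1 rows and columns
#'   `log_g0`, `log_ginf`, `log_ec50`, `n`.
#' @return An object of class `hill_posterior` with elements `samples`,
#'   `mean` and `sd` (named numeric vectors on the storage scales).
#' @export
hill_posterior <- function(samples) {
  cols <- c("log_g0", "log_ginf", "log_ec50", "n")
  samples <- as.matrix(samples)
  if (is.null(colnames(samples)) && ncol(samples) == 4L) colnames(samples) <- cols
  if (!all(cols %in% colnames(samples)))
    stop("hill_posterior: samples must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  samples <- samples[, cols, drop = FALSE]
  rownames(samples) <- NULL
  if (nrow(samples) < 1L || any(!is.finite(samples)))
    stop("hill_posterior: need >= 1 finite draw", call. = FALSE)
  if (any(samples[, "n"] <= 0))
    stop("hill_posterior: Hill coefficient draws must be positive", call. = FALSE)
  structure(list(
    samples = samples,
    mean = colMeans(samples),
    sd = apply(samples, 2L, stats::sd)
  ), class = "hill_posterior")
}

#' Posterior point estimates on natural scales
#'
#' @param posterior A `hill_posterior`.
#' @param stat `"median"` (default) or `"mean"`, applied on the storage
#'   (log) scales before exponentiating.
#' @return Named vector `g0`, `ginf`, `ec50` (natural units) and `n`.
#' @export
posterior_point <- function(posterior, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") function(x) apply(x, 2L, stats::median) else colMeans
  s <- f(posterior$samples)
  c(g0 = 10^s[["log_g0"]], ginf = 10^s[["log_ginf"]],
    ec50 = 10^s[["log_ec50"]], n = s[["n"]])
}

#' @export
print.hill_posterior <- function(x, ...) {
  p <- posterior_point(x)
  cat(sprintf(
    "Hill posterior (%d draws): G0 %.3g, Ginf %.3g MEF, EC50 %.3g umol/L, n %.2f%s\n",
    nrow(x$samples), p[["g0"]], p[["ginf"]], p[["ec50"]], p[["n"]],
    if (p[["ginf"]] < p[["g0"]]) " [inverted]" else ""))
  invisible(x)
}

#' Prior configuration for Hill fitting
#'
#' Weakly informative defaults spanning every phenotype class seen in
#' large-scale LacI landscapes: log-normal priors on `g0` and `ginf`
#' centred on the observed data range, a log-uniform prior on `ec50` over
#' 0.1 to 1e4 umol/L, and a truncated normal on `n` with support (0, 6].
#'
#' @param log_gsd Prior SD (decades) for log10 `g0` and `ginf`.
#' @param ec50_range Support of the log-uniform EC50 prior, umol/L.
#' @param n_mean,n_sd,n_max Location, scale and upper bound of the
#'   truncated-normal prior on the Hill coefficient.
#' @param noise_floor Minimum per-point lognormal noise scale (relative).
#' @return A list of class `hill_priors`.
#' @export
hill_priors <- function(log_gsd = 1.5, ec50_range = c(0.1, 1e4),
                        n_mean = 1.5, n_sd = 1, n_max = 6,
                        noise_floor = 0.02) {
  stopifnot(log_gsd > 0, length(ec50_range) == 2L, all(ec50_range > 0),
            ec50_range[1] < ec50_range[2], n_sd > 0, n_max > 0, noise_floor > 0)
  structure(list(log_gsd = log_gsd, ec50_range = ec50_range,
                 n_mean = n_mean, n_sd = n_sd, n_max = n_max,
                 noise_floor = noise_floor), class = "hill_priors")
}

hill_jags_model <- "
model {
  for (i in 1:N) {
    mu[i] <- log(g0 + (ginf - g0) * pow(L[i], n) / (pow(L[i], n) + pow(ec50, n)))
    logy[i] ~ dnorm(mu[i], 1 / (s[i] * s[i]))
  }
  log_g0 ~ dnorm(c_low, 1 / (log_gsd * log_gsd))
  log_ginf ~ dnorm(c_high, 1 / (log_gsd * log_gsd))
  log_ec50 ~ dunif(ec_lo, ec_hi)
  n ~ dnorm(n_mean, 1 / (n_sd * n_sd)) T(0.001, n_max)
  g0 <- pow(10, log_g0)
  ginf <- pow(10, log_ginf)
  ec50 <- pow(10, log_ec50)
}"

#' Bayesian Hill-equation fit of dose-response data
#'
#' Fits the Hill equation to pooled (non-outlier) replicate dose-response
#' measurements by MCMC, with a lognormal observation model: the log of
#' each geometric-mean fluorescence is normal around the log of the Hill
#' curve with per-point scale `max(geo_mean_err/geo_mean, noise_floor)`.
#' Four chains are run; convergence is flagged when any parameter's
#' potential scale reduction factor exceeds 1.05 (the fit is still
#' returned, with `converged = FALSE` and a warning).
#'
#' @param data Data frame with columns `ligand` (umol/L, >= 0),
#'   `geo_mean` (MEF, > 0) and optionally `geo_mean_err` (MEF, >= 0;
#'   defaults to 0, so the noise floor applies). Replicates are pooled:
#'   pass all non-outlier points together.
#' @param priors A [hill_priors()] configuration.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param n_iter Post-warmup draws per chain (4 chains).
#' @param n_adapt,n_burn Adaptation and burn-in iterations.
#' @return An object of classes `hill_fit` and `hill_posterior`:
#'   posterior draws and summary (see [hill_posterior()]) plus the data,
#'   convergence diagnostics (`psrf`, `converged`) and the seed.
#' @examples
#' \donttest{
#' grid <- ligand_grid()
#' truth <- hill_params(200, 20000, 100, 1.5)
#' set.seed(1)
#' y <- hill_response(truth, grid) * exp(rnorm(length(grid), 0, 0.05))
#' fit <- fit_hill(data.frame(ligand = grid, geo_mean = y,
#'                            geo_mean_err = 0.05 * y), seed = 1)
#' coef(fit)
#' }
#' @export
fit_hill <- function(data, priors = hill_priors(), seed = 1L,
                     n_iter = 1000L, n_adapt = 500L, n_burn = 500L) {
  req <- c("ligand", "geo_mean")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stop("fit_hill: data must have columns 'ligand' and 'geo_mean'", call. = FALSE)
  if (is.null(data$geo_mean_err)) data$geo_mean_err <- 0
  if (any(!is.finite(data$ligand)) || any(data$ligand < 0))
    stop("fit_hill: ligand concentrations must be >= 0", call. = FALSE)
  if (any(!is.finite(data$geo_mean)) || any(data$geo_mean <= 0))
    stop("fit_hill: geo_mean values must be positive", call. = FALSE)
  if (length(unique(data$ligand)) < 2L)
    stop("fit_hill: need >= 2 distinct ligand levels to identify the model",
         call. = FALSE)
  stopifnot(inherits(priors, "hill_priors"))
  seed <- as.integer(seed)

  s <- pmax(data$geo_mean_err / data$geo_mean, priors$noise_floor)
  jdata <- list(
    N = nrow(data), L = data$ligand, logy = log(data$geo_mean), s = s,
    c_low = log10(min(data$geo_mean)), c_high = log10(max(data$geo_mean)),
    log_gsd = priors$log_gsd,
    ec_lo = log10(priors$ec50_range[1]), ec_hi = log10(priors$ec50_range[2]),
    n_mean = priors$n_mean, n_sd = priors$n_sd, n_max = priors$n_max)
  inits <- lapply(1:4, function(i)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed + i))
  jm <- rjags::jags.model(textConnection(hill_jags_model), data = jdata,
                          inits = inits, n.chains = 4L, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("log_g0", "log_ginf", "log_ec50", "n"),
                              n.iter = n_iter, progress.bar = "none")
  psrf <- tryCatch(coda::gelman.diag(samp, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1L],
                   error = function(e) rep(NA_real_, 4L))
  converged <- all(is.finite(psrf)) && max(psrf) <= 1.05
  if (!converged)
    warning("fit_hill: convergence diagnostic failed (max PSRF = ",
            signif(max(psrf), 4), ")", call. = FALSE)

  m <- as.matrix(samp)[, c("log_g0", "log_ginf", "log_ec50", "n"), drop = FALSE]
  out <- hill_posterior(m)
  out$data <- data
  out$psrf <- psrf
  out$converged <- converged
  out$seed <- seed
  out$priors <- priors
  class(out) <- c("hill_fit", class(out))
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  NextMethod()
  if (!x$converged) cat("  WARNING: convergence diagnostic failed\n")
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- data.frame(
    parameter = c("log_g0", "log_ginf", "log_ec50", "n"),
    mean = unname(object$mean),
    sd = unname(object$sd),
    median = apply(object$samples, 2L, stats::median),
    q2.5 = apply(object$samples, 2L, stats::quantile, 0.025),
    q97.5 = apply(object$samples, 2L, stats::quantile, 0.975),
    psrf = unname(object$psrf[c("log_g0", "log_ginf", "log_ec50", "n")]),
    row.names = NULL)
  structure(list(table = tab, converged = object$converged,
                 n_draws = nrow(object$samples)), class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Bayesian Hill fit,", x$n_draws, "posterior draws",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) posterior_point(object, stat = "mean")

#' Posterior predictive dose-response curve
#'
#' @param object A `hill_fit`.
#' @param L Ligand concentrations, umol/L (default: the fitted data's).
#' @param level Credible level for the interval columns.
#' @param ... Unused.
#' @return Data frame with `ligand`, posterior-mean `fit`, and `lwr`/`upr`
#'   pointwise credible bounds (MEF).
#' @export
predict.hill_fit <- function(object, L = NULL, level = 0.95, ...) {
  if (is.null(L)) L <- sort(unique(object$data$ligand))
  draws <- predictive_curves(object, L)
  a <- (1 - level) / 2
  data.frame(ligand = L,
             fit = colMeans(draws),
             lwr = apply(draws, 2L, stats::quantile, a),
             upr = apply(draws, 2L, stats::quantile, 1 - a))
}

# draws x length(L) matrix of Hill curves from posterior samples
predictive_curves <- function(posterior, L) {
  s <- posterior$samples
  t(vapply(seq_len(nrow(s)), function(i) {
    hill_response(hill_params(10^s[i, "log_g0"], 10^s[i, "log_ginf"],
                              10^s[i, "log_ec50"], s[i, "n"]), L)
  }, numeric(length(L))))
}

#' @export
residuals.hill_fit <- function(object, ...) {
  p <- posterior_point(object, "mean")
  fit <- hill_response(hill_params(p[["g0"]], p[["ginf"]], p[["ec50"]], p[["n"]]),
                       object$data$ligand)
  log(object$data$geo_mean) - log(fit)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  Lplot <- d$ligand
  off <- min(Lplot[Lplot > 0]) / 4   # plotting position for L = 0 on log axis
  grid <- sort(unique(c(0, exp(seq(log(off), log(max(Lplot)), length.out = 60)))))
  pr <- predict(x, grid)
  px <- ifelse(pr$ligand == 0, off, pr$ligand)
  graphics::plot(ifelse(Lplot == 0, off, Lplot), d$geo_mean, log = "xy",
                 xlab = "ligand (umol/L; leftmost point is 0)",
                 ylab = "output (MEF)", ...)
  graphics::lines(px, pr$fit)
  graphics::lines(px, pr$lwr, lty = 2)
  graphics::lines(px, pr$upr, lty = 2)
  invisible(x)
}
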