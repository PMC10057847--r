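#' Hill parameter-recovery benchmark
#'
#' Simulates dose-response curves on the standard 12-point ligand grid
#' with 5 percent lognormal noise from randomly drawn non-inverted Hill
#' parameter sets, fits each with [fit_hill()], and reports how often the
#' central 95 percent posterior interval covers the generating value,
#' pooled over all four parameters.
#'
#' @param n_curves Number of simulated curves.
#' @param seed Integer seed.
#' @param cv Relative lognormal noise per point.
#' @return List: `coverage` (fraction of parameter intervals covering
#'   truth), `n_intervals`, and the per-curve detail data frame.
#' @export
benchmark_hill_recovery <- function(n_curves = 50L, seed = 1L, cv = 0.05) {
  set.seed(as.integer(seed))
  grid <- ligand_grid()
  truths <- lapply(seq_len(n_curves), function(i)
    hill_params(g0 = 10^stats::runif(1, 2, 3),
                ginf = 10^stats::runif(1, 3.8, 4.6),
                ec50 = 10^stats::runif(1, 0.7, 2.7),
                n = stats::runif(1, 1, 2.5)))
  noise <- matrix(stats::rnorm(n_curves * length(grid), 0, cv),
                  n_curves, length(grid))
  rows <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    tr <- truths[[i]]
    y <- hill_response(tr, grid) * exp(noise[i, ])
    fit <- suppressWarnings(
      fit_hill(data.frame(ligand = grid, geo_mean = y, geo_mean_err = cv * y),
               seed = seed + i))
    truth_log <- c(log10(tr$g0), log10(tr$ginf), log10(tr$ec50), tr$n)
    lo <- apply(fit$samples, 2L, stats::quantile, 0.025)
    hi <- apply(fit$samples, 2L, stats::quantile, 0.975)
    rows[[i]] <- data.frame(curve = i,
                            parameter = colnames(fit$samples),
                            truth = truth_log,
                            covered = lo <= truth_log & truth_log <= hi,
                            converged = fit$converged, row.names = NULL)
  }
  detail <- do.call(rbind, rows)
  list(coverage = mean(detail$covered), n_intervals = nrow(detail),
       detail = detail)
}

#' In silico selection benchmark on synthetic landscapes
#'
#' Two-part benchmark of the selection method under the standard
#' synthetic-landscape conditions (10^4-variant libraries, mean 4.4
#' missense mutations, FACS prescreen on).
#'
#' Part one (ranking): for each seed, a landscape is generated and three
#' variants whose true parameters sit exactly on a multi-objective
#' target (EC50 30 umol/L, Ginf 16 kMEF, low G0) are planted with
#' ordinary posterior widths; the preset multi-objective selection
#' (1.2-fold / 1.1-fold / G0 < 2 kMEF, top 3) is run and the rank-1 hit
#' is checked against the planted set.
#'
#' Part two (accuracy): on the first three seeds' unplanted landscapes,
#' the selection is run for the standard grid of specifications (EC50
#' 10, 30, 100 umol/L crossed with Ginf 16, 25 kMEF, omitting the
#' wild-type-like 100/25k cell); each selected variant's "measured"
#' dose-response is simulated from the generator truth with replicate-
#' level lognormal noise (geometric SD 1.16-fold for EC50, 1.11-fold for
#' Ginf), and the fold-accuracy against the targeted values is computed.
#'
#' @param seeds Integer vector of seeds (one landscape per seed).
#' @param n_variants Library size per landscape.
#' @param top_k Variants selected per specification.
#' @return List: `top1_planted_rate`, per-seed `top1_planted`,
#'   `ec50_fold_accuracy`, `ginf_fold_accuracy`, `n_selected`.
#' @export
benchmark_selection <- function(seeds = 1:20, n_variants = 10000L,
                                top_k = 3L) {
  vocab <- make_vocabulary()
  em <- effect_model(vocab)
  nm <- noise_model()
  spec_rank <- preset_specs("multiobjective", target_ec50 = 30,
                            target_ginf = 16000)
  top1 <- logical(length(seeds))
  acc_ls <- list()
  for (j in seq_along(seeds)) {
    seed <- as.integer(seeds[j])
    gt <- simulate_library(n_variants, vocabulary = vocab, seed = seed)
    ls <- simulate_landscape(gt, em, nm, seed = seed)
    if (j <= 3L) acc_ls[[j]] <- ls
    set.seed(seed + 500000L)
    planted <- lapply(1:3, function(i)
      variant_record(genotype(sample(vocab, 4)),
                     simulate_posterior(list(g0 = 300, ginf = 16000,
                                             ec50 = 30, n = 1.5), nm, 1, 50),
                     id = paste0("planted", i)))
    sel <- select_variants(landscape(c(ls$records, planted)), spec_rank,
                           top_k = top_k)
    top1[j] <- nrow(sel$table) > 0 && grepl("^planted", sel$table$variant[1])
  }
  targets <- expand.grid(ec50 = c(10, 30, 100), ginf = c(16000, 25000))
  targets <- targets[!(targets$ec50 == 100 & targets$ginf == 25000), ]
  set.seed(as.integer(seeds[1]) + 700000L)
  meas_ec50 <- tgt_ec50 <- meas_ginf <- tgt_ginf <- numeric(0)
  for (ls in acc_ls) {
    truth <- attr(ls, "truth")
    for (i in seq_len(nrow(targets))) {
      spec <- preset_specs("multiobjective", target_ec50 = targets$ec50[i],
                           target_ginf = targets$ginf[i])
      sel <- select_variants(ls, spec, top_k = top_k)
      if (!nrow(sel$table)) next
      tr <- truth[match(sel$table$variant, truth$variant), ]
      k <- nrow(tr)
      meas_ec50 <- c(meas_ec50, tr$ec50 * exp(stats::rnorm(k, 0, log(1.16))))
      tgt_ec50 <- c(tgt_ec50, rep(targets$ec50[i], k))
      meas_ginf <- c(meas_ginf, tr$ginf * exp(stats::rnorm(k, 0, log(1.11))))
      tgt_ginf <- c(tgt_ginf, rep(targets$ginf[i], k))
    }
  }
  list(top1_planted_rate = mean(top1), top1_planted = top1,
       ec50_fold_accuracy = if (length(tgt_ec50))
         fold_accuracy(tgt_ec50, meas_ec50) else NA_real_,
       ginf_fold_accuracy = if (length(tgt_ginf))
         fold_accuracy(tgt_ginf, meas_ginf) else NA_real_,
       n_selected = length(meas_ec50))
}

#' Latent-model forward-prediction benchmark
#'
#' Trains the latent model (K dimensions) on a synthetic landscape and
#' predicts held-out variants generated from the same effect model with
#' fresh genotypes (prescreen off, wild type excluded). Held-out
#' variants whose generator truth is inverted are excluded, mirroring
#' the training exclusion. Reports fold-accuracy of the predicted
#' posterior-mean EC50 and Ginf against the generator truth and the
#' empirical coverage of the mean +- 2 SD interval from 50 Monte Carlo
#' predictive draws.
#'
#' @param n_train Training library size.
#' @param n_test Held-out library size.
#' @param K Latent dimensionality.
#' @param seed Integer seed.
#' @param n_draws Predictive draws per variant.
#' @return List: `ec50_fold_accuracy`, `ginf_fold_accuracy`,
#'   `within2_ec50`, `within2_ginf` (fractions of held-out variants
#'   predicted within 2-fold), `coverage_ec50`, `coverage_ginf`,
#'   `n_test`.
#' @export
benchmark_latent <- function(n_train = 10000L, n_test = 1500L, K = 3L,
                             seed = 1L, n_draws = 50L) {
  vocab <- make_vocabulary()
  em <- effect_model(vocab)
  seed <- as.integer(seed)
  gt <- simulate_library(n_train, vocabulary = vocab, seed = seed)
  ls <- simulate_landscape(gt, em, seed = seed)
  model <- fit_latent_landscape(ls, K = K, seed = seed)
  gt_te <- simulate_library(n_test, vocabulary = vocab, seed = seed + 900000L,
                            include_wt = FALSE)
  ls_te <- simulate_landscape(gt_te, em, seed = seed + 900000L,
                              facs_prescreen = FALSE)
  truth <- attr(ls_te, "truth")
  keep <- truth$ginf > truth$g0
  gts <- lapply(ls_te$records[keep], function(r) r$genotype)
  pr <- predict_phenotype(model, gts, n_draws = n_draws, seed = seed + 1L)
  tt <- truth[keep, ]
  list(ec50_fold_accuracy = fold_accuracy(10^pr$log_ec50_mean, tt$ec50),
       ginf_fold_accuracy = fold_accuracy(10^pr$log_ginf_mean, tt$ginf),
       within2_ec50 = within_fold_fraction(10^pr$log_ec50_mean, tt$ec50, 2),
       within2_ginf = within_fold_fraction(10^pr$log_ginf_mean, tt$ginf, 2),
       coverage_ec50 = mean(abs(pr$log_ec50_mean - log10(tt$ec50)) <=
                              2 * pr$log_ec50_sd),
       coverage_ginf = mean(abs(pr$log_ginf_mean - log10(tt$ginf)) <=
                              2 * pr$log_ginf_sd),
       n_test = sum(keep))
}

#' Wild-type replicate benchmark
#'
#' Simulates replicate wild-type dose-response measurements at the
#' anchor operating point, fits each replicate separately, and reports
#' the pooled-fit basal output and the replicate geometric SD of the
#' per-replicate EC50 estimates.
#'
#' @param n_replicates Number of technical replicates.
#' @param seed Integer seed.
#' @param cv Relative lognormal noise per curve point.
#' @return List: `g0_mef` (posterior-mean basal output of the pooled
#'   fit), `ec50_gsd` (geometric SD, fold), `n_replicates`.
#' @export
benchmark_wildtype <- function(n_replicates = 15L, seed = 1L, cv = 0.05) {
  wt <- biophys_to_hill(biophys_params())
  curves <- simulate_curves(wt, n_replicates = n_replicates, cv = cv,
                            seed = as.integer(seed) + 300000L)
  pooled <- suppressWarnings(
    fit_hill(data.frame(ligand = curves$IPTG, geo_mean = curves$geo_mean,
                        geo_mean_err = curves$geo_mean_err),
             seed = as.integer(seed)))
  per_rep <- vapply(split(curves, curves$clone), function(cv1) {
    f <- suppressWarnings(
      fit_hill(data.frame(ligand = cv1$IPTG, geo_mean = cv1$geo_mean,
                          geo_mean_err = cv1$geo_mean_err),
               seed = as.integer(seed) + 1L))
    posterior_point(f)[["ec50"]]
  }, 0)
  list(g0_mef = coef(pooled)[["g0"]],
       ec50_gsd = geometric_stats(per_rep)$gsd,
       n_replicates = n_replicates)
}

#' K_A mechanism benchmark for inverted sensors
#'
#' Scans the active-state ligand binding constant K_A over a grid in the
#' inverted regime (destabilised active state, K_A < K_I) and checks,
#' via [biophys_to_hill()], that decreasing K_A monotonically decreases
#' both EC50 and Ginf - the forward-engineering mechanism for improving
#' inverted variants.
#'
#' @param ka_grid Decreasing-to-increasing grid of K_A values, umol/L.
#' @param dEps_AI Allosteric constant of the inverted regime, k_B T.
#' @param K_I Inactive-state binding constant, umol/L.
#' @return List: `monotone_fraction` (fraction of adjacent grid steps
#'   where both EC50 and Ginf move with K_A), `ec50`, `ginf`, `inverted`.
#' @export
benchmark_inverted_ka <- function(ka_grid = 10^seq(log10(0.005), log10(0.3),
                                                   length.out = 12),
                                  dEps_AI = -5, K_I = 0.53) {
  fits <- lapply(ka_grid, function(ka)
    biophys_to_hill(biophys_params(dEps_AI = dEps_AI, K_A = ka, K_I = K_I)))
  ec50 <- vapply(fits, function(h) h$ec50, 0)
  ginf <- vapply(fits, function(h) h$ginf, 0)
  inverted <- vapply(fits, function(h) h$ginf < h$g0, TRUE)
  ok <- diff(ec50) >= -1e-8 * ec50[-1] & diff(ginf) >= -1e-8 * ginf[-1]
  list(monotone_fraction = mean(ok), ec50 = ec50, ginf = ginf,
       inverted = inverted)
}
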