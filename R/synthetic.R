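#' Deterministic mutation vocabulary for synthetic landscapes
#'
#' Generates a vocabulary of missense substitution codes at distinct
#' 1-based positions in a LacI-like core domain (positions 2-329).
#' Positions are unique so that any subset of the vocabulary is a valid
#' genotype.
#'
#' @param size Number of distinct mutations.
#' @param seed Integer seed (fixed default so that the default vocabulary
#'   is shared across the generator functions).
#' @return Character vector of codes, ordered by position.
#' @export
make_vocabulary <- function(size = 150, seed = 101L) {
  stopifnot(size >= 1, size <= 328)
  set.seed(as.integer(seed))
  pos <- sort(sample(2:329, size))
  wt <- sample(AA_ALPHABET, size, replace = TRUE)
  new <- vapply(wt, function(a) sample(setdiff(AA_ALPHABET, a), 1L), "")
  paste0(wt, pos, new)
}

#' Per-mutation latent effect model
#'
#' Assigns each vocabulary mutation a K-dimensional latent effect vector;
#' a genotype's latent coordinate is the *sum* of its mutations' vectors
#' (the wild type sits at zero), and the summed coordinate maps to MWC
#' biophysical parameters (see [biophys_params()]):
#' dimension 1 shifts the allosteric constant `dEps_AI`, dimension 2
#' *decreases* `log K_A` (so an increase along dimension 2 lowers the
#' active-state ligand binding constant), dimension 3 shifts the operator
#' binding energy `dEps_RA`.
#'
#' Effects are sparse and heavy-tailed, as in deep mutational scans: most
#' mutations are near-neutral, a minority have substantial effects, a
#' small fraction are strongly deleterious (large positive dimension-3
#' effect, giving constitutively high basal output), and a small fraction
#' are inversion-prone (large dimension-2 effect plus destabilised active
#' state, pushing `K_A` below `K_I`).
#'
#' @param vocabulary Character vector of mutation codes
#'   (default [make_vocabulary()]).
#' @param K Latent dimensionality (default 3; only the first 3 dimensions
#'   are mapped to biophysics, further dimensions are inert).
#' @param frac_deleterious Fraction of strongly deleterious mutations.
#' @param frac_inverting Fraction of inversion-prone mutations.
#' @param anchor Wild-type [biophys_params()] anchor.
#' @param seed Integer seed.
#' @param effects Optional p x K matrix of latent effects overriding the
#'   random draw (rows in vocabulary order); used to plant known effects.
#' @return Object of class `effect_model` with the `vocabulary`, the
#'   p x K `effects` matrix (rows named by mutation), the anchor, and the
#'   flags of deleterious / inversion-prone mutations.
#' @export
effect_model <- function(vocabulary = make_vocabulary(), K = 3L,
                         frac_deleterious = 0.05, frac_inverting = 0.03,
                         anchor = biophys_params(), seed = 202L,
                         effects = NULL) {
  stopifnot(K >= 1, frac_deleterious >= 0, frac_inverting >= 0,
            frac_deleterious + frac_inverting < 1,
            inherits(anchor, "biophys_params"))
  p <- length(vocabulary)
  set.seed(as.integer(seed))
  if (!is.null(effects)) {
    eff <- as.matrix(effects)
    stopifnot(nrow(eff) == p, ncol(eff) == K)
    dimnames(eff) <- list(vocabulary, paste0("z", seq_len(K)))
    del <- inv <- rep(FALSE, p)
  } else {
    eff <- matrix(stats::rnorm(p * K, 0, 0.05), p, K,
                  dimnames = list(vocabulary, paste0("z", seq_len(K))))
    # a minority of mutations carry substantial, heavy-tailed effects
    active <- stats::runif(p) < 0.5
    for (k in seq_len(min(K, 3L)))
      eff[active, k] <- eff[active, k] + 0.6 * stats::rt(sum(active), df = 3)
    roles <- sample(c("del", "inv", "plain"), p, replace = TRUE,
                    prob = c(frac_deleterious, frac_inverting,
                             1 - frac_deleterious - frac_inverting))
    del <- roles == "del"; inv <- roles == "inv"
    if (any(del)) eff[del, min(3L, K)] <- stats::rnorm(sum(del), 4, 1)
    if (any(inv)) {
      eff[inv, min(2L, K)] <- stats::rnorm(sum(inv), 4, 1)
      eff[inv, 1L] <- eff[inv, 1L] - abs(stats::rnorm(sum(inv), 2, 0.5))
    }
  }
  structure(list(vocabulary = as.character(vocabulary), effects = eff,
                 K = as.integer(K), anchor = anchor,
                 deleterious = vocabulary[del], inverting = vocabulary[inv],
                 seed = as.integer(seed)),
            class = "effect_model")
}

# Map summed latent coordinates (n x K matrix) to per-variant MWC
# parameter vectors around the anchor.
latent_to_biophys <- function(em, Z) {
  a <- em$anchor
  z <- function(k) if (k <= ncol(Z)) Z[, k] else 0
  list(dEps_RA = a$dEps_RA + z(3L),
       dEps_AI = a$dEps_AI + z(1L),
       K_A = exp(log(a$K_A) - z(2L)),
       K_I = rep_len(a$K_I, nrow(Z)),
       R = rep_len(a$R, nrow(Z)),
       N_NS = rep_len(a$N_NS, nrow(Z)),
       G_max = rep_len(a$G_max, nrow(Z)))
}

# True Hill parameters for a set of genotypes under an effect model.
true_hill_table <- function(em, genotypes) {
  X <- encode_genotypes(genotypes, em$vocabulary)
  Z <- X %*% em$effects
  biophys_to_hill_vec(latent_to_biophys(em, Z))
}

#' Measurement / posterior-width noise model
#'
#' Controls the synthetic landscape's reported uncertainties and the
#' lognormal noise of simulated raw dose-response curves. Posterior SDs
#' (base-10 log scale for the level parameters and EC50, linear for `n`)
#' are inflated as `quality^-1/2` for low-quality records, emulating the
#' reduced read support of FACS-prescreened (e.g. inverted) variants.
#'
#' @param log_sd Baseline posterior SDs, named `log_g0`, `log_ginf`,
#'   `log_ec50` (decades) and `n` (linear).
#' @param curve_cv Relative lognormal noise of simulated raw curve points.
#' @param quality_floor Minimum quality (caps the inflation).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(log_sd = c(log_g0 = 0.05, log_ginf = 0.03,
                                   log_ec50 = 0.06, n = 0.08),
                        curve_cv = 0.05, quality_floor = 0.05) {
  stopifnot(all(log_sd > 0), curve_cv > 0, quality_floor > 0,
            all(c("log_g0", "log_ginf", "log_ec50", "n") %in% names(log_sd)))
  structure(list(log_sd = log_sd, curve_cv = curve_cv,
                 quality_floor = quality_floor), class = "noise_model")
}

#' Simulate a mutant library of genotypes
#'
#' Missense mutation counts per variant are Poisson with the given mean
#' (the LacI-like default is 4.4); each variant's mutations are drawn
#' without replacement from the vocabulary.
#'
#' @param n_variants Number of genotypes (>= 0). The first genotype is
#'   always the wild type when `include_wt = TRUE`.
#' @param mean_missense Mean missense count (> 0).
#' @param vocabulary Mutation vocabulary (default [make_vocabulary()]).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param include_wt Prepend the wild-type genotype.
#' @return List of [genotype()]s, length `n_variants`.
#' @export
simulate_library <- function(n_variants, mean_missense = 4.4,
                             vocabulary = make_vocabulary(), seed = 1L,
                             include_wt = TRUE) {
  stopifnot(n_variants >= 0)
  if (mean_missense <= 0)
    stop("simulate_library: mean_missense must be > 0", call. = FALSE)
  if (n_variants == 0L) return(list())
  set.seed(as.integer(seed))
  counts <- pmin(stats::rpois(n_variants, mean_missense), length(vocabulary))
  if (include_wt) counts[1L] <- 0L
  lapply(counts, function(k) genotype(sample(vocabulary, k)))
}

#' The standard inducer concentration grid
#'
#' Twelve concentrations: zero plus an 11-point two-fold serial dilution
#' from the top concentration, matching the plate layout used for IPTG
#' dose-response measurements.
#'
#' @param top Highest concentration, umol/L (default 2048).
#' @return Numeric vector of length 12, ascending, starting at 0.
#' @export
ligand_grid <- function(top = 2048) {
  stopifnot(top > 0)
  c(0, top / 2^(10:0))
}

# Gaussian posterior draws in log-parameter space around a true Hill
# parameter set, with widths from the noise model inflated by quality.
simulate_posterior <- function(truth, noise, quality = 1, n_draws = 50L) {
  infl <- 1 / sqrt(max(quality, noise$quality_floor))
  sd <- noise$log_sd * infl
  mu <- c(log10(truth$g0), log10(truth$ginf), log10(truth$ec50), truth$n)
  draws <- cbind(
    log_g0 = stats::rnorm(n_draws, mu[1], sd[["log_g0"]]),
    log_ginf = stats::rnorm(n_draws, mu[2], sd[["log_ginf"]]),
    log_ec50 = stats::rnorm(n_draws, mu[3], sd[["log_ec50"]]),
    n = pmax(stats::rnorm(n_draws, mu[4], sd[["n"]]), 0.05))
  hill_posterior(draws)
}

#' Simulate a genotype-phenotype landscape
#'
#' For each genotype, true Hill parameters are derived from the summed
#' latent effects through the MWC allostery map; the emitted posterior
#' samples are centred on the truth with widths from the noise model.
#' With the FACS prescreen on, variants with high basal output are
#' retained with a probability that decreases logistically in log G0, and
#' retained high-G0 records carry proportionally reduced quality (hence
#' inflated posterior widths) - this reproduces the sparse, noisy
#' inverted tail of the real data.
#'
#' @param genotypes List of [genotype()]s (see [simulate_library()]).
#' @param em An [effect_model()]; every mutation in `genotypes` must be
#'   in its vocabulary.
#' @param noise A [noise_model()].
#' @param facs_prescreen Apply the basal-output prescreen (default TRUE).
#' @param seed Integer seed.
#' @param n_draws Posterior draws per variant.
#' @param prescreen_mid,prescreen_width Midpoint (MEF) and width (decades)
#'   of the logistic retention function.
#' @return A [landscape()]. The true Hill parameters used by the
#'   generator are attached as attribute `"truth"` (a data frame aligned
#'   with the records: `variant`, `g0`, `ginf`, `ec50`, `n`).
#' @examples
#' \donttest{
#' gt <- simulate_library(200, seed = 3)
#' ls <- simulate_landscape(gt, seed = 3)
#' head(attr(ls, "truth"))
#' }
#' @export
simulate_landscape <- function(genotypes, em = effect_model(),
                               noise = noise_model(), facs_prescreen = TRUE,
                               seed = 1L, n_draws = 50L,
                               prescreen_mid = 3000, prescreen_width = 0.5) {
  stopifnot(inherits(em, "effect_model"), inherits(noise, "noise_model"))
  set.seed(as.integer(seed))
  truth <- true_hill_table(em, genotypes)
  flat <- !is.finite(truth$ec50)
  if (any(flat)) {            # effectively flat curves: keep a nominal EC50
    truth$ec50[flat] <- em$anchor$K_A
    truth$n[flat] <- 1
  }
  keep <- rep(TRUE, nrow(truth))
  quality <- rep(1, nrow(truth))
  if (facs_prescreen) {
    p_keep <- stats::plogis((log10(prescreen_mid) - log10(truth$g0)) /
                              prescreen_width)
    keep <- stats::runif(nrow(truth)) < p_keep
    keep[1L] <- keep[1L] || length(genotypes[[1L]]) == 0L  # never drop wt
    quality <- pmax(p_keep, noise$quality_floor)
  }
  idx <- which(keep)
  records <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    tr <- list(g0 = truth$g0[i], ginf = truth$ginf[i],
               ec50 = truth$ec50[i], n = truth$n[i])
    records[[j]] <- variant_record(
      genotypes[[i]],
      simulate_posterior(tr, noise, quality[i], n_draws),
      quality = quality[i], id = sprintf("v%05d", i))
  }
  out <- landscape(records)
  attr(out, "truth") <- data.frame(variant = sprintf("v%05d", idx),
                                   g0 = truth$g0[idx], ginf = truth$ginf[idx],
                                   ec50 = truth$ec50[idx], n = truth$n[idx])
  out
}

#' Simulate raw dose-response curves for a variant
#'
#' Generates replicate dose-response measurements on the standard ligand
#' grid with multiplicative lognormal noise, in the raw-curve table
#' schema (`variant`, `mutation_codes`, `clone`, `IPTG`, `geo_mean`,
#' `geo_mean_err`, `date_plate`, `row`).
#'
#' @param params True [hill_params()].
#' @param n_replicates Number of replicate curves.
#' @param grid Ligand grid (default [ligand_grid()]).
#' @param cv Relative lognormal noise per point.
#' @param seed Integer seed.
#' @param variant,mutation_codes Identifier columns.
#' @return Data frame in the raw-curve schema.
#' @export
simulate_curves <- function(params, n_replicates = 1L, grid = ligand_grid(),
                            cv = 0.05, seed = 1L, variant = "v00001",
                            mutation_codes = "") {
  stopifnot(inherits(params, "hill_params"), n_replicates >= 1, cv > 0)
  set.seed(as.integer(seed))
  G <- hill_response(params, grid)
  do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    y <- G * exp(stats::rnorm(length(grid), 0, cv))
    data.frame(variant = variant, mutation_codes = mutation_codes,
               clone = sprintf("clone%02d", r), IPTG = grid,
               geo_mean = y, geo_mean_err = cv * y,
               date_plate = sprintf("sim_plate%02d", r),
               row = LETTERS[1L + (r - 1L) %% 8L])
  }))
}

curve_cols <- c("variant", "mutation_codes", "clone", "IPTG",
                "geo_mean", "geo_mean_err", "date_plate", "row")

#' Read / write raw dose-response curve tables
#'
#' CSV tables with columns `variant`, `mutation_codes`, `clone`, `IPTG`
#' (umol/L), `geo_mean`, `geo_mean_err` (MEF), `date_plate`, `row`.
#'
#' @param path CSV path.
#' @return `read_curves`: the curve data frame.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("read_curves: file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(mutation_codes = "character"))
  miss <- setdiff(curve_cols, names(d))
  if (length(miss))
    stop("read_curves: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname read_curves
#' @param curves Curve data frame in the same schema.
#' @export
write_curves <- function(curves, path) {
  miss <- setdiff(curve_cols, names(curves))
  if (length(miss))
    stop("write_curves: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(curves[, curve_cols], path, row.names = FALSE)
  invisible(path)
}
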