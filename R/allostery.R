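#' Biophysical parameters of an allosteric repressor
#'
#' Thermodynamic (MWC-style) description of a two-state allosteric
#' repressor such as LacI: the repressor is in equilibrium between an
#' active (operator-binding) and an inactive conformation, each with two
#' ligand-binding sites, and represses output in proportion to its
#' operator occupancy.
#'
#' Defaults describe a wild-type-like non-inverted LacI sensor: operator
#' binding energy and allosteric constant in the range reported for LacI
#' thermodynamic models, ligand (IPTG) dissociation constants
#' `K_A > K_I`, and an output scale `G_max` calibrated so the wild-type
#' anchor reproduces a basal output near 158 MEF and a saturating output
#' near 25 kMEF.
#'
#' @param dEps_RA Operator binding free energy, k_B T units (more
#'   negative = tighter operator binding).
#' @param dEps_AI Log allosteric constant, k_B T units (free-energy
#'   difference between active and inactive conformations; positive
#'   favours the active state in the absence of ligand).
#' @param K_A Ligand dissociation constant of the active state, umol/L.
#' @param K_I Ligand dissociation constant of the inactive state, umol/L.
#' @param R Repressor copy number per cell, dimensionless.
#' @param N_NS Number of nonspecific genomic background sites.
#' @param G_max Unrepressed output level, MEF.
#' @return Object of class `biophys_params`.
#' @export
biophys_params <- function(dEps_RA = -15.3, dEps_AI = 4.5,
                           K_A = 139, K_I = 0.53,
                           R = 208, N_NS = 4.6e6, G_max = 31520) {
  for (nm in c("K_A", "K_I", "R", "N_NS", "G_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("biophys_params: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  stopifnot(is.finite(dEps_RA), is.finite(dEps_AI))
  structure(list(dEps_RA = dEps_RA, dEps_AI = dEps_AI, K_A = K_A, K_I = K_I,
                 R = R, N_NS = N_NS, G_max = G_max),
            class = "biophys_params")
}

#' @export
print.biophys_params <- function(x, ...) {
  cat(sprintf(
    "MWC repressor: dEps_RA = %.3g kT, dEps_AI = %.3g kT, K_A = %.3g, K_I = %.3g umol/L\n",
    x$dEps_RA, x$dEps_AI, x$K_A, x$K_I))
  cat(sprintf("  R = %.3g, N_NS = %.3g, G_max = %.3g MEF\n", x$R, x$N_NS, x$G_max))
  invisible(x)
}

# Probability that the repressor is in the active conformation at ligand
# concentration c (two ligand-binding sites per repressor).
p_active <- function(c, dEps_AI, K_A, K_I) {
  a <- (1 + c / K_A)^2
  b <- exp(-dEps_AI) * (1 + c / K_I)^2
  a / (a + b)
}

#' Fold-change in output under allosteric repression
#'
#' `fold_change = [1 + p_act(c) (R/N_NS) exp(-dEps_RA)]^-1`, where
#' `p_act` is the active-state probability of the MWC two-state model.
#' The value is the ratio of repressed to unrepressed expression and lies
#' in (0, 1].
#'
#' @param bp A [biophys_params()].
#' @param c Ligand concentration(s), umol/L, >= 0; vectorized.
#' @return Numeric vector in (0, 1].
#' @export
fold_change <- function(bp, c) {
  stopifnot(inherits(bp, "biophys_params"))
  if (any(!is.finite(c)) || any(c < 0))
    stop("fold_change: ligand concentrations must be finite and >= 0",
         call. = FALSE)
  pa <- p_active(c, bp$dEps_AI, bp$K_A, bp$K_I)
  1 / (1 + pa * (bp$R / bp$N_NS) * exp(-bp$dEps_RA))
}

# Vectorized biophys -> Hill map over parameter columns. `df` is a data
# frame / list with numeric vectors dEps_RA, dEps_AI, K_A, K_I, R, N_NS,
# G_max (recycled to a common length). Returns a data.frame with g0,
# ginf, ec50, n. The MWC dose-response is monotone in c for all valid
# parameters, so the midpoint crossing is unique; EC50 is found by
# bisection on log(c).
biophys_to_hill_vec <- function(df, rel_tol = 1e-6,
                                bracket = c(1e-3, 1e6)) {
  len <- max(lengths(df))
  p <- lapply(df, rep_len, len)
  gout <- function(c) {
    # c is a vector of per-variant concentrations (or scalar)
    a <- (1 + c / p$K_A)^2
    b <- exp(-p$dEps_AI) * (1 + c / p$K_I)^2
    pa <- a / (a + b)
    p$G_max / (1 + pa * (p$R / p$N_NS) * exp(-p$dEps_RA))
  }
  pa0 <- 1 / (1 + exp(-p$dEps_AI))
  painf <- 1 / (1 + exp(-p$dEps_AI) * (p$K_A / p$K_I)^2)
  rep_strength <- (p$R / p$N_NS) * exp(-p$dEps_RA)
  g0 <- p$G_max / (1 + pa0 * rep_strength)
  ginf <- p$G_max / (1 + painf * rep_strength)
  mid <- (g0 + ginf) / 2
  sgn <- sign(ginf - g0)                 # direction of the response
  lo <- rep_len(log(bracket[1]), len)
  hi <- rep_len(log(bracket[2]), len)
  flat <- abs(ginf - g0) <= 1e-12 * pmax(g0, ginf)
  for (it in 1:60) {
    mid_l <- (lo + hi) / 2
    val <- gout(exp(mid_l))
    up <- sgn * (val - mid) < 0          # still below midpoint along the response
    lo <- ifelse(up, mid_l, lo)
    hi <- ifelse(up, hi, mid_l)
    if (max(hi - lo) < rel_tol / 2) break
  }
  ec50 <- exp((lo + hi) / 2)
  # Hill coefficient from the log-slope at EC50:
  # for a Hill curve dG/dlnL at EC50 = (Ginf - G0) * n / 4
  h <- 1e-4
  dG <- (gout(ec50 * exp(h)) - gout(ec50 * exp(-h))) / (2 * h)
  n <- ifelse(flat, NA_real_, 4 * dG / (ginf - g0))
  data.frame(g0 = g0, ginf = ginf, ec50 = ifelse(flat, NA_real_, ec50), n = n)
}

#' Convert biophysical parameters to Hill parameters
#'
#' Maps an MWC parameter set to the four Hill parameters of the resulting
#' dose-response curve `G(c) = G_max * fold_change(c)`: `G0 = G(0)` and
#' `Ginf = G(Inf)` in closed form, `EC50` as the unique concentration
#' where the output crosses `(G0 + Ginf)/2` (bisection on a log grid to
#' relative tolerance 1e-6 within 1e-3 to 1e6 umol/L), and `n` from the
#' log-slope of the curve at EC50. Monotonicity of `G(c)` is checked
#' numerically before root-finding.
#'
#' @param bp A [biophys_params()].
#' @return A [hill_params()].
#' @examples
#' biophys_to_hill(biophys_params())  # wild-type-like anchor
#' @export
biophys_to_hill <- function(bp) {
  stopifnot(inherits(bp, "biophys_params"))
  grid <- c(0, 10^seq(-3, 6, length.out = 200))
  G <- bp$G_max * fold_change(bp, grid)
  d <- diff(G)
  tol <- 1e-9 * max(G)
  if (any(d > tol) && any(d < -tol))
    stop("biophys_to_hill: dose-response is not monotone; ",
         "phenotype is not Hill-representable", call. = FALSE)
  hp <- biophys_to_hill_vec(lapply(unclass(bp), as.numeric))
  if (!is.finite(hp$ec50))
    stop("biophys_to_hill: flat dose-response (Ginf = G0); ",
         "EC50 is undefined", call. = FALSE)
  hill_params(hp$g0, hp$ginf, hp$ec50, hp$n)
}
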