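#' One-hot encode genotypes against a mutation vocabulary
#'
#' @param x A [landscape()], or a list of [genotype()]s / character
#'   vectors of mutation codes.
#' @param vocabulary Character vector fixing the column order (default:
#'   the landscape's vocabulary).
#' @return Binary matrix with one row per variant and one column per
#'   vocabulary mutation; the wild type encodes to the zero row and row
#'   sums equal mutation counts.
#' @export
encode_genotypes <- function(x, vocabulary = NULL) {
  if (inherits(x, "landscape")) {
    if (is.null(vocabulary)) vocabulary <- x$vocabulary
    x <- lapply(x$records, function(r) r$genotype)
  }
  if (is.null(vocabulary))
    stop("encode_genotypes: a vocabulary is required", call. = FALSE)
  vocabulary <- as.character(vocabulary)
  X <- matrix(0L, length(x), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(x)) {
    codes <- as.character(unclass(x[[i]]))
    codes <- codes[nzchar(codes)]
    unknown <- setdiff(codes, vocabulary)
    if (length(unknown))
      stop("encode_genotypes: mutation(s) not in vocabulary: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    X[i, codes] <- 1L
  }
  X
}

# Fit one smooth probabilistic surface over the active latent dimensions.
# Uses bam() with discretization for large n. Returns the fitted mgcv
# object; an intercept-only fit when no dimension varies.
fit_surface <- function(z, y, active) {
  d <- as.data.frame(z)
  d$.y <- y
  if (!any(active)) return(mgcv::gam(.y ~ 1, data = d))
  vars <- colnames(z)[active]
  kk <- c(10, 7, 5, 4)[min(length(vars), 4L)]
  form <- if (length(vars) == 1L)
    stats::as.formula(sprintf(".y ~ s(%s, k = 10)", vars))
  else
    stats::as.formula(sprintf(".y ~ te(%s, k = %d)",
                              paste(vars, collapse = ", "), kk))
  if (nrow(d) >= 3000)
    mgcv::bam(form, data = d, discrete = TRUE)
  else
    mgcv::gam(form, data = d, method = "REML")
}

surface_mean <- function(fit, z) {
  as.numeric(mgcv::predict.gam(fit, newdata = as.data.frame(z)))
}

#' Train an interpretable latent genotype-phenotype model
#'
#' Learns a low-dimensional linear embedding of one-hot genotypes,
#' `z = x W` with `K << p`, composed with a smooth nonlinear surface
#' `y = f(z)` per phenotype. Multi-mutant embeddings are additive by
#' construction: the embedding of a genotype is the sum of its mutations'
#' latent effect vectors.
#'
#' Fitting is by projection pursuit with Gauss-Newton refinement: the
#' leading latent directions come from the singular value decomposition
#' of the multivariate (ridge-stabilised) least-squares coefficients of
#' the phenotypes on the one-hot encoding; when `K` exceeds the linear
#' rank, further directions are extracted the same way from the
#' residuals of a smooth fit on the directions found so far. The
#' embedding is then refined by a few damped Gauss-Newton steps that
#' minimise the joint surface residual over all phenotypes (linearising
#' the surfaces around the current coordinates and re-fitting them after
#' every accepted step), which substantially sharpens the recovered
#' latent span. Each latent coordinate is scaled to unit variance,
#' dimensions are ordered by their contribution to explained phenotype
#' variance, and the final surfaces are tensor-product smooths
#' (thin-plate for `K = 1`) with a samplable coefficient posterior.
#'
#' @param X Binary genotype matrix from [encode_genotypes()] (n x p).
#' @param Y Phenotype matrix (n x D), finite; conventionally columns
#'   `log_ec50` and `log_ginf` (and optionally `log_g0`) on base-10 log
#'   scales.
#' @param K Latent dimensionality (default 3).
#' @param refine_iter Damped Gauss-Newton refinement steps (default 3;
#'   0 disables refinement).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return Object of class `latent_landscape`: the p x K latent effect
#'   matrix `W` (rows named by mutation) with standard errors `W_se`, the
#'   fitted `surfaces` (one per phenotype), per-dimension
#'   `explained_variance`, the training coordinate ranges used to guard
#'   extrapolation, and residual scales `sigma`.
#' @examples
#' \donttest{
#' ls <- simulate_landscape(simulate_library(1000, seed = 2), seed = 2)
#' m <- fit_latent_landscape(ls, K = 3, seed = 2)
#' head(latent_effects_report(m))
#' }
#' @export
train_latent_model <- function(X, Y, K = 3L, refine_iter = 3L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); D <- ncol(Y)
  if (nrow(Y) != n) stop("train_latent_model: X and Y rows must align", call. = FALSE)
  if (any(!is.finite(Y)))
    stop("train_latent_model: Y must be finite (exclude ill-defined fits upstream)",
         call. = FALSE)
  K <- as.integer(K)
  if (K < 1L || K >= p)
    stop("train_latent_model: need 1 <= K < p", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(D))
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(p))
  set.seed(as.integer(seed))

  # ridge-stabilised multivariate OLS of Y on [1, X]
  lam <- 1e-6 * n
  Xi <- cbind(1, X)
  XtXinv <- chol2inv(chol(crossprod(Xi) + diag(c(0, rep(lam, p)))))
  solve_full <- function(Ymat) XtXinv %*% crossprod(Xi, Ymat)
  ols <- function(Ymat) solve_full(Ymat)[-1L, , drop = FALSE]
  Ball <- solve_full(Y)
  B <- Ball[-1L, , drop = FALSE]
  sig2_lin <- colSums((Y - Xi %*% Ball)^2) / max(n - p - 1L, 1L)
  varB <- outer(diag(XtXinv)[-1L], sig2_lin)   # p x D coefficient variances

  take_dirs <- function(Bmat, Vmat, m) {
    sv <- svd(Bmat)
    r <- sum(sv$d > max(1e-8 * max(sv$d, 1e-12), 1e-10))
    r <- min(r, m)
    if (r == 0L) return(NULL)
    list(A = sv$u[, seq_len(r), drop = FALSE] %*%
           diag(sv$d[seq_len(r)], r),
         se = sqrt(Vmat %*% (sv$v[, seq_len(r), drop = FALSE]^2)),
         r = r)
  }

  W <- matrix(0, p, K, dimnames = list(colnames(X), paste0("z", seq_len(K))))
  W_se <- W
  d0 <- take_dirs(B, varB, K)
  filled <- 0L
  if (!is.null(d0)) {
    W[, seq_len(d0$r)] <- d0$A
    W_se[, seq_len(d0$r)] <- d0$se[, seq_len(d0$r)]
    filled <- d0$r
  }
  # residual directions beyond the linear rank
  while (filled < K) {
    z <- X %*% W[, seq_len(max(filled, 1L)), drop = FALSE]
    colnames(z) <- paste0("z", seq_len(ncol(z)))
    act <- apply(z, 2L, stats::sd) > 1e-10
    R <- Y
    for (dph in seq_len(D)) {
      f <- fit_surface(z, Y[, dph], act)
      R[, dph] <- Y[, dph] - surface_mean(f, z)
    }
    Br <- ols(R)
    sig2_r <- colSums(R^2) / max(n - p - 1L, 1L)
    dr <- take_dirs(Br, outer(diag(XtXinv)[-1L], sig2_r), 1L)
    if (is.null(dr)) break                 # nothing left to extract
    filled <- filled + 1L
    W[, filled] <- dr$A[, 1L]
    W_se[, filled] <- dr$se[, 1L]
  }

  # damped Gauss-Newton refinement of the embedding against the surfaces
  if (refine_iter > 0L && any(abs(W) > 0)) {
    surf_for <- function(Wc) {
      Zc <- X %*% Wc
      colnames(Zc) <- paste0("z", seq_len(K))
      act <- apply(Zc, 2L, stats::sd) > 1e-10
      list(Z = Zc,
           fits = lapply(seq_len(D), function(dph)
             fit_surface(Zc, Y[, dph], act)))
    }
    loss_of <- function(st) {
      zdf <- as.data.frame(st$Z)
      sum(vapply(seq_len(D), function(dph)
        mean((Y[, dph] - surface_mean(st$fits[[dph]], zdf))^2), 0))
    }
    st <- surf_for(W)
    h <- 0.01
    for (it in seq_len(refine_iter)) {
      zdf <- as.data.frame(st$Z)
      AtA <- matrix(0, K * p, K * p)
      Atb <- numeric(K * p)
      for (dph in seq_len(D)) {
        f <- st$fits[[dph]]
        res <- Y[, dph] - surface_mean(f, zdf)
        A <- matrix(0, n, K * p)
        for (k in seq_len(K)) {
          zp <- zdf; zp[[k]] <- zp[[k]] + h
          zm <- zdf; zm[[k]] <- zm[[k]] - h
          g <- (surface_mean(f, zp) - surface_mean(f, zm)) / (2 * h)
          A[, ((k - 1L) * p + 1L):(k * p)] <- g * X
        }
        AtA <- AtA + crossprod(A)
        Atb <- Atb + crossprod(A, res)[, 1L]
      }
      dW <- matrix(solve(AtA + diag(1e-3 * n, K * p), Atb), p, K)
      loss0 <- loss_of(st)
      step <- 1
      accepted <- FALSE
      while (step >= 1 / 32) {
        cand <- surf_for(W + step * dW)
        if (loss_of(cand) < loss0) {
          W <- W + step * dW
          st <- cand
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
    }
  }

  # scale each latent coordinate to unit variance
  Zs <- X %*% W
  sc <- apply(Zs, 2L, stats::sd)
  sc[sc < 1e-12] <- 1
  W <- sweep(W, 2L, sc, "/")
  W_se <- sweep(W_se, 2L, sc, "/")
  Z <- X %*% W
  colnames(Z) <- colnames(W)
  active <- apply(Z, 2L, stats::sd) > 1e-10

  fit_all <- function(Zmat) {
    lapply(seq_len(D), function(dph)
      fit_surface(Zmat, Y[, dph], apply(Zmat, 2L, stats::sd) > 1e-10))
  }
  surfaces <- fit_all(Z)

  # order dimensions by knockout loss of explained variance
  r2 <- function(surf, Zmat) {
    tot <- 0
    for (dph in seq_len(D)) {
      pr <- surface_mean(surf[[dph]], Zmat)
      tot <- tot + max(0, 1 - stats::var(Y[, dph] - pr) / stats::var(Y[, dph]))
    }
    tot / D
  }
  r2_full <- r2(surfaces, Z)
  ev <- vapply(seq_len(K), function(k) {
    Zk <- Z; Zk[, k] <- 0
    r2_full - r2(surfaces, Zk)
  }, 0)
  ord <- order(ev, decreasing = TRUE)
  if (!identical(ord, seq_len(K))) {
    W <- W[, ord, drop = FALSE]; W_se <- W_se[, ord, drop = FALSE]
    ev <- ev[ord]
    colnames(W) <- colnames(W_se) <- paste0("z", seq_len(K))
    Z <- X %*% W
    colnames(Z) <- colnames(W)
    surfaces <- fit_all(Z)
  }

  sigma <- vapply(surfaces, function(f) sqrt(f$sig2), 0)
  structure(list(
    W = W, W_se = W_se, K = K, vocabulary = colnames(X),
    phenotypes = colnames(Y), surfaces = surfaces,
    explained_variance = stats::setNames(ev, colnames(W)),
    z_range = apply(Z, 2L, range), sigma = sigma,
    r2 = r2_full, n_train = n, seed = as.integer(seed)),
    class = "latent_landscape")
}

#' Train a latent model directly from a landscape
#'
#' Convenience wrapper around [train_latent_model()]: encodes the
#' landscape's genotypes, takes the posterior-mean `log_ec50`, `log_ginf`
#' and `log_g0` (base-10) as phenotypes, and by default excludes inverted
#' variants, whose noisy, sparsely sampled phenotypes the latent model is
#' not expected to learn. Modelling the basal output alongside EC50 and
#' Ginf gives the linear stage a third independent constraint on the
#' latent span, which markedly improves the recovered embedding.
#'
#' @param x A [landscape()].
#' @param K Latent dimensionality.
#' @param seed Integer seed.
#' @param exclude_inverted Drop records with median Ginf < G0.
#' @param include_g0 Model `log_g0` as a third phenotype (default TRUE).
#' @param ... Passed to [train_latent_model()] (e.g. `refine_iter`).
#' @return A `latent_landscape` (see [train_latent_model()]).
#' @export
fit_latent_landscape <- function(x, K = 3L, seed = 1L,
                                 exclude_inverted = TRUE,
                                 include_g0 = TRUE, ...) {
  stopifnot(inherits(x, "landscape"))
  keep <- if (exclude_inverted) !x$summary$inverted else
    rep(TRUE, length(x$records))
  X <- encode_genotypes(x)[keep, , drop = FALSE]
  Y <- cbind(log_ec50 = log10(x$summary$ec50[keep]),
             log_ginf = log10(x$summary$ginf[keep]))
  if (include_g0) Y <- cbind(Y, log_g0 = log10(x$summary$g0[keep]))
  train_latent_model(X, Y, K = K, seed = seed, ...)
}

#' @export
print.latent_landscape <- function(x, ...) {
  cat(sprintf("Latent genotype-phenotype model: K = %d, p = %d mutations, %d phenotypes\n",
              x$K, length(x$vocabulary), length(x$phenotypes)))
  cat(sprintf("  trained on %d variants, R^2 = %.3f\n", x$n_train, x$r2))
  cat("  explained variance by dimension:",
      paste(sprintf("%s %.3f", names(x$explained_variance),
                    x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.latent_landscape <- function(object, ...) object$W

#' Monte Carlo predictive summary for genotypes
#'
#' Embeds each genotype (`z` = sum of its mutations' latent vectors),
#' clamps the coordinates to the training range to avoid spline
#' extrapolation, and draws from the surface's approximate coefficient
#' posterior; by default residual noise is added so the draws represent
#' the posterior predictive distribution of a new measurement. Mean and
#' SD of the draws summarise the predictive interval.
#'
#' @param model A `latent_landscape`.
#' @param genotypes List of [genotype()]s (or character vectors), or a
#'   [landscape()].
#' @param n_draws Number of Monte Carlo draws (default 50).
#' @param seed Integer seed.
#' @param include_noise Add residual observation noise to each draw.
#' @param raw Also return the draw array.
#' @return Data frame with one row per genotype: `mutation_codes`, then
#'   `<phenotype>_mean` and `<phenotype>_sd` columns. With `raw = TRUE`
#'   the draws (genotypes x draws x phenotypes) are attached as
#'   attribute `"draws"`.
#' @export
predict_phenotype <- function(model, genotypes, n_draws = 50L, seed = 1L,
                              include_noise = TRUE, raw = FALSE) {
  stopifnot(inherits(model, "latent_landscape"), n_draws >= 1)
  if (n_draws == 1L)
    warning("predict_phenotype: n_draws = 1 gives a degenerate SD of 0",
            call. = FALSE)
  if (inherits(genotypes, "landscape"))
    genotypes <- lapply(genotypes$records, function(r) r$genotype)
  if (inherits(genotypes, "genotype") || is.character(genotypes))
    genotypes <- list(genotypes)
  set.seed(as.integer(seed))
  X <- encode_genotypes(genotypes, model$vocabulary)
  Z <- X %*% model$W
  for (k in seq_len(ncol(Z)))              # no extrapolation beyond training
    Z[, k] <- pmin(pmax(Z[, k], model$z_range[1L, k]), model$z_range[2L, k])
  zdf <- as.data.frame(Z)
  colnames(zdf) <- colnames(model$W)
  nv <- nrow(Z); D <- length(model$phenotypes)
  draws <- array(NA_real_, c(nv, n_draws, D),
                 dimnames = list(NULL, NULL, model$phenotypes))
  for (dph in seq_len(D)) {
    f <- model$surfaces[[dph]]
    Xp <- mgcv::predict.gam(f, newdata = zdf, type = "lpmatrix")
    beta <- mgcv::rmvn(n_draws, as.numeric(stats::coef(f)), f$Vp)
    if (n_draws == 1L) beta <- matrix(beta, nrow = 1L)
    mu <- Xp %*% t(beta)
    if (include_noise)
      mu <- mu + matrix(stats::rnorm(nv * n_draws, 0, model$sigma[dph]),
                        nv, n_draws)
    draws[, , dph] <- mu
  }
  out <- data.frame(mutation_codes = vapply(genotypes, function(g)
    format(genotype(as.character(unclass(g)))), ""))
  for (dph in seq_len(D)) {
    ph <- model$phenotypes[dph]
    m <- matrix(draws[, , dph], nv, n_draws)
    out[[paste0(ph, "_mean")]] <- rowMeans(m)
    out[[paste0(ph, "_sd")]] <- if (n_draws > 1L) apply(m, 1L, stats::sd) else 0
  }
  if (raw) attr(out, "draws") <- draws
  out
}

#' @param object A `latent_landscape`.
#' @param newdata Genotypes (as in [predict_phenotype()]).
#' @param ... Passed to [predict_phenotype()].
#' @rdname predict_phenotype
#' @export
predict.latent_landscape <- function(object, newdata, ...) {
  predict_phenotype(object, newdata, ...)
}

#' Per-mutation latent effect table
#'
#' One row per vocabulary mutation with its latent effect vector,
#' standard errors, and a per-dimension significance flag
#' (`|effect| > 2 SE`).
#'
#' @param model A `latent_landscape`.
#' @return Data frame with columns `mutation`, `effect_z*`, `se_z*`,
#'   `significant_z*`.
#' @export
latent_effects_report <- function(model) {
  stopifnot(inherits(model, "latent_landscape"))
  out <- data.frame(mutation = rownames(model$W), row.names = NULL)
  for (k in seq_len(model$K)) {
    out[[paste0("effect_z", k)]] <- model$W[, k]
    out[[paste0("se_z", k)]] <- model$W_se[, k]
    out[[paste0("significant_z", k)]] <-
      abs(model$W[, k]) > 2 * model$W_se[, k]
  }
  out
}

#' Rank mutations for biophysics-guided improvement
#'
#' Returns the mutations with a significant effect of the requested sign
#' on the chosen latent dimension, ranked by signed effect size - the
#' forward-engineering step that pairs the latent model with a
#' biophysical hypothesis about what the dimension encodes (e.g. latent
#' dimension 2 tracking the active-state ligand binding constant K_A).
#'
#' @param model A `latent_landscape`.
#' @param dimension Latent dimension index (1-based, <= K).
#' @param direction +1 (increase, default) or -1 (decrease).
#' @param top_m Maximum number of mutations returned.
#' @return Data frame `mutation`, `effect`, `se`, ranked.
#' @export
propose_improvement_mutations <- function(model, dimension, direction = 1,
                                          top_m = 3L) {
  stopifnot(inherits(model, "latent_landscape"))
  if (!(dimension %in% seq_len(model$K)))
    stop("propose_improvement_mutations: dimension must be in 1..K", call. = FALSE)
  direction <- sign(direction)
  if (direction == 0) stop("direction must be +1 or -1", call. = FALSE)
  eff <- model$W[, dimension]
  se <- model$W_se[, dimension]
  keep <- abs(eff) > 2 * se & sign(eff) == direction
  out <- data.frame(mutation = rownames(model$W)[keep],
                    effect = eff[keep], se = se[keep], row.names = NULL)
  out <- out[order(-direction * out$effect), , drop = FALSE]
  utils::head(out, top_m)
}

#' @export
plot.latent_landscape <- function(x, dimension = 1L, phenotype = 1L, ...) {
  zr <- x$z_range[, dimension]
  grid <- seq(zr[1L], zr[2L], length.out = 100)
  Z <- matrix(0, 100, x$K, dimnames = list(NULL, colnames(x$W)))
  Z[, dimension] <- grid
  mu <- surface_mean(x$surfaces[[phenotype]], Z)
  graphics::plot(grid, mu, type = "l",
                 xlab = paste0("latent z", dimension, " (others at 0)"),
                 ylab = x$phenotypes[phenotype], ...)
  invisible(x)
}
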