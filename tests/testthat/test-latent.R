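test_that("one-hot encoding fixes column order and rejects unknown mutations", {
  vocab <- c("A2V", "R5K", "V136E")
  X <- encode_genotypes(list(genotype(character()),
                             genotype(c("V136E", "A2V")),
                             genotype("R5K")), vocab)
  expect_equal(colnames(X), vocab)
  expect_equal(X[1, ], c(A2V = 0L, R5K = 0L, V136E = 0L))
  expect_equal(rowSums(X), c(0, 2, 1))
  expect_error(encode_genotypes(list(genotype("C7W")), vocab),
               "C7W")
})

test_that("a purely additive landscape with K = 1 recovers the planted effects", {
  set.seed(15)
  p <- 30; n <- 600
  beta <- rnorm(p, 0, 0.5)
  X <- matrix(rbinom(n * p, 1, 0.12), n, p,
              dimnames = list(NULL, paste0("A", 2:(p + 1), "V")))
  Y <- cbind(log_ec50 = drop(X %*% beta) + rnorm(n, 0, 0.05))
  m <- train_latent_model(X, Y, K = 1, seed = 15)
  expect_gt(abs(cor(m$W[, 1], beta)), 0.95)
})

test_that("a planted saturating nonlinearity is fit better than a linear baseline", {
  set.seed(16)
  p <- 25; n <- 800
  beta <- rnorm(p, 0, 0.8)
  X <- matrix(rbinom(n * p, 1, 0.15), n, p,
              dimnames = list(NULL, paste0("A", 2:(p + 1), "V")))
  z <- drop(X %*% beta)
  f <- function(z) 2 * tanh(z)                     # saturating 1-D trait
  Y <- cbind(log_ec50 = f(z) + rnorm(n, 0, 0.05))
  # held-out split
  tr <- 1:600; te <- 601:800
  m <- train_latent_model(X[tr, ], Y[tr, , drop = FALSE], K = 1, seed = 16)
  gte <- lapply(te, function(i) genotype(colnames(X)[X[i, ] == 1]))
  pred <- predict_phenotype(m, gte, n_draws = 30, seed = 1,
                            include_noise = FALSE)
  lin <- lm.fit(cbind(1, X[tr, ]), Y[tr, 1])
  lin_pred <- drop(cbind(1, X[te, ]) %*% lin$coefficients)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(pred$log_ec50_mean, Y[te, 1]), rmse(lin_pred, Y[te, 1]))
})

test_that("constant phenotypes give a constant surface and null effects", {
  set.seed(17)
  X <- matrix(rbinom(600, 1, 0.2), 60, 10,
              dimnames = list(NULL, paste0("A", 2:11, "V")))
  Y <- cbind(log_ec50 = rep(2, 60))
  m <- train_latent_model(X, Y, K = 2, seed = 17)
  expect_lt(max(abs(m$W)), 0.05)
  pr <- predict_phenotype(m, list(genotype("A2V"), genotype(character())),
                          n_draws = 20, seed = 2, include_noise = FALSE)
  expect_equal(pr$log_ec50_mean, rep(2, 2), tolerance = 0.02)
  rep_tab <- latent_effects_report(m)
  expect_false(any(rep_tab$significant_z1))
})

test_that("multi-mutant embeddings are sums of per-mutation latent vectors", {
  ls <- simulate_landscape(simulate_library(800, seed = 23), seed = 23)
  m <- fit_latent_landscape(ls, K = 2, seed = 23)
  W <- coef(m)
  g <- genotype(c(rownames(W)[3], rownames(W)[7]))
  z <- encode_genotypes(list(g), m$vocabulary) %*% W
  expect_equal(drop(z), W[3, ] + W[7, ])
})

test_that("wild-type predictions sit at the surface value at z = 0", {
  ls <- simulate_landscape(simulate_library(800, seed = 24), seed = 24)
  m <- fit_latent_landscape(ls, K = 2, seed = 24)
  pr <- predict_phenotype(m, list(genotype(character())), n_draws = 400,
                          seed = 3, include_noise = FALSE)
  z0 <- as.data.frame(matrix(0, 1, m$K, dimnames = list(NULL, colnames(m$W))))
  mu0 <- as.numeric(mgcv::predict.gam(m$surfaces[[1]], newdata = z0))
  expect_equal(pr$log_ec50_mean, mu0, tolerance = 4 * pr$log_ec50_sd / sqrt(400))
})

test_that("more Monte Carlo draws shrink the error of the predictive mean", {
  ls <- simulate_landscape(simulate_library(600, seed = 25), seed = 25)
  m <- fit_latent_landscape(ls, K = 2, seed = 25)
  g <- list(genotype(m$vocabulary[1]))
  means_for <- function(nd) vapply(1:15, function(s)
    predict_phenotype(m, g, n_draws = nd, seed = 1000 + s)$log_ec50_mean, 0)
  expect_lt(sd(means_for(1000)), sd(means_for(10)))
})

test_that("n_draws = 1 is flagged degenerate with SD 0", {
  ls <- simulate_landscape(simulate_library(300, seed = 26), seed = 26)
  m <- fit_latent_landscape(ls, K = 1, seed = 26)
  expect_warning(
    pr <- predict_phenotype(m, list(genotype(character())), n_draws = 1),
    "degenerate")
  expect_equal(pr$log_ec50_sd, 0)
})

test_that("effect report flags planted large effects and only those", {
  set.seed(27)
  p <- 20; n <- 800
  X <- matrix(rbinom(n * p, 1, 0.15), n, p,
              dimnames = list(NULL, paste0("A", 2:(p + 1), "V")))
  beta2 <- rep(0, p); beta2[5] <- 2          # big effect on one mutation only
  beta1 <- rnorm(p, 0, 0.4)
  Y <- cbind(log_ec50 = drop(X %*% beta1) + rnorm(n, 0, 0.05),
             log_ginf = drop(X %*% beta2) + rnorm(n, 0, 0.05))
  m <- train_latent_model(X, Y, K = 2, seed = 27)
  rep_tab <- latent_effects_report(m)
  expect_equal(nrow(rep_tab), p)
  # the planted mutation must be significant on the dimension that
  # carries the log_ginf signal
  dim_of_5 <- which.max(abs(m$W[5, ]))
  expect_true(rep_tab[[paste0("significant_z", dim_of_5)]][5])
  # proposing improvements along that dimension ranks it first
  prop <- propose_improvement_mutations(m, dim_of_5,
                                        direction = sign(m$W[5, dim_of_5]))
  expect_equal(prop$mutation[1], rownames(m$W)[5])
  # direction flip excludes it
  flip <- propose_improvement_mutations(m, dim_of_5,
                                        direction = -sign(m$W[5, dim_of_5]))
  expect_false(rownames(m$W)[5] %in% flip$mutation)
  expect_error(propose_improvement_mutations(m, 5), "1..K")
})

test_that("training validates its configuration", {
  X <- matrix(rbinom(100, 1, 0.3), 20, 5,
              dimnames = list(NULL, paste0("A", 2:6, "V")))
  Y <- cbind(log_ec50 = rnorm(20))
  expect_error(train_latent_model(X, Y, K = 5), "K < p")
  Yna <- Y; Yna[1] <- NA
  expect_error(train_latent_model(X, Yna, K = 1), "finite")
  expect_error(train_latent_model(X, Y[-1, , drop = FALSE], K = 1), "align")
})
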