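test_that("EC50 correction recovers hand-computed ln-ln fits", {
  # identity data -> identity map
  x <- c(1, 10, 100, 1000)
  cm <- fit_ec50_correction(x, x)
  expect_equal(cm$slope, 1, tolerance = 1e-12)
  expect_equal(cm$intercept, 0, tolerance = 1e-12)
  expect_equal(predict(cm, 37), 37, tolerance = 1e-10)
  # two points (ln x, ln y) = (0, 0.5), (1, 1): slope 0.5, intercept 0.5
  cm2 <- fit_ec50_correction(exp(c(0, 1)), exp(c(0.5, 1)))
  expect_equal(cm2$slope, 0.5)
  expect_equal(cm2$intercept, 0.5)
  # compressive (slope < 1) fits raise low and lower high predictions
  expect_gt(predict(cm2, 1e-3), 1e-3)
  expect_lt(predict(cm2, 1e3), 1e3)
  expect_error(fit_ec50_correction(1, 1), "length >= 2")
  expect_error(fit_ec50_correction(c(2, 2), c(1, 3)), "degenerate")
  expect_error(fit_ec50_correction(c(-1, 2), c(1, 3)), "positive")
})

test_that("success probability equals the draw-counting oracle", {
  spec <- specification(ec50_target = 100, ec50_fold = 1.2)
  # hand-constructed 10-draw posterior with exactly 4 draws in band
  ec50 <- c(rep(100, 4), rep(500, 6))
  post <- hill_posterior(cbind(log_g0 = rep(2, 10), log_ginf = rep(4, 10),
                               log_ec50 = log10(ec50), n = rep(1.5, 10)))
  expect_equal(success_probability(post, spec), 0.4)
  # all inside / none inside
  post_in <- hill_posterior(cbind(2, 4, log10(rep(100, 5)), 1.5))
  expect_equal(success_probability(post_in, spec), 1.0)
  post_out <- hill_posterior(cbind(2, 4, log10(rep(1000, 5)), 1.5))
  expect_equal(success_probability(post_out, spec), 0.0)
})

test_that("success probability matches an exhaustive count on random posteriors", {
  spec <- specification(ec50_target = 50, ec50_fold = 1.5,
                        ginf_target = 16000, ginf_fold = 1.3, g0_upper = 2000)
  for (s in 1:50) {
    post <- make_posterior(log_g0 = runif(1, 1, 4), log_ginf = runif(1, 3, 5),
                           log_ec50 = runif(1, 1, 2.5), seed = s)
    m <- post$samples
    oracle <- mean(
      10^m[, "log_ec50"] >= 50 / 1.5 & 10^m[, "log_ec50"] <= 50 * 1.5 &
      10^m[, "log_ginf"] >= 16000 / 1.3 & 10^m[, "log_ginf"] <= 16000 * 1.3 &
      10^m[, "log_g0"] < 2000)
    expect_equal(success_probability(post, spec), oracle)
  }
})

test_that("widening any band never decreases success probability", {
  for (s in 1:25) {
    post <- make_posterior(log_g0 = runif(1, 1, 4), log_ginf = runif(1, 3, 5),
                           log_ec50 = runif(1, 1, 2.5), seed = 100 + s)
    base <- specification(ec50_target = 80, ec50_fold = 1.2,
                          ginf_target = 20000, ginf_fold = 1.1)
    wide_ec <- specification(ec50_target = 80, ec50_fold = 2,
                             ginf_target = 20000, ginf_fold = 1.1)
    wide_gi <- specification(ec50_target = 80, ec50_fold = 1.2,
                             ginf_target = 20000, ginf_fold = 1.6)
    p0 <- success_probability(post, base)
    expect_gte(success_probability(post, wide_ec), p0)
    expect_gte(success_probability(post, wide_gi), p0)
  }
})

test_that("preset specifications carry the standard criteria", {
  mo <- preset_specs("multiobjective", target_ec50 = 30, target_ginf = 16000)
  expect_equal(mo$ec50_fold, 1.2)
  expect_equal(c(mo$ec50_target / mo$ec50_fold, mo$ec50_target * mo$ec50_fold),
               c(25, 36))
  expect_equal(mo$ginf_fold, 1.1)
  expect_equal(mo$ginf_target * mo$ginf_fold, 17600)
  expect_equal(mo$g0_upper, 2000)
  inv <- preset_specs("inverted", target_ec50 = 100)
  expect_equal(c(100 / inv$ec50_fold, 100 * inv$ec50_fold),
               c(100 / 1.5, 150))
  expect_equal(inv$ginf_upper, 12500)
  expect_equal(c(inv$g0_lower, inv$g0_upper), c(19200, 32500))
  expect_equal(inv$phenotype, "inverted")
  expect_error(preset_specs("bandstop", 10), "unknown preset")
})

test_that("selection ranks a dominating variant first and respects top_k/min_prob", {
  set.seed(6)
  spec <- preset_specs("multiobjective", target_ec50 = 30, target_ginf = 16000)
  # background variants scattered; one variant planted dead-centre
  recs <- lapply(1:20, function(i)
    variant_record(genotype(sprintf("A%dV", i + 1)),
                   make_posterior(log_g0 = 2, log_ginf = runif(1, 3.5, 4.8),
                                  log_ec50 = runif(1, 0, 3), seed = 300 + i),
                   id = sprintf("v%05d", i)))
  recs[[21]] <- variant_record(genotype("V136E"),
                               make_posterior(log_g0 = 2, log_ginf = log10(16000),
                                              log_ec50 = log10(30), seed = 999),
                               id = "v00021")
  ls <- landscape(recs)
  sel <- select_variants(ls, spec, top_k = 3)
  expect_equal(sel$table$variant[1], "v00021")
  expect_true(all(diff(sel$table$probability) <= 0))   # non-increasing ranking
  # min_prob above every probability -> empty
  expect_equal(nrow(select_variants(ls, spec, min_prob = 1)$table), 0L)
  # top_k limits the returned count
  expect_lte(nrow(select_variants(ls, spec, top_k = 1)$table), 1L)
  expect_warning(select_variants(landscape(list()), spec), "empty landscape")
})

test_that("probability ties break toward fewer mutations then lexicographic genotype", {
  spec <- specification(g0_upper = 1e9)   # satisfied by every draw
  mk <- function(codes, id, seed)
    variant_record(genotype(codes), make_posterior(seed = seed), id = id)
  ls <- landscape(list(mk(c("A2V", "R5K"), "vdouble", 1),
                       mk("R5K", "vB", 2), mk("A2V", "vA", 3)))
  sel <- select_variants(ls, spec, top_k = 3)
  expect_equal(sel$table$probability, rep(1, 3))
  expect_equal(sel$table$variant, c("vA", "vB", "vdouble"))
})

test_that("the EC50 correction is applied to draws, keeping ranking coherent", {
  # posterior centred at 60; a compressive landscape bias maps 60 -> ~100
  cm <- structure(list(intercept = log(100) - 0.5 * log(60), slope = 0.5,
                       n = 10L), class = "ec50_correction")
  spec <- specification(ec50_target = 100, ec50_fold = 1.2)
  post <- make_posterior(log_ec50 = log10(60), sd = c(.05, .03, .01, .08),
                         seed = 44)
  expect_gt(success_probability(post, spec, correction = cm), 0.9)
  expect_lt(success_probability(post, spec), 0.05)
})

test_that("specification YAML files round-trip", {
  spec <- preset_specs("inverted", target_ec50 = 30)
  tmp <- tempfile(fileext = ".yaml")
  write_specification(spec, tmp)
  back <- read_specification(tmp)
  expect_equal(unclass(back), unclass(spec))
  expect_error(specification(), "at least one criterion")
  expect_error(specification(ec50_target = 10, ec50_fold = 0.5), ">= 1")
})
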