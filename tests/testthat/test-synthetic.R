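test_that("simulated libraries have Poisson missense counts at the stated mean", {
  gt <- simulate_library(10000, mean_missense = 4.4, seed = 2)
  counts <- vapply(gt[-1], length, 1L)        # first genotype is wild type
  se <- sqrt(4.4 / length(counts))
  expect_lt(abs(mean(counts) - 4.4), 3 * se)
  expect_equal(simulate_library(0), list())
  expect_error(simulate_library(10, mean_missense = 0), "mean_missense")
  # reproducibility
  expect_identical(lapply(simulate_library(50, seed = 5), unclass),
                   lapply(simulate_library(50, seed = 5), unclass))
})

test_that("the ligand grid is 12 points: zero plus a 2-fold dilution series", {
  g <- ligand_grid()
  expect_length(g, 12L)
  expect_equal(g[1], 0)
  expect_equal(max(g), 2048)
  expect_equal(unique(round(g[-1][-1] / g[-1][-11], 10)), 2)
  expect_equal(max(ligand_grid(top = 1024)), 1024)
})

test_that("wild type maps to the anchor and planted effects act through the MWC map", {
  vocab <- c("A2V", "R5K")
  # one mutation doubling K_A (z2 = -log(2)), one inert
  eff <- rbind(c(0, -log(2), 0), c(0, 0, 0))
  em <- effect_model(vocab, K = 3, effects = eff)
  gts <- list(genotype(character()), genotype("A2V"), genotype("R5K"))
  ls <- simulate_landscape(gts, em, facs_prescreen = FALSE, seed = 4)
  truth <- attr(ls, "truth")
  anchor <- biophys_to_hill(em$anchor)
  expect_equal(truth$ec50[1], anchor$ec50, tolerance = 1e-5)
  expect_equal(truth$g0[1], anchor$g0, tolerance = 1e-6)
  expect_equal(truth$ginf[1], anchor$ginf, tolerance = 1e-6)
  # construction oracle: the A2V truth equals the direct map at doubled K_A
  shifted <- biophys_params(K_A = em$anchor$K_A * 2, G_max = em$anchor$G_max,
                            R = em$anchor$R)
  expect_equal(truth$ec50[2], biophys_to_hill(shifted)$ec50, tolerance = 1e-5)
  expect_false(isTRUE(all.equal(truth$ec50[2], truth$ec50[1])))
  expect_equal(truth$ec50[3], truth$ec50[1], tolerance = 1e-6)  # inert
})

test_that("the FACS prescreen depletes inverted variants", {
  gt <- simulate_library(4000, seed = 13)
  em <- effect_model()
  on <- simulate_landscape(gt, em, facs_prescreen = TRUE, seed = 13)
  off <- simulate_landscape(gt, em, facs_prescreen = FALSE, seed = 13)
  expect_lt(mean(on$summary$inverted), mean(off$summary$inverted))
  # prescreened high-G0 survivors carry reduced quality
  expect_lt(min(on$summary$quality), 1)
})

test_that("synthetic landscapes reproduce the qualitative real-data structure", {
  gt <- simulate_library(4000, seed = 31)
  ls <- simulate_landscape(gt, seed = 31)
  s <- ls$summary
  expect_gt(log10(max(s$ec50) / min(s$ec50)), 3)     # >= 3 decades of EC50
  expect_gt(mean(!s$inverted), 0.9)                  # dense non-inverted mode
  expect_gt(sum(s$inverted), 0)                      # sparse inverted tail
  expect_lt(mean(s$inverted), 0.1)
})

test_that("generated posteriors are centred on the generator truth", {
  gt <- simulate_library(300, seed = 17)
  ls <- simulate_landscape(gt, seed = 17, facs_prescreen = FALSE)
  truth <- attr(ls, "truth")
  err <- log10(ls$summary$ec50) - log10(truth$ec50)
  expect_lt(abs(mean(err)), 0.02)            # unbiased
  expect_lt(sd(err), 0.05)                   # about the nominal width/sqrt(S)
})

test_that("raw curve tables round-trip and follow the schema", {
  curves <- simulate_curves(hill_params(200, 20000, 100, 1.5),
                            n_replicates = 2, seed = 8)
  expect_equal(nrow(curves), 24L)
  tmp <- tempfile(fileext = ".csv")
  write_curves(curves, tmp)
  back <- read_curves(tmp)
  expect_equal(back$geo_mean, curves$geo_mean, tolerance = 1e-10)
  expect_error(write_curves(curves[, -4], tmp), "missing columns")
})
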