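test_that("spectral library matches the analysis wavelength window", {
  lib <- spectral_library(1)
  expect_length(lib$wavelengths, 412)
  expect_equal(lib$wavelengths[1], 427.75)
  expect_equal(lib$wavelengths[412], 948.49)
  expect_true(all(diff(lib$wavelengths) > 0))
  expect_true(all(lib$baseline >= 0 & lib$baseline <= 1))
})

test_that("library encodes red-edge, pigment and water band structure", {
  lib <- spectral_library(1)
  b_at <- function(nm) lib$baseline[which.min(abs(lib$wavelengths - nm))]
  expect_lt(b_at(550), b_at(800))
  expect_true(lib$absorbers$water$center >= 940 &&
                lib$absorbers$water$center <= 960)
  for (a in c("chlorophyll_a", "chlorophyll_b"))
    expect_true(lib$absorbers[[a]]$center >= 430 &&
                  lib$absorbers[[a]]$center <= 690)
  # deterministic axis regardless of seed
  expect_identical(spectral_library(2)$wavelengths, lib$wavelengths)
  expect_identical(spectral_library(2)$absorbers, lib$absorbers)
  expect_false(identical(
    spectral_library(2, randomize_strengths = TRUE)$absorbers,
    spectral_library(3, randomize_strengths = TRUE)$absorbers))
})

test_that("zero absorbers and zero noise return the baseline exactly", {
  lib <- spectral_library(1)
  s <- simulate_spectrum(lib, 0, 0, scatter_mult = 1, scatter_add = 0,
                         noise_sd = 0)
  expect_equal(s$values, lib$baseline, tolerance = 1e-15)
  expect_error(simulate_spectrum(lib, 1, 1, noise_sd = -0.1), "noise_sd")
  expect_error(simulate_spectrum(lib, -1, 1), ">= 0")
})

test_that("pigment and water losses move reflectance the right way", {
  lib <- spectral_library(1)
  vis <- function(s) mean(s$values[s$wavelengths >= 550 &
                                     s$wavelengths <= 700])
  hi <- simulate_spectrum(lib, 2.0, 1.5)
  lo <- simulate_spectrum(lib, 0.5, 1.5)
  expect_gt(vis(lo), vis(hi))
  at950 <- function(s) s$values[length(s$values)]
  wet <- simulate_spectrum(lib, 1, 1.5)
  dry <- simulate_spectrum(lib, 1, 0.2)
  expect_gt(at950(dry), at950(wet))
})

test_that("same seed gives bit-identical spectra", {
  lib <- spectral_library(1)
  a <- simulate_spectrum(lib, 1, 1, noise_sd = 0.02, seed = 11)
  b <- simulate_spectrum(lib, 1, 1, noise_sd = 0.02, seed = 11)
  expect_identical(a, b)
})

test_that("stress monotonically raises visible and lowers NIR reflectance", {
  lib <- spectral_library(1)
  link <- link_params()
  shiks <- seq(10, 150, length.out = 10)
  lat <- shikimap:::latent_from_shikimate(shiks, link)
  sp <- lapply(seq_along(shiks), function(i)
    simulate_spectrum(lib, lat$pigment[i], lat$water[i], lat$structure[i]))
  vis <- vapply(sp, function(s)
    mean(s$values[s$wavelengths >= 550 & s$wavelengths <= 700]), numeric(1))
  nir <- vapply(sp, function(s)
    mean(s$values[s$wavelengths >= 900 & s$wavelengths <= 948.49]),
    numeric(1))
  expect_true(all(diff(vis) > 0))
  expect_true(all(diff(nir) < 0))
})

test_that("default design emits the study's replication counts", {
  sim <- simulate_experiment(design_spec(seed = 1))
  m <- sim$spectra$meta
  expect_equal(nrow(m), 240)
  expect_equal(sum(m$genotype == "WT"), 120)
  expect_equal(sum(m$genotype == "TG"), 120)
  counts <- table(m$genotype, m$day, m$treatment)
  expect_true(all(counts[, , "water"] == 10))
  expect_true(all(counts[, , "glyphosate"] == 20))
  expect_error(design_spec(n_water = 0, n_glyphosate = 0), "empty")
})

test_that("stressed WT shikimate dominates TG at late days", {
  sim <- simulate_experiment(design_spec(seed = 7))
  m <- sim$spectra$meta; y <- sim$spectra$y
  cell_mean <- function(g, t, d)
    mean(y[m$genotype == g & m$treatment == t & m$day == d])
  expect_gte(cell_mean("WT", "glyphosate", 8) /
               cell_mean("TG", "glyphosate", 8), 1.4)
  for (d in c(4, 6, 8)) {
    wt_g <- cell_mean("WT", "glyphosate", d)
    expect_gt(wt_g, cell_mean("TG", "glyphosate", d))
    expect_gt(wt_g, cell_mean("WT", "water", d))
  }
  expect_true(all(y > 0))
})

test_that("experiment generation is a pure function of its seed", {
  a <- simulate_experiment(design_spec(seed = 13))
  b <- simulate_experiment(design_spec(seed = 13))
  expect_identical(a$spectra$X, b$spectra$X)
  expect_identical(a$chlf$X, b$chlf$X)
  expect_identical(a$truth$shikimate, b$truth$shikimate)
  expect_false(identical(
    a$spectra$X, simulate_experiment(design_spec(seed = 14))$spectra$X))
})

test_that("zero link slopes remove the group difference in mean spectra", {
  sim <- simulate_experiment(design_spec(seed = 21),
                             link = null_link_params())
  m <- sim$spectra$meta
  stressed <- m$genotype == "WT" & m$treatment == "glyphosate"
  g1 <- rowMeans(sim$spectra$X[stressed, ])
  g2 <- rowMeans(sim$spectra$X[!stressed, ])
  # two-sample comparison of overall reflectance level: within MC error
  se <- sqrt(var(g1) / length(g1) + var(g2) / length(g2))
  expect_lt(abs(mean(g1) - mean(g2)), 4 * se + 1e-4)
  # and the ChlF panel carries no shikimate signal
  cors <- abs(cor(sim$chlf$X, sim$chlf$y))
  expect_lt(max(cors), 0.35)
})

test_that("ChlF panel has 60 parameters, 11 informative", {
  sim <- simulate_experiment(design_spec(seed = 2))
  expect_equal(ncol(sim$chlf$X), 60)
  expect_length(sim$truth$informative_chlf, 11)
  expect_true(all(c("QY_max", "NPQ_Lss", "qL_Lss", "qP_Lss", "QY_Lss") %in%
                    sim$truth$informative_chlf))
  expect_false(anyDuplicated(colnames(sim$chlf$X)) > 0)
})

test_that("cube generation honours heterogeneity and soil contrast", {
  lib <- spectral_library(1)
  flat <- simulate_cube(lib, 90, canopy_shape = c(16, 16),
                        pixel_heterogeneity_sd = 0, seed = 1)
  expect_true(all(flat$truth[flat$cube$mask] == 90))
  expect_true(all(is.na(flat$truth[!flat$cube$mask])))
  # background soil stays below the default segmentation ratio
  bg <- which(!flat$cube$mask, arr.ind = TRUE)[1, ]
  soil <- spectrum(lib$wavelengths, flat$cube$data[bg[1], bg[2], ])
  ratio <- soil$values[band_index(soil$wavelengths, 800)] /
    soil$values[band_index(soil$wavelengths, 670)]
  expect_lt(ratio, 2)
  expect_error(simulate_cube(lib, 90, canopy_shape = matrix(FALSE, 4, 4)),
               "empty")
})

test_that("sparse-band generator marks its informative bands", {
  d <- simulate_sparse_bands(seed = 5)
  expect_equal(dim(d$X), c(80, 50))
  fit <- lm(d$y ~ d$X[, d$informative])
  expect_gt(summary(fit)$r.squared, 0.9)
  d2 <- simulate_sparse_bands(seed = 5)
  expect_identical(d$X, d2$X)
})
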