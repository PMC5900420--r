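# Synthetic study generator.
#
# Emulates the glyphosate-tolerance screening design: two genotypes (WT,
# transgenic TG carrying an insensitive EPSPS), water vs glyphosate
# treatment, assessments at 2/4/6/8 days, canopy Vis-NIR reflectance
# spectra, a ~60-parameter chlorophyll fluorescence panel, and per-plant
# shikimic acid ground truth. Stress physiology is encoded through three
# latent channels that all decline as shikimate accumulates: pigment
# (visible absorption), leaf water (950 nm absorption) and canopy
# structure (a multiplicative NIR-dominant scatter term).

#' Experimental design specification
#'
#' @param genotypes genotype labels (default `c("WT", "TG")`).
#' @param days assessment days after treatment (default `c(2, 4, 6, 8)`).
#' @param n_water water-control replicates per genotype-day (default 10).
#' @param n_glyphosate glyphosate replicates per genotype-day (default 20).
#' @param seed integer RNG seed carried by the design.
#' @return An object of class `design_spec`. The default design yields
#'   120 plants per genotype (240 total).
#' @export
design_spec <- function(genotypes = c("WT", "TG"), days = c(2, 4, 6, 8),
                        n_water = 10, n_glyphosate = 20, seed = 1) {
  if (n_water < 0 || n_glyphosate < 0)
    stop("replicate counts must be non-negative")
  if (length(genotypes) == 0 || length(days) == 0 ||
      (n_water + n_glyphosate) == 0)
    stop("design is empty")
  structure(list(genotypes = genotypes, days = days, n_water = n_water,
                 n_glyphosate = n_glyphosate, seed = seed),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  total <- length(x$genotypes) * length(x$days) * (x$n_water + x$n_glyphosate)
  cat(sprintf("<design_spec> %s x days {%s}, %d water + %d glyphosate per cell, %d plants\n",
              paste(x$genotypes, collapse = "/"),
              paste(x$days, collapse = ","), x$n_water, x$n_glyphosate, total))
  invisible(x)
}

#' Spectral library for the generator
#'
#' Fixed 412-band wavelength axis spanning 427.75-948.49 nm, a smooth
#' healthy-canopy baseline reflectance template (dark visible region,
#' green bump near 550 nm, red edge near 700-750 nm, NIR plateau), and
#' Gaussian absorbance bands for chlorophyll a (675 nm), chlorophyll b
#' (455 nm) and leaf water (950 nm, the second O-H stretch overtone
#' region).
#'
#' @param seed integer seed (only consumed when `randomize_strengths`).
#' @param randomize_strengths if TRUE, jitters absorber strengths by ~5%.
#' @return An object of class `spectral_library` with elements
#'   `wavelengths`, `baseline`, `absorbers` (list of center/width/strength).
#' @export
spectral_library <- function(seed = 1, randomize_strengths = FALSE) {
  wl <- seq(427.75, 948.49, length.out = 412)
  baseline <- 0.08 +
    0.42 / (1 + exp(-(wl - 715) / 18)) +         # red edge to NIR plateau
    0.06 * exp(-((wl - 550)^2) / (2 * 40^2))     # green reflectance bump
  absorbers <- list(
    chlorophyll_a = list(center = 675, width = 45, strength = 0.60),
    chlorophyll_b = list(center = 455, width = 35, strength = 0.40),
    water         = list(center = 950, width = 35, strength = 0.15))
  if (randomize_strengths) {
    absorbers <- with_seed(seed, lapply(absorbers, function(a) {
      a$strength <- a$strength * exp(stats::rnorm(1, 0, 0.05))
      a
    }))
  }
  structure(list(wavelengths = wl, baseline = baseline,
                 absorbers = absorbers),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d bands %.2f-%.2f nm, absorbers: %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              paste(names(x$absorbers), collapse = ", ")))
  invisible(x)
}

# unit-height Gaussian absorbance profile on the library axis
absorber_profile <- function(lib, which) {
  a <- lib$absorbers[[which]]
  a$strength * exp(-((lib$wavelengths - a$center)^2) / (2 * a$width^2))
}

pigment_profile <- function(lib)
  absorber_profile(lib, "chlorophyll_a") + absorber_profile(lib, "chlorophyll_b")

water_profile <- function(lib) absorber_profile(lib, "water")

#' Simulate one canopy reflectance spectrum
#'
#' Beer-Lambert-style generative model on the library baseline:
#' `r = scatter_mult * baseline * exp(-(pigment * g_chl + water * g_w)) +
#' scatter_add + noise`, clipped to \[0, 1.2\]. `g_chl` is the summed
#' chlorophyll a+b absorbance profile and `g_w` the water profile. Lower
#' pigment raises visible (550-700 nm) reflectance; lower water raises the
#' 950 nm band shoulder.
#'
#' @param lib a [spectral_library()].
#' @param pigment,water non-negative latent absorber amounts.
#' @param scatter_mult,scatter_add multiplicative / additive scatter terms.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(lib, pigment, water, scatter_mult = 1,
                              scatter_add = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(lib, "spectral_library"))
  if (pigment < 0 || water < 0) stop("pigment and water must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  absorbance <- pigment * pigment_profile(lib) + water * water_profile(lib)
  r <- scatter_mult * lib$baseline * exp(-absorbance) + scatter_add
  if (noise_sd > 0)
    r <- r + with_seed(seed, stats::rnorm(length(r), 0, noise_sd))
  spectrum(lib$wavelengths, pmin(pmax(r, 0), 1.2))
}

#' Stress-to-spectrum / stress-to-fluorescence link parameters
#'
#' The effect sizes tying shikimic acid concentration (arbitrary
#' fresh-weight units; healthy ~25, stressed WT up to ~150) to the three
#' latent spectral channels and to the informative chlorophyll
#' fluorescence parameters. `null_link_params()` returns the same
#' structure with every slope zeroed, the no-signal control condition.
#'
#' @param pigment_per_shik pigment lost per unit shikimate.
#' @param water_per_shik water lost per unit shikimate.
#' @param structure_per_shik scatter multiplier lost per unit shikimate.
#' @param shik_base,shik_day_slope WT-glyphosate shikimate kinetics:
#'   mean concentration `shik_base + shik_day_slope * day`.
#' @param healthy_mean,healthy_sd shikimate distribution for TG plants and
#'   water controls.
#' @param shik_noise_sd per-plant shikimate spread around the WT kinetic
#'   mean.
#' @param chlf_slope_scale multiplier on all informative ChlF slopes
#'   (1 = default effects, 0 = null).
#' @return A list of class `link_params`.
#' @export
link_params <- function(pigment_per_shik = 0.012,
                        water_per_shik = 0.006,
                        structure_per_shik = 0.0015,
                        shik_base = 20, shik_day_slope = 15,
                        healthy_mean = 25, healthy_sd = 6,
                        shik_noise_sd = 10,
                        chlf_slope_scale = 1) {
  structure(list(pigment0 = 2.0, pigment_per_shik = pigment_per_shik,
                 water0 = 1.5, water_per_shik = water_per_shik,
                 structure0 = 1.05, structure_per_shik = structure_per_shik,
                 shik_base = shik_base, shik_day_slope = shik_day_slope,
                 healthy_mean = healthy_mean, healthy_sd = healthy_sd,
                 shik_noise_sd = shik_noise_sd,
                 chlf_slope_scale = chlf_slope_scale),
            class = "link_params")
}

#' @rdname link_params
#' @export
null_link_params <- function() {
  link_params(pigment_per_shik = 0, water_per_shik = 0,
              structure_per_shik = 0, chlf_slope_scale = 0)
}

#' Noise model for the generator
#'
#' Standard deviations of the latent-link noise (pigment, water,
#' structure), the additive spectral noise, and the additive scatter
#' offset spread. The link-noise magnitudes set the best achievable
#' prediction error of the study: they are calibrated so an ideal
#' regression bottoms out at an RMSE of roughly 8-13 shikimate units.
#'
#' @param pigment_sd,water_sd,structure_sd latent link noise.
#' @param spectral_sd additive per-band reflectance noise.
#' @param scatter_add_sd per-plant additive scatter offset spread.
#' @param chlf_shared_sd shared plant-level physiological noise on the
#'   informative ChlF parameters, in shikimate-equivalent units: all
#'   informative parameters read the same noisy physiological state
#'   `shik + u`, so this noise does not average away across parameters
#'   and sets the irreducible RMSE floor of fluorescence-based
#'   calibration (default 9).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(pigment_sd = 0.13, water_sd = 0.09,
                         structure_sd = 0.02, spectral_sd = 0.004,
                         scatter_add_sd = 0.002, chlf_shared_sd = 9) {
  structure(list(pigment_sd = pigment_sd, water_sd = water_sd,
                 structure_sd = structure_sd, spectral_sd = spectral_sd,
                 scatter_add_sd = scatter_add_sd,
                 chlf_shared_sd = chlf_shared_sd),
            class = "noise_params")
}

# deterministic part of the latent links (floors keep absorbances physical)
latent_from_shikimate <- function(shik, link) {
  list(pigment = pmax(link$pigment0 - link$pigment_per_shik * shik, 0.05),
       water = pmax(link$water0 - link$water_per_shik * shik, 0.05),
       structure = pmax(link$structure0 - link$structure_per_shik * shik, 0.3))
}

# 60-parameter FluorCam-style panel; first 11 are informative
chlf_panel <- function() {
  informative <- data.frame(
    name = c("QY_max", "NPQ_Lss", "qL_Lss", "qP_Lss", "QY_Lss", "NPQ_L5",
             "QY_L5", "Rfd_Lss", "Fv", "qN_Lss", "Fm_Lss"),
    base = c(0.78, 0.80, 0.55, 0.70, 0.62, 0.90, 0.60, 2.5, 550, 0.45, 420),
    slope = c(-0.0012, 0.004, -0.0015, -0.0018, -0.0016, 0.0035,
              -0.0015, -0.008, -1.2, 0.002, -0.9),
    sd = c(0.015, 0.05, 0.02, 0.025, 0.02, 0.05, 0.02, 0.10, 18, 0.03, 14),
    stringsAsFactors = FALSE)
  noise_names <- c(
    "Fo", "Fm", "Ft_Lss", "Fo_Lss", "Fv_Lss",
    paste0("Fm_L", 1:5), paste0("NPQ_L", 1:4), paste0("qL_L", 1:5),
    paste0("qP_L", 1:5), paste0("QY_L", 1:4), paste0("Rfd_L", 1:5),
    paste0("qN_L", 1:5), paste0("Fm_D", 1:3), paste0("NPQ_D", 1:3),
    paste0("QY_D", 1:3), "Fp", "Area")
  base_for <- function(nm) {
    if (grepl("^(Fo|Fm|Ft|Fv|Fp)", nm)) 400
    else if (grepl("^NPQ", nm)) 0.8
    else if (grepl("^Rfd", nm)) 2.4
    else if (grepl("^Area", nm)) 1000
    else 0.6
  }
  sd_for <- function(nm) {
    if (grepl("^(Fo|Fm|Ft|Fv|Fp)", nm)) 30
    else if (grepl("^NPQ", nm)) 0.08
    else if (grepl("^Rfd", nm)) 0.15
    else if (grepl("^Area", nm)) 100
    else 0.05
  }
  noise <- data.frame(name = noise_names,
                      base = vapply(noise_names, base_for, numeric(1)),
                      slope = 0,
                      sd = vapply(noise_names, sd_for, numeric(1)),
                      stringsAsFactors = FALSE)
  rbind(informative, noise)
}

#' Simulate the full glyphosate-tolerance experiment
#'
#' Draws per-plant shikimic acid ground truth (WT-glyphosate rises
#' linearly with day; TG plants and water controls stay at a low constant
#' mean), maps it through the latent links to pigment/water/structure,
#' generates a canopy mean spectrum per plant via [simulate_spectrum()],
#' and generates the 60-parameter ChlF table of which 11 parameters are
#' affine in shikimate and the rest pure noise. Row order is randomized
#' under the design seed.
#'
#' @param design a [design_spec()].
#' @param lib a [spectral_library()].
#' @param link a [link_params()].
#' @param noise a [noise_params()].
#' @return A list with elements `spectra` ([sample_table()], 412 bands),
#'   `chlf` ([sample_table()], 60 parameters), and `truth` (list with
#'   `shikimate`, `latent_pigment`, `latent_water`, `latent_structure`,
#'   `informative_bands`, `informative_chlf`).
#' @export
simulate_experiment <- function(design, lib = spectral_library(design$seed),
                                link = link_params(),
                                noise = noise_params()) {
  stopifnot(inherits(design, "design_spec"))
  cells <- expand.grid(genotype = design$genotypes, day = design$days,
                       treatment = c("water", "glyphosate"),
                       stringsAsFactors = FALSE)
  cells$n <- ifelse(cells$treatment == "water", design$n_water,
                    design$n_glyphosate)
  cells <- cells[cells$n > 0, , drop = FALSE]
  meta <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(
      plant_id = sprintf("%s_%s_d%d_r%02d", genotype, substr(treatment, 1, 3),
                         day, seq_len(n)),
      genotype = genotype, treatment = treatment, day = day,
      stringsAsFactors = FALSE))
  }))
  n <- nrow(meta)

  with_seed(design$seed, {
    stressed <- meta$genotype == "WT" & meta$treatment == "glyphosate"
    shik <- ifelse(stressed,
                   link$shik_base + link$shik_day_slope * meta$day +
                     stats::rnorm(n, 0, link$shik_noise_sd),
                   stats::rnorm(n, link$healthy_mean, link$healthy_sd))
    shik <- pmax(shik, 1)

    lat <- latent_from_shikimate(shik, link)
    pigment <- pmax(lat$pigment + stats::rnorm(n, 0, noise$pigment_sd), 0.05)
    water <- pmax(lat$water + stats::rnorm(n, 0, noise$water_sd), 0.05)
    struct <- pmax(lat$structure + stats::rnorm(n, 0, noise$structure_sd), 0.3)
    offs <- stats::rnorm(n, 0, noise$scatter_add_sd)

    X <- t(vapply(seq_len(n), function(i)
      simulate_spectrum(lib, pigment[i], water[i], struct[i], offs[i],
                        noise$spectral_sd)$values,
      numeric(length(lib$wavelengths))))
    colnames(X) <- sprintf("%.2f", lib$wavelengths)

    panel <- chlf_panel()
    u <- stats::rnorm(n, 0, noise$chlf_shared_sd)  # shared physiological state
    C <- vapply(seq_len(nrow(panel)), function(j)
      panel$base[j] + link$chlf_slope_scale * panel$slope[j] * (shik + u) +
        stats::rnorm(n, 0, panel$sd[j]),
      numeric(n))
    colnames(C) <- panel$name

    ord <- sample.int(n)
    meta <- meta[ord, , drop = FALSE]
    rownames(meta) <- NULL
    X <- X[ord, , drop = FALSE]
    C <- C[ord, , drop = FALSE]
    shik <- shik[ord]; pigment <- pigment[ord]; water <- water[ord]
    struct <- struct[ord]

    sens <- link$pigment_per_shik * pigment_profile(lib) +
      link$water_per_shik * water_profile(lib)
    informative_bands <- if (max(sens) > 0)
      which(sens > 0.5 * max(sens)) else integer(0)

    list(spectra = sample_table(X, y = shik, meta = meta),
         chlf = sample_table(C, y = shik, meta = meta),
         truth = list(shikimate = shik, latent_pigment = pigment,
                      latent_water = water, latent_structure = struct,
                      informative_bands = informative_bands,
                      informative_chlf = panel$name[panel$slope != 0]))
  })
}

#' Simulate a sparse band-signal table
#'
#' Small ground-truth construction for wavelength-selection power
#' studies, mimicking the collinearity structure of contiguous spectral
#' bands: the uninformative bands are linear mixtures of a handful of
#' shared background factors (mutually highly collinear, as neighbouring
#' wavelengths are), while each informative band is driven by its own
#' independent latent factor plus band noise. The response is
#' `y = latents %*% beta + noise`. Because the informative bands carry
#' the only directions that survive orthogonal projection against the
#' redundant background, this is exactly the regime the successive
#' projections algorithm is designed for.
#'
#' @param n samples.
#' @param p number of bands.
#' @param informative indices of the signal-carrying bands.
#' @param beta response loading of each informative latent factor.
#' @param n_background number of shared background factors (default 3).
#' @param band_noise_sd idiosyncratic noise on every band (default 0.1).
#' @param noise_sd response noise standard deviation.
#' @param seed integer seed.
#' @return list with `X`, `y`, `informative`.
#' @export
simulate_sparse_bands <- function(n = 80, p = 50,
                                  informative = c(5, 15, 25, 35, 45),
                                  beta = c(1.5, -1.2, 1.0, 0.8, -1.0),
                                  n_background = 3, band_noise_sd = 0.1,
                                  noise_sd = 0.3, seed = 1) {
  stopifnot(length(informative) == length(beta), max(informative) <= p)
  with_seed(seed, {
    k <- length(informative)
    L <- matrix(stats::rnorm(n * k), n, k)
    B <- matrix(stats::rnorm(n * n_background), n, n_background)
    W <- matrix(stats::rnorm(n_background * p), n_background, p)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    X <- B %*% W + matrix(stats::rnorm(n * p, 0, band_noise_sd), n, p)
    X[, informative] <- L +
      matrix(stats::rnorm(n * k, 0, band_noise_sd), n, k)
    colnames(X) <- paste0("b", seq_len(p))
    y <- as.numeric(L %*% beta + stats::rnorm(n, 0, noise_sd))
    list(X = X, y = y, informative = informative)
  })
}

# flat soil/conveyor background template: weak, nearly wavelength-flat
soil_spectrum <- function(lib) {
  0.15 + 0.00012 * (lib$wavelengths - 400)
}

# default plant-like canopy mask: a rosette of three overlapping ellipses
default_canopy_mask <- function(rows = 48, cols = 48) {
  rc <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  inside <- function(ry, rx, ang) {
    dy <- rc$r - cy; dx <- rc$c - cx
    u <- cos(ang) * dx + sin(ang) * dy
    v <- -sin(ang) * dx + cos(ang) * dy
    (u / rx)^2 + (v / ry)^2 <= 1
  }
  m <- inside(rows * 0.18, cols * 0.42, 0) |
    inside(rows * 0.42, cols * 0.18, 0) |
    inside(rows * 0.30, cols * 0.30, pi / 4)
  matrix(m, rows, cols)
}

#' Simulate a hyperspectral cube for one plant
#'
#' Foreground pixels carry spectra generated from per-pixel shikimate
#' concentrations (`plant_shikimate` plus spatial Gaussian heterogeneity)
#' pushed through the deterministic latent links; background pixels carry
#' a flat soil template whose NIR/red ratio stays below the default
#' segmentation threshold. The aligned per-pixel concentration truth map
#' is returned with the cube.
#'
#' @param lib a [spectral_library()].
#' @param plant_shikimate scalar plant-level concentration.
#' @param canopy_shape logical foreground matrix, or `c(rows, cols)` to use
#'   the built-in rosette mask.
#' @param pixel_heterogeneity_sd spatial concentration noise sd.
#' @param noise_sd per-band reflectance noise sd.
#' @param link a [link_params()].
#' @param seed integer seed.
#' @return list with `cube` (a [hypercube()] carrying the truth mask) and
#'   `truth` (rows x cols concentration matrix, NA outside the canopy).
#' @export
simulate_cube <- function(lib, plant_shikimate, canopy_shape = c(48, 48),
                          pixel_heterogeneity_sd = 5, noise_sd = 0,
                          link = link_params(), seed = 1) {
  stopifnot(inherits(lib, "spectral_library"))
  mask <- if (is.matrix(canopy_shape)) {
    storage.mode(canopy_shape) <- "logical"
    canopy_shape
  } else default_canopy_mask(canopy_shape[1], canopy_shape[2])
  if (!any(mask)) stop("canopy mask is empty")
  rows <- nrow(mask); cols <- ncol(mask)
  nb <- length(lib$wavelengths)
  npx <- sum(mask)

  with_seed(seed, {
    conc <- pmax(plant_shikimate +
                   stats::rnorm(npx, 0, pixel_heterogeneity_sd), 0.1)
    lat <- latent_from_shikimate(conc, link)
    absorb <- outer(lat$pigment, pigment_profile(lib)) +
      outer(lat$water, water_profile(lib))
    fg <- (lat$structure * exp(-absorb)) *
      matrix(lib$baseline, npx, nb, byrow = TRUE)
    if (noise_sd > 0)
      fg <- fg + matrix(stats::rnorm(npx * nb, 0, noise_sd), npx, nb)
    fg <- pmin(pmax(fg, 0), 1.2)

    arr <- array(rep(soil_spectrum(lib), each = rows * cols),
                 c(rows, cols, nb))
    flat <- matrix(arr, rows * cols, nb)
    flat[as.vector(mask), ] <- fg
    arr <- array(flat, c(rows, cols, nb))

    truth <- matrix(NA_real_, rows, cols)
    truth[mask] <- conc
    list(cube = hypercube(arr, lib$wavelengths, mask), truth = truth)
  })
}
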