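test_that("preprocessing removes baseline without destroying peak area", {
  mz <- seq(5000, 6000, by = 0.5)

  # constant spectrum is pure baseline
  flat <- liga_spectrum(mz, rep(7, length(mz)))
  expect_true(all(preprocess_spectrum(flat)$intensity < 1e-9))

  # Gaussian on a linear ramp: area recovered within 2%
  true_area <- 900
  y <- true_area * dnorm(mz, 5500, 3) + 0.001 * (mz - 5000) + 0.2
  sp <- preprocess_spectrum(liga_spectrum(mz, y), baseline_window = 150)
  fit <- fit_peaks(sp, list(species_model("pk", 5500)), tolerance = 40)
  expect_lt(abs(fit$area - true_area) / true_area, 0.02)

  # near-idempotence
  sp2 <- preprocess_spectrum(sp, baseline_window = 150)
  expect_lt(max(abs(sp2$intensity - sp$intensity)), 0.01 * max(sp$intensity))

  expect_error(preprocess_spectrum(flat, baseline_window = 5000), "span")
  expect_error(liga_spectrum(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
  expect_error(liga_spectrum(c(1, 2), c(0, NA)), "non-finite")
})

test_that("species mass prediction adds residue masses and ghost satellites", {
  m <- maldi_masses()
  base_plus <- m[["pviii"]] + m[["dbco"]] + m[["linker"]]

  g <- glycan_structure("A2G2", composition = c(Hex = 5, HexNAc = 4))
  sp <- predict_species_masses(glycan = g)
  nm <- vapply(sp, `[[`, character(1), "name")
  conj <- sp[[match("A2G2", nm)]]
  expect_equal(conj$expected_mass, base_plus + 5 * 162.0528 + 4 * 203.0794)

  # empty composition: conjugate = base + adducts only
  g0 <- glycan_structure("bare")
  sp0 <- predict_species_masses(glycan = g0)
  conj0 <- sp0[[match("bare", vapply(sp0, `[[`, character(1), "name"))]]
  expect_equal(conj0$expected_mass, base_plus)

  # disialylated species emit two ghost companions at -291.10 and -582.19
  gs <- glycan_structure("A2G2S2", composition = c(Hex = 5, HexNAc = 4, Neu5Ac = 2))
  sps <- predict_species_masses(glycan = gs)
  nms <- vapply(sps, `[[`, character(1), "name")
  expect_true(all(c("A2G2S2_ghost1", "A2G2S2_ghost2") %in% nms))
  parent <- sps[[match("A2G2S2", nms)]]
  g1 <- sps[[match("A2G2S2_ghost1", nms)]]
  g2 <- sps[[match("A2G2S2_ghost2", nms)]]
  expect_equal(parent$expected_mass - g1$expected_mass, 291.0954)
  expect_equal(parent$expected_mass - g2$expected_mass, 582.1908)
  expect_equal(g1$ghost_parent, "A2G2S2")

  expect_error(predict_species_masses(glycan = list(structure_id = "x",
                                                    composition = c(Xyl = 1))),
               "unknown monosaccharide")
})

test_that("Gaussian peak fitting recovers synthetic truth", {
  mz <- seq(5000, 5500, by = 0.25)
  set.seed(9)

  # single peak: area within 1%, center within 0.1 Da
  y <- 1000 * dnorm(mz, 5238, 3) + rnorm(length(mz), 0, 0.05)
  sp <- liga_spectrum(mz, pmax(y, 0))
  fit <- fit_peaks(sp, list(species_model("pviii", 5238, "pviii")))
  expect_lt(abs(fit$area - 1000) / 1000, 0.01)
  expect_lt(abs(fit$center - 5238), 0.1)

  # pure noise: everything below the detection threshold, all areas 0
  noise <- liga_spectrum(mz, abs(rnorm(length(mz), 0, 0.05)))
  fit0 <- fit_peaks(noise, list(species_model("pviii", 5238, "pviii")))
  expect_equal(fit0$area, 0)

  # two overlapping Gaussians 8 Da apart: joint fit recovers both within 5%
  y2 <- 800 * dnorm(mz, 5230, 3) + 500 * dnorm(mz, 5238, 3) +
    rnorm(length(mz), 0, 0.05)
  sp2 <- liga_spectrum(mz, pmax(y2, 0))
  fit2 <- fit_peaks(sp2, list(species_model("a", 5230), species_model("b", 5238)),
                    tolerance = 6)
  expect_lt(abs(fit2$area[fit2$species == "a"] - 800) / 800, 0.05)
  expect_lt(abs(fit2$area[fit2$species == "b"] - 500) / 500, 0.05)

  # area conservation: fitted area cannot exceed the intensity mass in-window
  win_mass <- sum(sp$intensity[abs(sp$mz - 5238) <= 40]) * 0.25
  expect_lte(fit$area, win_mass * 1.05)

  expect_error(fit_peaks(sp, list(species_model("far", 9000))), "outside")
})

test_that("ghost correction reattributes but conserves area", {
  fits <- data.frame(species = c("parent", "parent_ghost1"),
                     class = c("conjugate", "conjugate"),
                     ghost_parent = c(NA, "parent"),
                     center = c(7000, 6708.9), sigma = c(3, 3),
                     amplitude = c(1, 1), area = c(70, 30), residual = NA)
  class(fits) <- c("peak_fit", "data.frame")

  fr_on <- quantify_species(fits, ghost_correct = TRUE)
  expect_equal(unname(fr_on["parent"]), 1)
  expect_equal(unname(fr_on["parent_ghost1"]), 0)

  fr_off <- quantify_species(fits, ghost_correct = FALSE)
  expect_equal(unname(fr_off), c(0.7, 0.3))

  expect_equal(sum(fr_on), 1)
  expect_equal(sum(fr_off), 1)

  single <- fits[1, ]; class(single) <- class(fits)
  expect_equal(unname(quantify_species(single)), 1)

  zero <- fits; zero$area <- 0
  expect_error(quantify_species(zero), "zero")
})

test_that("density estimation converts modified fraction to glycans/virion", {
  species <- predict_species_masses()[1:2]  # pviii + dbco_pviii
  # 4:1 unmodified:conjugated -> fraction 0.2 -> 540 glycans/virion
  de <- estimate_density(c(pviii = 0.8, dbco_pviii = 0.2), species)
  expect_equal(de$modified_fraction, 0.2)
  expect_equal(de$mean_density, 540)

  expect_equal(estimate_density(c(pviii = 1, dbco_pviii = 0), species)$mean_density, 0)

  f <- 750 / 2700
  expect_equal(estimate_density(c(pviii = 1 - f, dbco_pviii = f), species)$mean_density, 750)

  expect_error(estimate_density(c(pviii = 0.7, dbco_pviii = 0.2), species), "sum to 1")
  expect_error(estimate_density(c(pviii = 1.2, dbco_pviii = -0.2), species), "negative")
})

test_that("density recovery improves with SNR and is tight at SNR 100", {
  species <- predict_species_masses()[1:2]
  masses <- c(pviii = species[[1]]$expected_mass,
              dbco_pviii = species[[2]]$expected_mass)
  true_density <- 750
  f <- true_density / 2700

  err_at_snr <- function(snr) {
    errs <- vapply(1:4, function(s) {
      sim <- simulate_spectrum(c(pviii = 1 - f, dbco_pviii = f), masses,
                               sigma = 3, noise_sd = 1 / snr,
                               baseline = c(0.02, 5e-5),
                               mz_range = c(4900, 5900), seed = 100 + s)
      sp <- preprocess_spectrum(sim$spectrum)
      fit <- fit_peaks(sp, species, snr_threshold = 3)
      de <- estimate_density(quantify_species(fit), species)
      abs(de$mean_density - true_density)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(5, 20, 100), err_at_snr, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lte(errs[3], 25)
})

test_that("conversion time courses track species percentages", {
  masses <- c(S2 = 7000, I1 = 6800, P1 = 6600)
  smod <- list(species_model("S2", 7000), species_model("I1", 6800),
               species_model("P1", 6600))
  k1 <- 1.2; k2 <- 0.6  # sequential first-order S -> I -> P
  frac_at <- function(t) {
    S <- exp(-k1 * t)
    I <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
    P <- max(1 - S - I, 0)
    c(S2 = S, I1 = I, P1 = P) / (S + I + P)
  }
  times <- c(0.25, 1, 2, 4, 8)
  specs <- lapply(times, function(t) {
    s <- simulate_spectrum(frac_at(t), masses, sigma = 3, noise_sd = 0.002,
                           mz_range = c(6300, 7300), seed = round(100 * t))$spectrum
    s$time <- t
    s
  })
  tc <- conversion_timecourse(specs, smod)
  expect_equal(tc$time, times)
  expect_equal(rowSums(tc[, c("S2", "I1", "P1")]), rep(100, 5), tolerance = 1e-6)
  truth <- t(vapply(times, frac_at, numeric(3))) * 100
  expect_lt(max(abs(truth - as.matrix(tc[, c("S2", "I1", "P1")]))), 3)

  # single species at all times -> 100% throughout
  one <- lapply(1:3, function(t) {
    s <- simulate_spectrum(c(P1 = 1), masses["P1"], noise_sd = 0.002,
                           mz_range = c(6300, 7300), seed = t)$spectrum
    s$time <- t
    s
  })
  tc1 <- conversion_timecourse(one, smod[3])
  expect_equal(tc1$P1, rep(100, 3))

  bad <- specs; bad[[2]]$time <- 0.1
  expect_error(conversion_timecourse(bad, smod), "strictly increasing")
  expect_error(conversion_timecourse(specs[1], smod), "two timepoints")
})

test_that("spectrum text files round-trip through the two-column dialect", {
  mz <- seq(5000, 5100, by = 0.5)
  sp <- liga_spectrum(mz, abs(sin(mz / 10)))
  f <- tempfile(fileext = ".txt")
  write_spectrum(sp, f)
  # '#' comments are skipped
  body <- readLines(f)
  writeLines(c("# instrument: synthetic", body), f)
  sp2 <- read_spectrum(f)
  expect_equal(sp2$mz, sp$mz)
  expect_equal(sp2$intensity, sp$intensity, tolerance = 1e-6)
})
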