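test_that("generators are deterministic in their seed and restore RNG state", {
  d <- fixture_dict()
  set.seed(99); before <- runif(1)  # fix external RNG state
  set.seed(99)
  a <- simulate_counts(d, seed = 5)
  after <- runif(1)
  expect_equal(after, before)  # generator did not consume the caller's stream

  b <- simulate_counts(d, seed = 5)
  expect_identical(unclass(a$counts), unclass(b$counts))
  c2 <- simulate_counts(d, seed = 6)
  expect_false(identical(unclass(a$counts), unclass(c2$counts)))

  des <- amplicon_design()
  f1 <- simulate_fastq(d, des, c(s = 50), seed = 3, dir = tempfile())
  f2 <- simulate_fastq(d, des, c(s = 50), seed = 3, dir = tempfile())
  expect_identical(readLines(f1$r1[["s"]]), readLines(f2$r1[["s"]]))

  s1 <- simulate_spectrum(c(a = 1), c(a = 5238), mz_range = c(5000, 5500), seed = 2)
  s2 <- simulate_spectrum(c(a = 1), c(a = 5238), mz_range = c(5000, 5500), seed = 2)
  expect_identical(s1$spectrum$intensity, s2$spectrum$intensity)

  t1 <- simulate_titration(5, 75, c(1, 10, 100), noise_sd = 0.1, seed = 4)
  t2 <- simulate_titration(5, 75, c(1, 10, 100), noise_sd = 0.1, seed = 4)
  expect_identical(t1$series$points$R, t2$series$points$R)
  expect_error(simulate_counts(d), "seed")
})

test_that("count simulation obeys its distributional contract", {
  d <- fixture_dict()

  # dispersion 0 is the Poisson limit: variance tracks the mean
  reps <- vapply(1:40, function(s) {
    sc <- simulate_counts(d, n_test = 1, n_control = 0, dispersion = 0,
                          baseline_meanlog = log(200), baseline_sdlog = 0,
                          libsize_range = c(1, 1), seed = s)
    unclass(sc$counts)[1:10, 1]
  }, numeric(10))
  ratio <- apply(reps, 1, var) / apply(reps, 1, mean)
  expect_lt(abs(mean(ratio) - 1), 0.35)

  # invariant clones always carry fold change 1
  fc <- setNames(rep(8, 3), glycan_ids(d)[1:3])
  sc <- simulate_counts(d, fc_map = fc, seed = 2)
  expect_true(all(sc$truth$fc[invariant_ids(d)] == 1))
  expect_equal(unname(sc$truth$fc[names(fc)]), rep(8, 3))
  expect_error(simulate_counts(d, fc_map = c(bogus = 2), seed = 1), "not in dictionary")

  # null fold changes: the test/control comparison is calibrated
  pvals <- vapply(1:100, function(s) {
    sc0 <- simulate_counts(d, dispersion = 0.1, seed = 1000 + s)
    m <- unclass(sc0$counts)[1, ]
    suppressWarnings(wilcox.test(m[1:3], m[4:6])$p.value)
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.08)
})

test_that("read simulation respects its geometry and error model", {
  d <- fixture_dict()
  des <- amplicon_design()
  sim <- simulate_fastq(d, des, c(s = 40), error_rate = 0, seed = 7,
                        dir = tempfile())
  reads <- readLines(sim$r1[["s"]])
  seqs <- reads[seq(2, length(reads), by = 4)]
  expect_true(all(nchar(seqs) == 75))
  expect_true(all(grepl(des$upstream1, seqs, fixed = TRUE)))
  expect_equal(sum(sim$truth$counts), 40)

  # zero reads: a valid empty FASTQ
  sim0 <- simulate_fastq(d, des, c(s = 0), seed = 1, dir = tempfile())
  expect_length(readLines(sim0$r1[["s"]]), 0)
  cm0 <- count_reads(sim0$r1, des, d)
  expect_equal(attr(cm0, "totals")$total, 0)

  expect_error(simulate_fastq(d, des, c(s = 10), error_rate = 0.5, seed = 1),
               "error_rate")
})

test_that("spectrum simulation round-trips through quantification", {
  masses <- c(A = 6000, B = 6500)
  # no ghosts, no suppression, no noise: fractions recovered within 1%
  sim <- simulate_spectrum(c(A = 0.6, B = 0.4), masses, noise_sd = 0,
                           mz_range = c(5700, 6800), seed = 1)
  fits <- fit_peaks(sim$spectrum,
                    list(species_model("A", 6000), species_model("B", 6500)),
                    noise = 1e-9)
  fr <- quantify_species(fits)
  expect_lt(max(abs(fr - c(A = 0.6, B = 0.4))), 0.01)

  # ghost_fraction 0.3: corrected fractions match truth, uncorrected parent
  # is low by ~30% of its area
  gm <- c(P = 7000)
  simg <- simulate_spectrum(c(P = 1), gm, sialic_counts = c(P = 1),
                            ghost_fraction = 0.3, noise_sd = 0,
                            mz_range = c(6500, 7300), seed = 2)
  smod <- list(species_model("P", 7000, sialic_count = 1),
               species_model("P_ghost1", 7000 - 291.0954,
                             ghost_parent = "P"))
  fitg <- fit_peaks(simg$spectrum, smod, noise = 1e-9)
  expect_equal(unname(quantify_species(fitg, TRUE)["P"]), 1, tolerance = 0.01)
  expect_equal(unname(quantify_species(fitg, FALSE)["P"]), 0.7, tolerance = 0.02)

  # fractions must sum to one
  expect_error(simulate_spectrum(c(A = 0.6, B = 0.3), masses, seed = 1),
               "sum to 1")
})

test_that("titration simulation inverts the isotherm", {
  # noiseless: fit_kd is a fixed point
  sim <- simulate_titration(5, 20, c(0.5, 2, 8, 32, 128), noise_sd = 0, seed = 1)
  expect_equal(fit_kd(sim$series)$Kd, 20, tolerance = 1e-4)

  # no-binding limit: Kd far above the ligand range
  weak <- simulate_titration(5, 1e6, c(1, 10, 100), noise_sd = 0, seed = 1)
  expect_true(all(weak$series$points$R < 1e-3))

  # saturated points (f = 1) are clipped with a warning
  expect_warning(simulate_titration(5, 0, c(20, 50, 100), seed = 1), "clipped")
})
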