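test_that("invariant-set normalization recovers sample scale factors", {
  d <- tiny_dict()
  inv <- "e3"
  # two identical samples -> factors (1, 1)
  mat <- cbind(A = c(e1 = 100L, e2 = 50L, e3 = 200L),
               B = c(e1 = 100L, e2 = 50L, e3 = 200L))
  nf <- normalize_counts(mat, "invariant_set", invariant_ids = inv)
  expect_equal(unname(nf$size_factors), c(1, 1))
  expect_equal(exp(mean(log(nf$size_factors))), 1)

  # sample B doubled on the invariant clone -> equal normalized invariants
  mat2 <- cbind(A = c(e1 = 100L, e2 = 50L, e3 = 200L),
                B = c(e1 = 90L, e2 = 60L, e3 = 400L))
  nf2 <- normalize_counts(mat2, "invariant_set", invariant_ids = inv)
  norm_inv <- mat2["e3", ] / nf2$size_factors
  expect_equal(unname(norm_inv[1]), unname(norm_inv[2]))

  # invariant entry with a zero count is excluded with a warning; with no
  # usable invariant left this is an error naming the entries
  mat3 <- cbind(A = c(e1 = 10L, e2 = 5L, e3 = 0L), B = c(e1 = 8L, e2 = 7L, e3 = 4L))
  expect_error(normalize_counts(mat3, "invariant_set", invariant_ids = "e3"), "e3")
  mat4 <- rbind(mat2, e4 = c(0L, 5L))
  expect_warning(
    nf4 <- normalize_counts(mat4, "invariant_set", invariant_ids = c("e3", "e4")),
    "e4")
  expect_equal(unname(nf4$size_factors), unname(nf2$size_factors))
})

test_that("TMM normalization undoes a global scale difference", {
  set.seed(1)
  base <- rnbinom(200, mu = 300, size = 10)
  mat <- cbind(A = base, B = as.integer(round(3 * base)))
  rownames(mat) <- sprintf("g%03d", seq_len(200))
  nf <- normalize_counts(mat, "tmm")
  expect_lt(abs(nf$size_factors[["B"]] / nf$size_factors[["A"]] - 3), 1e-6)

  # library-size (naive composition) factors behave the same way here
  nf2 <- normalize_counts(mat, "naive_composition")
  expect_equal(unname(nf2$size_factors[["B"]] / nf2$size_factors[["A"]]),
               sum(mat[, "B"]) / sum(mat[, "A"]))
})

test_that("dispersion estimation recovers known values", {
  groups <- rep(c("t", "c"), each = 3)
  sf <- rep(1, 6)

  # Poisson counts: common estimate near zero
  set.seed(2)
  pois <- matrix(rpois(50 * 6, lambda = 200), 50, 6,
                 dimnames = list(sprintf("e%02d", 1:50), sprintf("s%d", 1:6)))
  disp0 <- estimate_dispersion(pois, sf, groups, per_entry = FALSE)
  expect_lte(disp0$common, 0.02)

  # NB with dispersion 0.1: recovered within +/- 0.05
  set.seed(3)
  nb <- matrix(rnbinom(50 * 6, mu = 200, size = 10), 50, 6,
               dimnames = dimnames(pois))
  disp1 <- estimate_dispersion(nb, sf, groups, per_entry = FALSE)
  expect_lt(abs(disp1$common - 0.1), 0.05)

  # constant counts: no variance, dispersion 0
  const <- matrix(100L, 10, 6, dimnames = list(sprintf("e%d", 1:10), sprintf("s%d", 1:6)))
  expect_equal(estimate_dispersion(const, sf, groups, per_entry = FALSE)$common, 0)

  # single replicate everywhere: floor with a warning flag
  single <- estimate_dispersion(pois[, c(1, 4)], sf[1:2], c("t", "c"))
  expect_true(single$warning)
  expect_equal(single$common, 0.05)

  # shrinkage pulls per-entry values toward the common dispersion
  shr <- estimate_dispersion(nb, sf, groups, shrinkage_weight = 1)
  expect_true(all(abs(shr$per_entry - shr$common) < 1e-12))
})

test_that("the conditional exact test matches the binomial oracle at dispersion 0", {
  # observed at the mode -> p = 1
  expect_equal(nb_exact_test(c(10, 10), c("a", "b"), 0), 1)
  # extreme split: p = P(0) + P(20) = 2 * 0.5^20
  expect_equal(nb_exact_test(c(0, 20), c("a", "b"), 0), 2 * 0.5^20)

  # brute-force agreement with binom.test for modest totals and both
  # balanced (1v1) and unbalanced (2v1) replication
  for (t in c(1, 5, 12, 20)) {
    for (s1 in 0:t) {
      p_pkg <- nb_exact_test(c(s1, t - s1), c("a", "b"), 0)
      p_bin <- binom.test(s1, t, 0.5)$p.value
      expect_equal(p_pkg, p_bin, tolerance = 1e-12,
                   info = sprintf("t=%d s1=%d", t, s1))
    }
  }
  for (t in c(6, 15)) {
    for (s1 in 0:t) {
      counts <- c(ceiling(s1 / 2), floor(s1 / 2), t - s1)
      p_pkg <- nb_exact_test(counts, c("a", "a", "b"), 0)
      p_bin <- binom.test(s1, t, 2 / 3)$p.value
      expect_equal(p_pkg, p_bin, tolerance = 1e-12)
    }
  }

  expect_error(nb_exact_test(c(1, 2), c("a", "b"), -0.1), ">= 0")
  expect_equal(nb_exact_test(c(0, 0), c("a", "b"), 0.2), 1)
})

test_that("the exact test is calibrated and consistent with edgeR at dispersion > 0", {
  # symmetric observation is modal under equal replication
  expect_equal(nb_exact_test(c(30, 30), c("a", "b"), 0.2), 1)
  # p-values shrink as the split grows more extreme
  ps <- vapply(c(35, 45, 55), function(s1)
    nb_exact_test(c(s1, 60 - s1), c("a", "b"), 0.1), numeric(1))
  expect_true(all(diff(ps) < 0))

  skip_if_not_installed("edgeR")
  set.seed(4)
  mu <- rep(c(100, 100, 100, 100, 300, 500), each = 10)
  mat <- matrix(rnbinom(60 * 4, mu = mu, size = 10), 60, 4,
                dimnames = list(sprintf("e%02d", 1:60), sprintf("s%d", 1:4)))
  groups <- c("a", "a", "b", "b")
  p_pkg <- apply(mat, 1, nb_exact_test, groups = groups, dispersion = 0.1)
  dge <- edgeR::DGEList(mat, group = groups, norm.factors = rep(1, 4))
  dge$samples$lib.size <- rep(round(mean(colSums(mat))), 4)
  p_edger <- edgeR::exactTest(dge, dispersion = 0.1)$table$PValue
  expect_gt(cor(log(p_pkg), log(p_edger), method = "spearman"), 0.98)
})

test_that("BH adjustment reproduces hand-enumerated step-up values", {
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # fdr >= p always; invariant to input order
  set.seed(5)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  ord <- sample(50)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
})

test_that("enrichment calls recover simulated truth and respect invariances", {
  d <- fixture_dict()
  glyc <- glycan_ids(d)
  enriched <- setNames(rep(8, 6), glyc[seq(1, 30, 5)])
  sim <- simulate_counts(d, fc_map = enriched, dispersion = 0.1, seed = 11)
  ct <- contrast_spec(paste0("test", 1:3), paste0("ctrl", 1:3), "sim 8x")
  res <- run_enrichment(sim$counts, d, ct)

  expect_s3_class(res, "liga_enrichment")
  expect_true(all(res$entry_id[res$significant] %in% names(enriched)))
  expect_setequal(res$entry_id[res$significant], names(enriched))
  expect_false(any(res$significant[res$modification_class != "glycan"]))
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_equal(res$significant, res$fdr <= 0.05)

  # a self-contrast (duplicated columns) gives log2FC 0 and no calls
  mat <- unclass(sim$counts)[, 1:2]
  selfmat <- cbind(mat, mat)
  colnames(selfmat) <- c("t1", "t2", "c1", "c2")
  self <- run_enrichment(liga_counts(selfmat), d,
                         contrast_spec(c("t1", "t2"), c("c1", "c2")))
  expect_equal(self$log2FC, rep(0, nrow(self)))
  expect_false(any(self$significant))

  # rescaling one sample's counts is absorbed by normalization
  scaled <- unclass(sim$counts)
  scaled[, "test1"] <- as.integer(round(scaled[, "test1"] * 2))
  res_scaled <- run_enrichment(liga_counts(scaled), d, ct)
  expect_equal(res_scaled$log2FC, res$log2FC, tolerance = 0.02)
  expect_setequal(res_scaled$entry_id[res_scaled$significant],
                  res$entry_id[res$significant])

  # heatmap arrangement: structures x densities with significance flags
  hm <- enrichment_heatmap(res)
  expect_equal(dim(hm), c(6, 5))
  expect_equal(colnames(hm), c("50", "150", "500", "750", "1000"))
  expect_equal(sum(attr(hm, "significant")), 6)

  expect_error(run_enrichment(sim$counts, d, contrast_spec("nope", "ctrl1")),
               "absent")
})

test_that("fold-change group tests call the standard procedures", {
  # exact two-sided U-test: perfect separation of 3v3 -> p = 2/C(6,3) = 0.1
  res <- group_tests(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$p_value, 0.1)
  # identical groups: no separation
  res2 <- group_tests(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res2$p_value, 1)

  av <- group_tests(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)),
                    mode = "one_way_anova")
  expect_equal(av$p_value,
               summary(aov(v ~ g, data.frame(v = 1:9,
                                             g = rep(letters[1:3], each = 3))))[[1]][["Pr(>F)"]][1])

  # degenerate: all groups identical constants
  dg <- group_tests(list(a = c(2, 2), b = c(2, 2)), mode = "one_way_anova")
  expect_true(dg$degenerate)
  expect_error(group_tests(list(a = numeric(), b = 1:3)), "empty")
})
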