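# Differential enrichment of barcoded glycophages versus a control condition.
#
# The abundance of each clone is modelled as negative binomial (NB) with a
# common (optionally entry-shrunk) dispersion estimated by conditional
# maximum likelihood on size-factor-adjusted counts; two-group differences
# are assessed with a conditional exact test, and multiplicity is controlled
# by Benjamini-Hochberg at alpha = 0.05. Normalization assumes a set of
# clones (unmodified or azidoethanol-capped "blank" phages) is invariant
# between test and control; TMM and library-size (naive-composition) factors
# are provided for datasets where the invariant set is too shallow.

#' Compute per-sample normalization factors
#'
#' Factors are on the scale of counts: dividing a sample's counts by its
#' factor puts samples on a common scale. Factors are rescaled to have
#' geometric mean 1.
#'
#' \describe{
#'   \item{invariant_set}{Median-of-ratios over the invariant clones: each
#'     invariant entry's counts are divided by the entry's geometric-mean
#'     pseudo-reference across samples, and the per-sample factor is the
#'     median of those ratios. This realizes "scaling the blank phages to
#'     unity". Invariant entries containing a zero count in any sample carry
#'     no usable ratio and are excluded with a warning.}
#'   \item{tmm}{Trimmed mean of M-values (30\% M-trim, 5\% A-trim, inverse
#'     asymptotic-variance weights) against the sample with median library
#'     size; the TMM scale is multiplied by library size to give a count
#'     scale factor.}
#'   \item{naive_composition}{Library-size factors: each sample's total count
#'     relative to the designated naive/control samples' scale. With
#'     `naive_samples = NULL` all samples' totals are used.}
#' }
#'
#' @param counts `liga_counts` or integer matrix (entries x samples).
#' @param method One of `"invariant_set"`, `"tmm"`, `"naive_composition"`.
#' @param invariant_ids Entry ids of the invariant clones (required for
#'   `invariant_set`).
#' @param naive_samples Sample names defining the naive composition.
#' @return List of class `liga_norm`: `method`, `size_factors` (named,
#'   geometric mean 1), `invariant_ids`.
#' @export
normalize_counts <- function(counts,
                             method = c("invariant_set", "tmm", "naive_composition"),
                             invariant_ids = NULL, naive_samples = NULL) {
  method <- match.arg(method)
  mat <- unclass(counts)
  samples <- colnames(mat)

  factors <- switch(method,
    invariant_set = {
      if (is.null(invariant_ids) || !length(invariant_ids))
        stop("invariant_set normalization requires `invariant_ids`")
      missing_ids <- setdiff(invariant_ids, rownames(mat))
      if (length(missing_ids))
        stop("invariant entries absent from counts: ",
             paste(missing_ids, collapse = ", "))
      inv <- mat[invariant_ids, , drop = FALSE]
      usable <- rowSums(inv == 0) == 0L
      if (!any(usable))
        stop("no invariant entry has nonzero counts in every sample (",
             paste(invariant_ids, collapse = ", "), ")")
      if (!all(usable))
        warning("invariant entries with zero counts excluded from normalization: ",
                paste(invariant_ids[!usable], collapse = ", "))
      inv <- inv[usable, , drop = FALSE]
      ref <- apply(inv, 1, geomean)          # per-entry pseudo-reference
      apply(inv / ref, 2, stats::median)
    },
    tmm = {
      lib <- colSums(mat)
      ref_idx <- which.min(abs(lib - stats::median(lib)))
      rel <- vapply(seq_along(samples), function(j)
        tmm_factor(mat[, j], mat[, ref_idx], lib[j], lib[ref_idx]),
        numeric(1))
      lib * rel
    },
    naive_composition = {
      lib <- colSums(mat)
      if (!is.null(naive_samples)) {
        missing_s <- setdiff(naive_samples, samples)
        if (length(missing_s)) stop("unknown naive samples: ",
                                    paste(missing_s, collapse = ", "))
      }
      lib
    })

  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("normalization produced non-positive factors")
  factors <- factors / geomean(factors)
  structure(list(method = method,
                 size_factors = stats::setNames(factors, samples),
                 invariant_ids = if (method == "invariant_set")
                   invariant_ids else NULL),
            class = "liga_norm")
}

# TMM scale of sample `obs` relative to `ref` (both raw count vectors), as a
# ratio of normalized concentrations. 30% two-sided trim on M, 5% on A,
# precision weights from the delta-method binomial variances.
tmm_factor <- function(obs, ref, n_obs = sum(obs), n_ref = sum(ref),
                       trim_m = 0.3, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- 1 / ((n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r))
  if (max(abs(m)) < 1e-10) return(1)
  lo_m <- stats::quantile(m, trim_m); hi_m <- stats::quantile(m, 1 - trim_m)
  lo_a <- stats::quantile(a, trim_a); hi_a <- stats::quantile(a, 1 - trim_a)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep2)) keep2 <- rep(TRUE, length(m))
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

# Conditional NB log-likelihood of replicate vector y given its sum, for
# dispersion phi (size r = 1/phi per observation). Reduces to the
# multinomial/binomial conditional distribution as phi -> 0.
cond_nb_loglik <- function(y, phi) {
  n <- length(y); t <- sum(y)
  if (n < 2L || t == 0L) return(0)
  if (phi < 1e-10) {
    # Poisson limit: y | t ~ multinomial(t, 1/n)
    return(lgamma(t + 1) - sum(lgamma(y + 1)) - t * log(n))
  }
  r <- 1 / phi
  sum(lgamma(y + r)) - n * lgamma(r) - sum(lgamma(y + 1)) +
    lgamma(t + 1) + lgamma(n * r) - lgamma(t + n * r)
}

#' Estimate NB dispersion by conditional maximum likelihood
#'
#' Counts are first put on a common scale by dividing by the size factors and
#' rounding to the nearest integer; the conditional (given replicate-group
#' totals) NB likelihood, which does not involve the entry means, is then
#' maximized for a common dispersion over all entries, and per-entry
#' estimates are shrunk toward the common value.
#'
#' @param counts Count matrix (entries x samples).
#' @param size_factors Named per-sample factors (see [normalize_counts()]).
#' @param groups Factor/character of group membership per sample.
#' @param shrinkage_weight Weight in `[0,1]` on the common value when forming
#'   per-entry dispersions (1 = pure common).
#' @param floor Dispersion returned (with `warning = TRUE` flag) when no
#'   group has two replicates.
#' @param per_entry Skip the (slower) per-entry maximizations when `FALSE`;
#'   `per_entry` values are then the common dispersion.
#' @return List of class `liga_dispersion`: `common`, `per_entry` (named),
#'   `shrinkage_weight`, `warning`.
#' @export
estimate_dispersion <- function(counts, size_factors, groups,
                                shrinkage_weight = 0.8, floor = 0.05,
                                per_entry = TRUE) {
  mat <- unclass(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(mat)) stop("`groups` must match the samples")
  if (!is.null(names(size_factors)) && !is.null(colnames(mat)))
    size_factors <- size_factors[colnames(mat)]
  adj <- round(sweep(mat, 2, size_factors, "/"))
  replicated <- names(which(table(groups) >= 2L))
  if (!length(replicated))
    return(structure(list(common = floor,
                          per_entry = stats::setNames(rep(floor, nrow(mat)),
                                                      rownames(mat)),
                          shrinkage_weight = shrinkage_weight, warning = TRUE),
                     class = "liga_dispersion"))

  entry_loglik <- function(i, phi) {
    sum(vapply(replicated, function(g)
      cond_nb_loglik(adj[i, groups == g], phi), numeric(1)))
  }
  total_loglik <- function(phi)
    sum(vapply(seq_len(nrow(adj)), entry_loglik, numeric(1), phi = phi))

  common <- stats::optimize(total_loglik, interval = c(0, 5),
                            maximum = TRUE, tol = 1e-5)$maximum
  if (total_loglik(0) >= total_loglik(common)) common <- 0

  if (per_entry) {
    per <- vapply(seq_len(nrow(adj)), function(i) {
      opt <- stats::optimize(function(p) entry_loglik(i, p), interval = c(0, 5),
                             maximum = TRUE, tol = 1e-4)
      if (entry_loglik(i, 0) >= opt$objective) 0 else opt$maximum
    }, numeric(1))
    per <- shrinkage_weight * common + (1 - shrinkage_weight) * per
  } else {
    per <- rep(common, nrow(adj))
  }
  structure(list(common = common,
                 per_entry = stats::setNames(per, rownames(mat)),
                 shrinkage_weight = shrinkage_weight, warning = FALSE),
            class = "liga_dispersion")
}

#' Conditional NB exact test for a two-group comparison of one entry
#'
#' Counts are adjusted to a common scale by the size factors (rounded to the
#' nearest integer) and summed within groups. Conditional on the grand total,
#' the first group's sum follows a negative hypergeometric law under the
#' null; the two-sided p-value is the total probability of outcomes no more
#' probable than the observed one. At dispersion 0 this reduces exactly to
#' the conditional binomial test.
#'
#' @param counts Integer counts for one entry, in sample order.
#' @param groups Two-level factor/character of group membership.
#' @param dispersion NB dispersion (>= 0).
#' @param size_factors Per-sample factors (default all 1).
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(counts, groups, dispersion = 0,
                          size_factors = rep(1, length(counts))) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  adj <- round(counts / size_factors)
  s1 <- sum(adj[groups == levels(groups)[1]])
  s2 <- sum(adj[groups == levels(groups)[2]])
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  t <- s1 + s2
  if (t == 0) return(1)

  x <- 0:t
  if (dispersion < 1e-10) {
    logp <- stats::dbinom(x, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / dispersion; r2 <- n2 / dispersion
    logp <- lgamma(x + r1) - lgamma(x + 1) - lgamma(r1) +
      lgamma(t - x + r2) - lgamma(t - x + 1) - lgamma(r2)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[s1 + 1L]
  p <- sum(exp(logp[logp <= p_obs + 1e-9]))
  min(1, p)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Vector of p-values in `[0,1]`.
#' @return FDR-adjusted values (monotone, clipped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Specify a two-condition contrast
#' @param test_samples,control_samples Disjoint, non-empty sample-name sets.
#' @param label Human-readable label (e.g. "SNA vs BSA").
#' @export
contrast_spec <- function(test_samples, control_samples, label = "test vs control") {
  if (!length(test_samples) || !length(control_samples))
    stop("both sample sets must be non-empty")
  if (length(intersect(test_samples, control_samples)))
    stop("test and control samples must be disjoint")
  structure(list(test_samples = test_samples, control_samples = control_samples,
                 label = label), class = "contrast_spec")
}

#' Test each clone for differential enrichment versus a control condition
#'
#' Normalizes the contrasted samples, estimates dispersion, and for every
#' dictionary entry computes the log2 fold change of normalized mean counts
#' (prior count 0.5 added to both means), a delta-method standard deviation
#' propagated from the NB variance of the normalized counts, a conditional
#' exact-test p-value and its BH-adjusted FDR, flagged significant at
#' `fdr <= alpha`.
#'
#' @param counts `liga_counts` or matrix.
#' @param dict `liga_dictionary` describing the entries.
#' @param contrast A [contrast_spec()].
#' @param normalization Method for [normalize_counts()].
#' @param invariant_ids Invariant clone ids; defaults to all non-glycan
#'   entries of the dictionary.
#' @param alpha FDR threshold for the `significant` flag.
#' @param dispersion `"common"` (default) or `"shrunk"` per-entry values;
#'   alternatively a single number to use as-is.
#' @param prior_count Added to both normalized means for the fold change.
#' @return `data.frame` of class `liga_enrichment` with columns `entry_id`,
#'   `structure_id`, `mean_density`, `modification_class`, `log2FC`, `FC_sd`,
#'   `p_value`, `fdr`, `significant`; attributes `norm` and `contrast`.
#' @export
run_enrichment <- function(counts, dict, contrast,
                           normalization = c("invariant_set", "tmm", "naive_composition"),
                           invariant_ids = NULL, alpha = 0.05,
                           dispersion = c("common", "shrunk"),
                           prior_count = 0.5) {
  normalization <- match.arg(normalization)
  mat <- unclass(counts)
  samples <- c(contrast$test_samples, contrast$control_samples)
  missing_s <- setdiff(samples, colnames(mat))
  if (length(missing_s)) stop("samples absent from counts: ",
                              paste(missing_s, collapse = ", "))
  missing_e <- setdiff(rownames(mat), dict$entries$entry_id)
  if (length(missing_e)) stop("entries absent from dictionary: ",
                              paste(missing_e, collapse = ", "))
  mat <- mat[, samples, drop = FALSE]
  groups <- factor(rep(c("test", "control"),
                       c(length(contrast$test_samples),
                         length(contrast$control_samples))),
                   levels = c("control", "test"))

  if (is.null(invariant_ids))
    invariant_ids <- dict$entries$entry_id[dict$entries$modification_class != "glycan"]
  norm <- normalize_counts(mat, normalization, invariant_ids = invariant_ids)
  sf <- norm$size_factors

  if (is.numeric(dispersion)) {
    disp_entry <- rep(dispersion, nrow(mat))
    disp_obj <- NULL
  } else {
    dispersion <- match.arg(dispersion)
    disp_obj <- estimate_dispersion(mat, sf, groups,
                                    per_entry = dispersion == "shrunk")
    disp_entry <- if (dispersion == "common")
      rep(disp_obj$common, nrow(mat)) else disp_obj$per_entry
  }

  y <- sweep(mat, 2, sf, "/")  # normalized counts
  is_test <- groups == "test"
  m1 <- rowMeans(y[, is_test, drop = FALSE])
  m0 <- rowMeans(y[, !is_test, drop = FALSE])
  log2fc <- log2((m1 + prior_count) / (m0 + prior_count))

  # delta-method variance of log2FC from NB count variances mu + phi mu^2,
  # with mu_s estimated as group mean * size factor
  var_mean <- function(m, idx, phi) {
    mu_s <- outer(m, sf[idx])               # entries x samples in group
    v <- sweep(mu_s + phi * mu_s^2, 2, sf[idx]^2, "/")
    rowSums(v) / length(idx)^2
  }
  v1 <- var_mean(m1, which(is_test), disp_entry)
  v0 <- var_mean(m0, which(!is_test), disp_entry)
  sd_log2fc <- sqrt(v1 / ((m1 + prior_count) * log(2))^2 +
                      v0 / ((m0 + prior_count) * log(2))^2)
  fc_sd <- 2^log2fc * log(2) * sd_log2fc   # sd of FC itself

  p <- vapply(seq_len(nrow(mat)), function(i)
    nb_exact_test(mat[i, ], groups, disp_entry[i], sf), numeric(1))
  fdr <- bh_adjust(p)

  meta <- dict$entries[match(rownames(mat), dict$entries$entry_id),
                       c("structure_id", "mean_density", "modification_class")]
  res <- data.frame(entry_id = rownames(mat), meta, log2FC = log2fc,
                    FC_sd = fc_sd, p_value = p, fdr = fdr,
                    significant = fdr <= alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "norm") <- norm
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  attr(res, "dispersion") <- disp_obj
  class(res) <- c("liga_enrichment", "data.frame")
  res
}

#' Arrange enrichment results as a structure x density heatmap matrix
#'
#' @param res A `liga_enrichment` result.
#' @return Numeric matrix of log2FC (structures x densities) with a logical
#'   attribute `significant` of the same shape; non-glycan entries are
#'   excluded.
#' @export
enrichment_heatmap <- function(res) {
  g <- res[res$modification_class == "glycan", ]
  structures <- unique(g$structure_id)
  densities <- sort(unique(g$mean_density))
  fc <- matrix(NA_real_, length(structures), length(densities),
               dimnames = list(structures, as.character(densities)))
  sig <- matrix(FALSE, length(structures), length(densities),
                dimnames = dimnames(fc))
  for (i in seq_len(nrow(g))) {
    r <- match(g$structure_id[i], structures)
    c <- match(as.character(g$mean_density[i]), colnames(fc))
    # multi-SDB entries: average FC, flag significant if any barcode is
    fc[r, c] <- if (is.na(fc[r, c])) g$log2FC[i] else mean(c(fc[r, c], g$log2FC[i]))
    sig[r, c] <- sig[r, c] || g$significant[i]
  }
  attr(fc, "significant") <- sig
  fc
}

#' Write enrichment results and the heatmap matrix as TSV
#' @param res A `liga_enrichment`.
#' @param path Results TSV path; heatmap goes to `<path>.heatmap.tsv` with
#'   `*` flags appended to significant cells.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hm <- enrichment_heatmap(res)
  sig <- attr(hm, "significant")
  cells <- matrix(sprintf("%.4f%s", hm, ifelse(sig, "*", "")),
                  nrow = nrow(hm), dimnames = dimnames(hm))
  cells[is.na(hm)] <- "NA"
  df <- data.frame(structure_id = rownames(hm), cells, check.names = FALSE)
  utils::write.table(df, paste0(path, ".heatmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare fold changes between clone groups
#'
#' Secondary tests over per-clone fold changes grouped by glycan class or
#' organ: a two-sided Mann-Whitney U test (exact when both groups have at
#' most 10 values, normal approximation with tie correction otherwise) or a
#' standard (Fisher) one-way ANOVA F-test.
#'
#' @param fc_by_group Named list of numeric fold-change vectors.
#' @param mode `"mann_whitney_two_sided"` (2 groups) or `"one_way_anova"`.
#' @return List: `p_value`, `statistic`, `mode`, `degenerate` (TRUE when all
#'   groups are identical constants, where no test is possible).
#' @export
group_tests <- function(fc_by_group,
                        mode = c("mann_whitney_two_sided", "one_way_anova")) {
  mode <- match.arg(mode)
  if (any(!lengths(fc_by_group))) stop("empty group")
  if (mode == "mann_whitney_two_sided") {
    if (length(fc_by_group) != 2L) stop("U-test requires exactly two groups")
    x <- fc_by_group[[1]]; y <- fc_by_group[[2]]
    exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                              exact = exact, correct = TRUE))
    list(p_value = wt$p.value, statistic = unname(wt$statistic),
         mode = mode, degenerate = FALSE)
  } else {
    if (length(fc_by_group) < 2L) stop("ANOVA requires at least two groups")
    if (any(lengths(fc_by_group) < 2L)) stop("ANOVA requires >= 2 values per group")
    values <- unlist(fc_by_group, use.names = FALSE)
    grp <- factor(rep(names(fc_by_group), lengths(fc_by_group)))
    within_var <- tapply(values, grp, stats::var)
    if (all(within_var < 1e-300)) {
      means <- tapply(values, grp, mean)
      if (max(means) - min(means) < 1e-300)
        return(list(p_value = NA_real_, statistic = NA_real_, mode = mode,
                    degenerate = TRUE))
    }
    ft <- stats::oneway.test(values ~ grp, var.equal = TRUE)
    list(p_value = ft$p.value, statistic = unname(ft$statistic),
         mode = mode, degenerate = FALSE)
  }
}
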