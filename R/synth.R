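# Seeded synthetic-data generators for every input the pipeline consumes.
#
# Each generator is a deterministic function of its arguments and mandatory
# seed (a private RNG stream is used and the caller's RNG state restored),
# and returns the ground truth alongside the data so any downstream stage's
# error can be measured without re-deriving parameters.

#' Simulate a barcode count matrix under the NB model
#'
#' Per-clone baseline abundances are log-normal (the mixing of titer-matched
#' phage stocks does not give uniform barcode distributions), per-sample
#' library-size factors are log-uniform over `libsize_range`, and counts are
#' drawn NB with `mean = baseline * FC(group) * libsize factor` and the given
#' dispersion (Poisson at dispersion 0). Invariant (non-glycan) clones have
#' fold change 1 by construction.
#'
#' @param dict `liga_dictionary` defining the clones.
#' @param n_test,n_control Replicates per condition.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (mean count scale ~ exp(meanlog + sdlog^2/2)).
#' @param fc_map Named fold changes applied to the test condition for glycan
#'   entries (default: all 1). Names are entry ids.
#' @param dispersion NB dispersion (>= 0; 0 = Poisson).
#' @param libsize_range Range of per-sample relative depth factors.
#' @param seed Integer seed (mandatory).
#' @return List: `counts` (a `liga_counts`), `truth` (list with `fc`,
#'   `baseline`, `lib_factor`, `group`, `dispersion`, `seed`).
#' @export
simulate_counts <- function(dict, n_test = 3L, n_control = 3L,
                            baseline_meanlog = log(300), baseline_sdlog = 0.8,
                            fc_map = NULL, dispersion = 0.1,
                            libsize_range = c(0.7, 1.4), seed) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  entries <- dict$entries
  n_entry <- nrow(entries)
  samples <- c(sprintf("test%d", seq_len(n_test)),
               sprintf("ctrl%d", seq_len(n_control)))
  group <- rep(c("test", "control"), c(n_test, n_control))

  fc <- stats::setNames(rep(1, n_entry), entries$entry_id)
  if (!is.null(fc_map)) {
    unknown <- setdiff(names(fc_map), entries$entry_id)
    if (length(unknown)) stop("fc_map names not in dictionary: ",
                              paste(unknown, collapse = ", "))
    fc[names(fc_map)] <- fc_map
  }
  fc[entries$modification_class != "glycan"] <- 1  # invariant by construction

  with_seed(seed, {
    baseline <- stats::rlnorm(n_entry, baseline_meanlog, baseline_sdlog)
    lib <- exp(stats::runif(length(samples), log(libsize_range[1]),
                            log(libsize_range[2])))
    fc_mat <- vapply(group, function(g) if (g == "test") fc else rep(1, n_entry),
                     numeric(n_entry))
    mu <- outer(baseline, lib) * fc_mat
    mat <- matrix(0L, n_entry, length(samples),
                  dimnames = list(entries$entry_id, samples))
    for (j in seq_along(samples)) {
      mat[, j] <- if (dispersion == 0) stats::rpois(n_entry, mu[, j])
      else stats::rnbinom(n_entry, mu = mu[, j], size = 1 / dispersion)
    }
    list(counts = liga_counts(mat),
         truth = list(fc = fc, baseline = baseline,
                      lib_factor = stats::setNames(lib, samples),
                      group = stats::setNames(group, samples),
                      dispersion = dispersion, seed = seed))
  })
}

random_bases <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < error_rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

#' Simulate paired-end FASTQ amplicon reads
#'
#' Forward reads embed `upstream1 + SDB1 + downstream1 + upstream2 + SDB2 +
#' downstream2` after a random-length pad, padded with uniform random bases
#' to the design read length (2 x 75 bp chemistry); per-base substitution
#' errors are applied at `error_rate`. Mate 2 is the reverse complement of
#' the forward template with independent errors (pass-through only).
#'
#' @param dict `liga_dictionary`.
#' @param design [amplicon_design()].
#' @param reads_per_sample Named integer vector (names = samples).
#' @param proportions Optional per-entry sampling weights (default uniform).
#' @param error_rate Per-base substitution probability in `[0, 0.2]`.
#' @param seed Integer seed (mandatory).
#' @param dir Output directory for the FASTQ files.
#' @return List: `r1`, `r2` (named paths), `truth` (entries x samples matrix
#'   of intended counts, plus `seed`, `error_rate`).
#' @export
simulate_fastq <- function(dict, design, reads_per_sample, proportions = NULL,
                           error_rate = 0, seed, dir = tempdir()) {
  if (error_rate < 0 || error_rate > 0.2) stop("error_rate must be in [0, 0.2]")
  if (is.null(names(reads_per_sample)))
    stop("`reads_per_sample` must be named by sample")
  entries <- dict$entries
  bc1 <- entries$sdb1; bc2 <- entries$sdb2
  if (is.null(proportions)) proportions <- rep(1, nrow(entries))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  samples <- names(reads_per_sample)
  r1_paths <- stats::setNames(file.path(dir, sprintf("%s_R1.fastq", samples)), samples)
  r2_paths <- stats::setNames(file.path(dir, sprintf("%s_R2.fastq", samples)), samples)
  truth <- matrix(0L, nrow(entries), length(samples),
                  dimnames = list(entries$entry_id, samples))

  with_seed(seed, {
    for (s in samples) {
      n <- reads_per_sample[[s]]
      r1_lines <- character(0); r2_lines <- character(0)
      if (n > 0) {
        picks <- sample.int(nrow(entries), n, replace = TRUE, prob = proportions)
        truth[, s] <- tabulate(picks, nbins = nrow(entries))
        core <- paste0(design$upstream1, bc1[picks], design$downstream1,
                       design$upstream2, bc2[picks], design$downstream2)
        reads <- vapply(core, function(cs) {
          pad <- sample.int(6L, 1L) - 1L
          full <- paste0(random_bases(pad), cs)
          tail_n <- design$read_length - nchar(full)
          if (tail_n > 0) full <- paste0(full, random_bases(tail_n))
          mutate_bases(substr(full, 1L, design$read_length), error_rate)
        }, character(1), USE.NAMES = FALSE)
        mates <- vapply(revcomp(core), mutate_bases, character(1),
                        error_rate = error_rate, USE.NAMES = FALSE)
        ids <- sprintf("@%s_read%d", s, seq_len(n))
        qual1 <- strrep("I", nchar(reads))
        qual2 <- strrep("I", nchar(mates))
        r1_lines <- as.vector(rbind(ids, reads, "+", qual1))
        r2_lines <- as.vector(rbind(ids, mates, "+", qual2))
      }
      writeLines(r1_lines, r1_paths[[s]])
      writeLines(r2_lines, r2_paths[[s]])
    }
  })
  list(r1 = r1_paths, r2 = r2_paths,
       truth = list(counts = truth, seed = seed, error_rate = error_rate))
}

#' Simulate a MALDI-TOF spectrum of glycophage coat protein
#'
#' Gaussian peaks at the species masses with areas proportional to
#' `fraction * suppression` (suppression applied to sialylated species,
#' emulating their reduced ionization efficiency), in-source ghost
#' satellites at multiples of -291.0954 Da (a sialylated parent loses its
#' k-th sialic acid with probability `ghost_fraction` per retained level,
#' conserving total parent area), a linear baseline drift, and additive
#' Gaussian noise.
#'
#' @param fractions Named species fractions, summing to 1.
#' @param masses Named masses (Da), same names.
#' @param sialic_counts Named integer sialic-acid counts (default 0).
#' @param sigma Peak width (Da).
#' @param noise_sd Additive noise, as a fraction of the tallest peak.
#' @param baseline Length-2 numeric `c(intercept, slope_per_Da)` drift.
#' @param ghost_fraction Probability of in-source loss per sialic acid.
#' @param sialyl_suppression Multiplier on sialylated species' areas.
#' @param mz_range,dmz Spectrum grid (Da).
#' @param total_area Total spectral area scale.
#' @param seed Integer seed (mandatory).
#' @return List: `spectrum` (a `liga_spectrum`), `truth` (input fractions,
#'   per-peak areas including ghosts, parameters).
#' @export
simulate_spectrum <- function(fractions, masses, sialic_counts = NULL,
                              sigma = 3, noise_sd = 0.005,
                              baseline = c(0, 0), ghost_fraction = 0,
                              sialyl_suppression = 1,
                              mz_range = c(4800, 8000), dmz = 0.5,
                              total_area = 1000, seed) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  nm <- names(fractions)
  if (is.null(nm) || !all(nm %in% names(masses)))
    stop("fractions and masses must share names")
  if (is.null(sialic_counts)) sialic_counts <- stats::setNames(rep(0L, length(nm)), nm)

  peak_mass <- c(); peak_area <- c()
  for (s in nm) {
    a <- total_area * fractions[[s]] *
      (if (sialic_counts[[s]] >= 1) sialyl_suppression else 1)
    k <- sialic_counts[[s]]
    if (ghost_fraction > 0 && k >= 1) {
      # sequential in-source loss: retain with prob (1-g) at each level
      w <- c((1 - ghost_fraction) * ghost_fraction^(0:(k - 1)), ghost_fraction^k)
      for (j in 0:k) {
        peak_mass <- c(peak_mass, masses[[s]] - RESIDUE_MASSES[["Neu5Ac"]] * j)
        peak_area <- c(peak_area, a * w[j + 1])
        names(peak_mass)[length(peak_mass)] <-
          if (j == 0) s else sprintf("%s_ghost%d", s, j)
      }
    } else {
      peak_mass <- c(peak_mass, stats::setNames(masses[[s]], s))
      peak_area <- c(peak_area, a)
    }
  }
  names(peak_area) <- names(peak_mass)

  mz <- seq(mz_range[1], mz_range[2], by = dmz)
  clean <- rowSums(vapply(seq_along(peak_mass), function(i)
    peak_area[i] * stats::dnorm(mz, peak_mass[i], sigma),
    numeric(length(mz))))
  drift <- baseline[1] + baseline[2] * (mz - mz_range[1])
  with_seed(seed, {
    noisy <- clean + drift +
      stats::rnorm(length(mz), 0, noise_sd * max(max(clean), 1e-12))
    spec <- liga_spectrum(mz, pmax(noisy, 0))
    list(spectrum = spec,
         truth = list(fractions = fractions, peak_areas = peak_area,
                      peak_masses = peak_mass, sigma = sigma,
                      ghost_fraction = ghost_fraction,
                      sialyl_suppression = sialyl_suppression, seed = seed))
  })
}

#' Simulate a native-MS titration series
#'
#' Fraction bound is computed from the 1:1 isotherm at the true `Kd` and
#' inverted to the abundance ratio `R = f / (1 - f)`; log-normal
#' multiplicative noise is applied to R.
#'
#' @param P0 Initial protein concentration (uM).
#' @param Kd True dissociation constant (uM).
#' @param L0 Ligand concentration grid (uM).
#' @param noise_sd Multiplicative (log-scale) noise on R.
#' @param seed Integer seed (mandatory).
#' @return List: `series` (a [titration_series()]), `truth` (`Kd`, `seed`).
#' @export
simulate_titration <- function(P0, Kd, L0, noise_sd = 0, seed) {
  f <- fraction_bound(P0, L0, Kd)
  if (any(f >= 1)) {
    warning("fraction bound of 1 clipped to avoid infinite ratios")
    f <- pmin(f, 1 - 1e-9)
  }
  r <- f / (1 - f)
  with_seed(seed, {
    if (noise_sd > 0) r <- r * exp(stats::rnorm(length(r), 0, noise_sd))
    list(series = titration_series(P0, L0, r),
         truth = list(Kd = Kd, P0 = P0, noise_sd = noise_sd, seed = seed))
  })
}
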