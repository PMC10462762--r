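# MALDI-TOF quantification of pVIII coat-protein modification.
#
# A spectrum of a glycophage sample shows the unmodified pVIII peak, the
# DBCO-functionalized pVIII peak and (after SPAAC ligation) glycoconjugate
# peaks, plus in-source "ghost" satellites at -291.10 Da per cleaved sialic
# acid. Gaussian peak areas, after optional ghost correction, give species
# fractions; the modified fraction times the 2700 available pVIII copies is
# the mean display density.

#' Construct a mass spectrum
#' @param mz Strictly increasing m/z values (Da).
#' @param intensity Non-negative intensities, same length.
#' @param label Optional label.
#' @param time Optional timepoint (h) for time-course series.
#' @export
liga_spectrum <- function(mz, intensity, label = NULL, time = NULL) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (is.unsorted(mz, strictly = TRUE)) stop("mz must be strictly increasing")
  if (any(!is.finite(intensity))) stop("non-finite intensities")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 label = label, time = time), class = "liga_spectrum")
}

#' Read a two-column MALDI text spectrum
#'
#' Whitespace- or tab-delimited `m/z intensity` rows; lines starting with
#' `#` are comments.
#' @param path File path.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, comment.char = "#", col.names = c("mz", "intensity"))
  ord <- order(df$mz)
  liga_spectrum(df$mz[ord], df$intensity[ord], label = basename(path))
}

#' Write a spectrum in the two-column text dialect
#' @param spec A `liga_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(data.frame(spec$mz, spec$intensity), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Baseline-subtract and smooth a spectrum
#'
#' The baseline is a rolling minimum followed by a rolling mean over the same
#' window (in Da), subtracted and clipped at zero; intensities are then
#' smoothed with a moving average of `smooth_window` points. Deterministic.
#'
#' @param spec A `liga_spectrum`.
#' @param baseline_window Window width in Da.
#' @param smooth_window Moving-average width in points (odd preferred; kept
#'   narrow by default so repeated preprocessing barely changes peak shape).
#' @return Preprocessed `liga_spectrum`.
#' @export
preprocess_spectrum <- function(spec, baseline_window = 150, smooth_window = 3) {
  if (baseline_window <= 0 || smooth_window <= 0) stop("windows must be positive")
  span <- diff(range(spec$mz))
  if (baseline_window > span) stop("baseline window larger than spectrum span")
  dmz <- stats::median(diff(spec$mz))
  w <- max(3L, round(baseline_window / dmz))
  base <- zoo::rollapply(spec$intensity, w, min, partial = TRUE)
  base <- zoo::rollapply(base, w, mean, partial = TRUE)
  y <- pmax(spec$intensity - base, 0)
  y <- zoo::rollapply(y, max(1L, round(smooth_window)), mean, partial = TRUE)
  liga_spectrum(spec$mz, y, label = spec$label, time = spec$time)
}

#' Declare a spectral species
#' @param name Species name.
#' @param expected_mass Expected mass (Da).
#' @param class One of `"pviii"`, `"dbco_pviii"`, `"conjugate"`.
#' @param sialic_count Number of sialic acids carried (ghost parents).
#' @param ghost_parent Name of the parent species when this peak is an
#'   in-source sialic-acid-loss artifact.
#' @export
species_model <- function(name, expected_mass,
                          class = c("conjugate", "pviii", "dbco_pviii"),
                          sialic_count = 0L, ghost_parent = NULL) {
  class <- match.arg(class)
  if (expected_mass <= 0) stop("expected_mass must be positive")
  structure(list(name = name, expected_mass = expected_mass, class = class,
                 sialic_count = as.integer(sialic_count),
                 ghost_parent = ghost_parent),
            class = "species_model")
}

#' Default mass constants for the M13 major coat protein workflow
#'
#' `pviii`: mature pVIII average mass; `dbco`: mass added by DBCO-NHS
#' acylation; `linker`: azido-octanoyl-Asn linker retained on the conjugate
#' after SPAAC. Configuration constants; override to match the instrument
#' calibration at hand.
#' @export
maldi_masses <- function() c(pviii = 5238.4, dbco = 287.3, linker = 297.3)

#' Predict the species expected in a glycophage spectrum
#'
#' Conjugate mass = pVIII base + DBCO adduct + linker + sum of residue masses
#' from the glycan composition (Hex 162.0528, HexNAc 203.0794, Neu5Ac
#' 291.0954, dHex 146.0579 Da). Every species carrying `k >= 1` sialic acids
#' additionally emits ghost companions at `-291.0954 * j` Da (`j = 1..k`)
#' flagged with `ghost_parent`.
#'
#' @param pviii_base pVIII mass (Da).
#' @param adducts Named numeric with `dbco` and `linker` masses.
#' @param glycan Optional [glycan_structure()] for the conjugate species.
#' @param include Character subset of `c("pviii", "dbco_pviii", "conjugate")`.
#' @return List of [species_model()] objects.
#' @export
predict_species_masses <- function(pviii_base = maldi_masses()[["pviii"]],
                                   adducts = maldi_masses()[c("dbco", "linker")],
                                   glycan = NULL,
                                   include = c("pviii", "dbco_pviii", "conjugate")) {
  species <- list()
  if ("pviii" %in% include)
    species$pviii <- species_model("pviii", pviii_base, "pviii")
  if ("dbco_pviii" %in% include)
    species$dbco_pviii <- species_model("dbco_pviii",
                                        pviii_base + adducts[["dbco"]],
                                        "dbco_pviii")
  if (!is.null(glycan) && "conjugate" %in% include) {
    comp <- glycan$composition
    bad <- setdiff(names(comp), names(RESIDUE_MASSES))
    if (length(bad)) stop("unknown monosaccharide class: ", paste(bad, collapse = ", "))
    gmass <- sum(RESIDUE_MASSES[names(comp)] * comp)
    sial <- if ("Neu5Ac" %in% names(comp)) comp[["Neu5Ac"]] else 0L
    nm <- glycan$structure_id
    species[[nm]] <- species_model(nm,
                                   pviii_base + adducts[["dbco"]] + adducts[["linker"]] + gmass,
                                   "conjugate", sialic_count = sial)
  }
  # ghost companions of every sialylated species
  for (sp in species) {
    if (sp$sialic_count >= 1L) {
      for (j in seq_len(sp$sialic_count)) {
        gnm <- sprintf("%s_ghost%d", sp$name, j)
        species[[gnm]] <- species_model(gnm,
                                        sp$expected_mass - RESIDUE_MASSES[["Neu5Ac"]] * j,
                                        sp$class, sialic_count = sp$sialic_count - j,
                                        ghost_parent = sp$name)
      }
    }
  }
  unname(species)
}

# gaussian profile with unit-height amplitude
gauss <- function(mz, center, sigma, amplitude) {
  amplitude * exp(-0.5 * ((mz - center) / sigma)^2)
}

#' Fit Gaussian peaks for a set of expected species
#'
#' Each species is fit by least squares in the window
#' `expected_mass +/- tolerance`; species whose windows overlap are fit
#' jointly as a sum of Gaussians. A species whose maximum local intensity is
#' below `snr_threshold` times the spectrum noise level (estimated robustly
#' from first differences, `mad(diff(intensity)) / sqrt(2)`, which is blind
#' to smooth peaks) is assigned area 0 and excluded from the fit. Peak width
#' is free within [0.5, 20] Da.
#'
#' @param spec A (preprocessed) `liga_spectrum`.
#' @param species List of [species_model()]s.
#' @param tolerance Center tolerance in Da.
#' @param snr_threshold Detection threshold in noise units.
#' @param noise Noise level override (intensity units).
#' @return `data.frame` of class `peak_fit`: `species`, `class`,
#'   `ghost_parent`, `center`, `sigma`, `amplitude`, `area`
#'   (`amplitude * sigma * sqrt(2*pi)`), `residual`.
#' @export
fit_peaks <- function(spec, species, tolerance = 40, snr_threshold = 8,
                      noise = NULL) {
  if (any(!is.finite(spec$intensity))) stop("non-finite intensities")
  masses <- vapply(species, `[[`, numeric(1), "expected_mass")
  if (any(masses < min(spec$mz) | masses > max(spec$mz)))
    stop("species mass outside the spectrum range")
  if (is.null(noise)) {
    noise <- stats::mad(diff(spec$intensity)) / sqrt(2)
    if (!is.finite(noise) || noise == 0) noise <- 1e-12
  }

  n <- length(species)
  out <- data.frame(species = vapply(species, `[[`, character(1), "name"),
                    class = vapply(species, `[[`, character(1), "class"),
                    ghost_parent = vapply(species, function(s)
                      s$ghost_parent %||% NA_character_, character(1)),
                    center = NA_real_, sigma = NA_real_, amplitude = 0,
                    area = 0, residual = NA_real_, stringsAsFactors = FALSE)

  detectable <- logical(n)
  local_max <- numeric(n)
  for (i in seq_len(n)) {
    win <- abs(spec$mz - masses[i]) <= tolerance
    local_max[i] <- if (any(win)) max(spec$intensity[win]) else 0
    detectable[i] <- local_max[i] >= snr_threshold * noise
  }
  if (!any(detectable)) {
    class(out) <- c("peak_fit", "data.frame")
    return(out)
  }

  # cluster detectable species whose windows overlap; fit each cluster jointly
  idx <- which(detectable)
  ord <- idx[order(masses[idx])]
  clusters <- list(); cur <- ord[1]
  if (length(ord) > 1) for (i in ord[-1]) {
    if (masses[i] - tolerance <= masses[cur[length(cur)]] + tolerance) {
      cur <- c(cur, i)
    } else {
      clusters[[length(clusters) + 1L]] <- cur; cur <- i
    }
  }
  clusters[[length(clusters) + 1L]] <- cur

  for (cl in clusters) {
    win <- spec$mz >= min(masses[cl]) - tolerance &
      spec$mz <= max(masses[cl]) + tolerance
    x <- spec$mz[win]; yobs <- spec$intensity[win]
    k <- length(cl)
    # init: local argmax near each expected mass
    init_c <- vapply(cl, function(i) {
      w <- abs(x - masses[i]) <= tolerance
      x[w][which.max(yobs[w])]
    }, numeric(1))
    init_a <- vapply(cl, function(i) max(local_max[i], 1e-9), numeric(1))
    start <- c(init_c, rep(3, k), init_a)
    lower <- c(masses[cl] - tolerance, rep(0.5, k), rep(0, k))
    upper <- c(masses[cl] + tolerance, rep(20, k), pmax(2 * init_a, 1e-6))
    model <- function(par) {
      cen <- par[1:k]; sig <- par[(k + 1):(2 * k)]; amp <- par[(2 * k + 1):(3 * k)]
      rowSums(vapply(seq_len(k), function(j) gauss(x, cen[j], sig[j], amp[j]),
                     numeric(length(x))))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = function(par) yobs - model(par),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # fallback: moment estimates from the window around each species
      for (j in seq_len(k)) {
        i <- cl[j]
        w <- abs(x - masses[i]) <= tolerance
        wt <- yobs[w]
        out$center[i] <- sum(x[w] * wt) / sum(wt)
        out$sigma[i] <- sqrt(sum((x[w] - out$center[i])^2 * wt) / sum(wt))
        out$area[i] <- sum(wt) * stats::median(diff(x))
        out$amplitude[i] <- out$area[i] / (out$sigma[i] * sqrt(2 * pi))
      }
      next
    }
    par <- fit$par
    resid_rms <- sqrt(mean(fit$fvec^2))
    for (j in seq_len(k)) {
      i <- cl[j]
      out$center[i] <- par[j]
      out$sigma[i] <- par[k + j]
      out$amplitude[i] <- par[2 * k + j]
      out$area[i] <- par[2 * k + j] * par[k + j] * sqrt(2 * pi)
      out$residual[i] <- resid_rms
    }
  }
  class(out) <- c("peak_fit", "data.frame")
  out
}

#' Species fractions from fitted peak areas
#'
#' With `ghost_correct = TRUE` each ghost peak's area is reassigned to its
#' parent species before normalizing, undoing in-source sialic-acid loss;
#' the total assigned area is unchanged, only its attribution.
#'
#' @param fits A `peak_fit` data.frame from [fit_peaks()].
#' @param ghost_correct Reassign ghost areas to parents (default TRUE).
#' @return Named numeric vector of fractions summing to 1 (ghost entries
#'   carry fraction 0 after correction).
#' @export
quantify_species <- function(fits, ghost_correct = TRUE) {
  areas <- stats::setNames(fits$area, fits$species)
  if (all(areas == 0)) stop("all fitted areas are zero")
  if (ghost_correct) {
    for (i in seq_len(nrow(fits))) {
      gp <- fits$ghost_parent[i]
      if (!is.na(gp) && areas[[fits$species[i]]] > 0) {
        areas[[gp]] <- areas[[gp]] + areas[[fits$species[i]]]
        areas[[fits$species[i]]] <- 0
      }
    }
  }
  areas / sum(areas)
}

#' Estimate mean display density from species fractions
#'
#' The modified fraction is the summed fraction of all non-pVIII species
#' (DBCO-pVIII and conjugates); the mean density is that fraction times the
#' available pVIII copies, rounded to the nearest integer. Estimating at the
#' DBCO stage avoids the sialylation ionization bias of conjugate peaks.
#'
#' @param fractions Named fractions (from [quantify_species()]).
#' @param species The [species_model()] list used for the fit (to resolve
#'   classes); optional when `fractions` is named with a `"pviii"` entry.
#' @param available pVIII copies per virion.
#' @return List of class `density_estimate`: `modified_fraction`,
#'   `mean_density`, `available_pviii`.
#' @export
estimate_density <- function(fractions, species = NULL,
                             available = AVAILABLE_PVIII) {
  if (any(fractions < -1e-9)) stop("negative fraction")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  if (!is.null(species)) {
    cls <- stats::setNames(vapply(species, `[[`, character(1), "class"),
                           vapply(species, `[[`, character(1), "name"))
    unmod <- names(fractions)[cls[names(fractions)] == "pviii"]
  } else {
    unmod <- intersect(names(fractions), "pviii")
  }
  modified <- 1 - sum(fractions[unmod])
  structure(list(modified_fraction = modified,
                 mean_density = round(modified * available),
                 available_pviii = as.integer(available)),
            class = "density_estimate")
}

#' Track enzymatic conversion over a spectral time course
#'
#' @param spectra List of `liga_spectrum` objects with strictly increasing
#'   `time` fields (hours), or a list of `list(time=, spectrum=)` pairs.
#' @param species [species_model()] list for [fit_peaks()].
#' @param preprocess Apply [preprocess_spectrum()] first.
#' @param ghost_correct Passed to [quantify_species()].
#' @param ... Passed to [fit_peaks()].
#' @return `data.frame`: `time` plus one percent column per non-ghost
#'   species; rows sum to 100.
#' @export
conversion_timecourse <- function(spectra, species, preprocess = TRUE,
                                  ghost_correct = TRUE, ...) {
  if (length(spectra) < 2L) stop("need at least two timepoints")
  get_time <- function(s) if (inherits(s, "liga_spectrum")) s$time else s$time
  get_spec <- function(s) if (inherits(s, "liga_spectrum")) s else s$spectrum
  times <- vapply(spectra, get_time, numeric(1))
  if (is.unsorted(times, strictly = TRUE)) stop("timepoints must be strictly increasing")
  keep <- vapply(species, function(s) is.null(s$ghost_parent), logical(1))
  keep_names <- vapply(species[keep], `[[`, character(1), "name")
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- get_spec(spectra[[i]])
    if (preprocess) sp <- preprocess_spectrum(sp)
    fr <- quantify_species(fit_peaks(sp, species, ...), ghost_correct = ghost_correct)
    fr <- fr[keep_names] / sum(fr[keep_names])
    c(time = times[i], 100 * fr)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time", keep_names)
  out
}
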