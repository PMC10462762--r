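# Direct ESI-MS affinity measurements for 1:1 protein-glycan binding.
#
# The abundance ratio R of ligand-bound to free protein, summed over charge
# states of charge-state-normalized peak areas, equals the solution
# concentration ratio [PL]/[P]. The fraction bound R/(R+1) follows the
# closed-form 1:1 equilibrium isotherm in the initial ligand concentration
# [L]0, from which the dissociation constant Kd is fitted.

#' Bound/free abundance ratio from charge-state-normalized peak areas
#'
#' `R = sum(Ab[PL]) / sum(Ab[P])` across charge states; invariant to a
#' common rescaling of all areas.
#'
#' @param pl_areas Areas of the protein-ligand complex per charge state.
#' @param p_areas Areas of the free protein per charge state.
#' @return The abundance ratio R.
#' @export
abundance_ratio <- function(pl_areas, p_areas) {
  if (any(pl_areas < 0) || any(p_areas < 0)) stop("areas must be >= 0")
  tot_p <- sum(p_areas)
  if (tot_p <= 0) stop("zero total free-protein abundance")
  sum(pl_areas) / tot_p
}

#' Fraction of protein bound at equilibrium (1:1 binding)
#'
#' Closed form of the 1:1 equilibrium:
#' \deqn{f = \frac{P_0 + L_0 + K_d - \sqrt{(K_d - L_0 + P_0)^2 + 4 K_d L_0}}{2 P_0}}
#' Monotone increasing in `L0`, decreasing in `Kd`; always in `[0, 1]`.
#'
#' @param P0 Initial protein concentration (uM), > 0.
#' @param L0 Initial ligand concentration(s) (uM), >= 0.
#' @param Kd Dissociation constant (uM), >= 0.
#' @return Fraction bound, same length as `L0`.
#' @export
fraction_bound <- function(P0, L0, Kd) {
  if (any(P0 <= 0)) stop("P0 must be > 0")
  if (any(L0 < 0) || any(Kd < 0)) stop("L0 and Kd must be >= 0")
  f <- (P0 + L0 + Kd - sqrt((Kd - L0 + P0)^2 + 4 * Kd * L0)) / (2 * P0)
  pmin(pmax(f, 0), 1)
}

#' Assemble a titration series
#' @param P0 Initial protein concentration (uM).
#' @param L0 Initial ligand concentrations (uM).
#' @param R Bound/free abundance ratios (>= 0).
#' @export
titration_series <- function(P0, L0, R) {
  stopifnot_scalar_number(P0, "P0", lower = 1e-12)
  if (length(L0) != length(R)) stop("L0 and R lengths differ")
  if (any(L0 < 0) || any(R < 0)) stop("L0 and R must be >= 0")
  structure(list(P0 = P0, points = data.frame(L0 = L0, R = R)),
            class = "titration_series")
}

#' Read a titration CSV (columns L0, R)
#' @param path CSV path.
#' @param P0 Initial protein concentration (uM).
#' @export
read_titration <- function(path, P0) {
  df <- utils::read.csv(path)
  if (!all(c("L0", "R") %in% names(df))) stop("titration CSV needs columns L0, R")
  titration_series(P0, df$L0, df$R)
}

#' Fit the dissociation constant from a titration series
#'
#' Nonlinear least squares of the fraction bound `R/(R+1)` against the 1:1
#' isotherm [fraction_bound()], with uniform weights. `Kd` is parameterized
#' on the log scale (positivity enforced); initialization is a log-grid
#' search over `[1e-3, 1e4]` uM. The standard error comes from the Jacobian
#' of the fit, back-transformed by the delta method.
#'
#' @param series A [titration_series()] with at least 3 points spanning at
#'   least a 4-fold `L0` range.
#' @param grid_points Size of the initialization grid.
#' @return List of class `kd_fit`: `Kd` (uM), `se`, `rss`, `converged`,
#'   `n_points`.
#' @export
fit_kd <- function(series, grid_points = 60L) {
  pts <- series$points
  if (nrow(pts) < 3L) stop("need at least 3 titration points")
  l_pos <- pts$L0[pts$L0 > 0]
  if (length(l_pos) < 2L || max(l_pos) / min(l_pos) < 4)
    stop("titration must span at least a 4-fold L0 range")
  y <- pts$R / (pts$R + 1)
  P0 <- series$P0

  rss_of <- function(lkd) sum((y - fraction_bound(P0, pts$L0, exp(lkd)))^2)
  grid <- seq(log(1e-3), log(1e4), length.out = grid_points)
  grid_rss <- vapply(grid, rss_of, numeric(1))
  lkd0 <- grid[which.min(grid_rss)]

  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(lkd = lkd0),
                       fn = function(par) y - fraction_bound(P0, pts$L0, exp(par[1])),
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-12,
                                                            ptol = 1e-12)),
    error = function(e) NULL)

  if (is.null(fit) || fit$info %in% c(0, 5)) {
    return(structure(list(Kd = exp(lkd0), se = NA_real_,
                          rss = min(grid_rss), converged = FALSE,
                          n_points = nrow(pts)), class = "kd_fit"))
  }
  lkd <- fit$par[["lkd"]]
  rss <- sum(fit$fvec^2)
  # SE from the Jacobian (central differences at the solution), using the
  # heteroscedasticity-robust HC3 sandwich: abundance noise is multiplicative
  # in R, so residual variance in fraction-bound space varies along the
  # curve. Delta method back to the Kd scale.
  h <- 1e-5
  jac <- (fraction_bound(P0, pts$L0, exp(lkd + h)) -
            fraction_bound(P0, pts$L0, exp(lkd - h))) / (2 * h)
  resid <- y - fraction_bound(P0, pts$L0, exp(lkd))
  hii <- jac^2 / sum(jac^2)
  se_lkd <- tryCatch(sqrt(sum(jac^2 * (resid / (1 - hii))^2)) / sum(jac^2),
                     error = function(e) NA_real_)
  structure(list(Kd = exp(lkd), se = exp(lkd) * se_lkd, rss = rss,
                 converged = TRUE, n_points = nrow(pts)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g uM (se %.3g), RSS %.3g, %d points%s\n",
              x$Kd, x$se, x$rss, x$n_points,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
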