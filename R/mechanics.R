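#' Strain-energy density transmitted between cells
#'
#' The strain energy density sensed at distance `dist` from a cell of
#' amplitude `M0` decays exponentially with decay factor
#' `lambda = E_s / E_c` scaled by the cell radius:
#' `M(dist) = M0 * exp(-lambda * dist / R)`. Contributions below the runtime
#' detection cutoff `eps` are clamped to zero (the default cutoff is 0).
#'
#' @param M0 strain-energy amplitude at the source, kg·um/min^2.
#' @param lambda attenuation ratio `E_s / E_c`, dimensionless.
#' @param dist distance(s) from the source centre, um (vectorised).
#' @param R cell radius, um.
#' @param eps runtime detection cutoff; values `< eps` return 0.
#' @return Energy density, kg·um/min^2 (vectorised over `dist`).
#' @examples
#' pairwise_energy(2.596e-2, 10, 30, 2.5) # ~1.99e-54
#' @export
pairwise_energy <- function(M0, lambda, dist, R, eps = 0) {
  if (R <= 0) stop("'R' must be positive", call. = FALSE)
  if (any(dist < 0)) stop("'dist' must be non-negative", call. = FALSE)
  v <- M0 * exp(-lambda * dist / R)
  if (eps > 0) v[v < eps] <- 0
  v
}

#' Detection threshold for remote mechanical signals
#'
#' The minimum detectable strain-energy density, defined by evaluating the
#' decay law at the largest detection distance `d_hat`:
#' `eps = M0 * exp(-lambda * d_hat / R)`. With the calibrated amplitude,
#' `lambda = 10`, `d_hat = 30` um and `R = 2.5` um this is about
#' `1.99e-54` kg·um/min^2; the runtime cutoff actually applied defaults to 0
#' since double precision underflows far above a meaningful scale here.
#'
#' @param M0 strain-energy amplitude, kg·um/min^2.
#' @param lambda attenuation ratio.
#' @param d_hat largest detection distance, um; must be positive (0 allowed
#'   for the degenerate identity `eps = M0`).
#' @param R cell radius, um.
#' @return The threshold energy density.
#' @export
detection_threshold <- function(M0, lambda, d_hat, R) {
  if (d_hat < 0) stop("'d_hat' must be non-negative", call. = FALSE)
  if (R <= 0) stop("'R' must be positive", call. = FALSE)
  M0 * exp(-lambda * d_hat / R)
}

#' Sensed mechanical stimulus of one cell
#'
#' Sums the strain-energy contributions of every other epithelial/cancer
#' cell at the position of cell `i`, and builds the migration direction as
#' the normalized weighted sum of unit vectors pointing *toward* each
#' neighbour, with weights equal to the neighbour's transmitted energy
#' density. Only this sign convention balances the contact repulsion into
#' the two-cell equilibrium reported for the model.
#'
#' @param i row index (not id) of the focal cell in `cells`.
#' @param cells a cell population `data.frame` of live epithelial/cancer
#'   cells (see [cell_population()]).
#' @param params a [model_params()] object.
#' @return A list with `M_total` (own amplitude included), `M_remote`
#'   (neighbours only), `z_hat` (unit direction, or `NULL` when no remote
#'   signal) and `alpha = beta R^3 / (mu F)`.
#' @export
sensed_stimulus <- function(i, cells, params = model_params()) {
  if (any(cells$phenotype == "tcell")) {
    stop("population must contain only epithelial/cancer cells", call. = FALSE)
  }
  if (anyDuplicated(cells$id)) {
    stop("population contains a duplicated cell id", call. = FALSE)
  }
  dx <- cells$x - cells$x[i]
  dy <- cells$y - cells$y[i]
  d <- sqrt(dx^2 + dy^2)
  keep <- seq_len(nrow(cells)) != i & d <= params$d_hat
  w <- pairwise_energy(params$M0, params$lambda_att, d[keep], params$R,
                       params$eps_runtime)
  M_remote <- sum(w)
  z <- c(sum(w * dx[keep] / d[keep]), sum(w * dy[keep] / d[keep]))
  nz <- sqrt(sum(z^2))
  # symmetric arrangements cancel the resultant only to round-off, so a
  # direction is reported only when it is numerically meaningful
  list(
    M_total = params$M0 + M_remote,
    M_remote = M_remote,
    z_hat = if (nz > 1e-12 * M_remote) z / nz else NULL,
    alpha = params$beta * params$R^3 / (params$mu * params$F_traction)
  )
}

#' Deterministic migration drift of an epithelial/cancer cell
#'
#' `alpha * max(net_energy, 0) * z_hat`, um/min. The attraction term is
#' active only while the contact-corrected net energy is positive; the
#' repulsive branch (negative net energy) is resolved against the contacting
#' partners by the integrator.
#'
#' @param stim result of [sensed_stimulus()].
#' @param net_energy contact-corrected net energy (drift variant), see
#'   [net_energy()].
#' @param alpha mobility, defaults to `stim$alpha`.
#' @return A length-2 displacement rate vector, um/min.
#' @export
migration_drift <- function(stim, net_energy, alpha = stim$alpha) {
  if (is.null(stim$z_hat) || net_energy <= 0) return(c(0, 0))
  alpha * net_energy * stim$z_hat
}
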