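#' Adaptive time step
#'
#' `dt = min(dt_max, R / (2 max_speed))`: no cell may travel more than half
#' its radius (a quarter diameter) per step, which also keeps the explicit
#' scheme stable. With vanishing speeds the default step `dt_max` applies.
#'
#' @param max_speed largest deterministic cell speed, um/min.
#' @param R radius of the epithelial/cancer cells, um.
#' @param dt_max default (maximum) step, min.
#' @return Step length, min.
#' @export
choose_dt <- function(max_speed, R, dt_max = 0.1) {
  if (max_speed < 0) stop("'max_speed' must be non-negative", call. = FALSE)
  if (max_speed == 0) return(dt_max)
  min(dt_max, R / (2 * max_speed))
}

#' Mechanical state of a mixed population
#'
#' Evaluates, for every cell, the remote stimulus, total stimulus, contact
#' sums, gating energy and the deterministic velocity of the
#' epithelial/cancer cells (attraction along the energy-weighted direction
#' while the drift net energy is positive, repulsion along the
#' contact-weighted away direction while it is negative). Contacts are
#' enumerated across the whole population including T cells; remote
#' mechanotactic signals are exchanged among epithelial/cancer cells only.
#'
#' @param cells cell population `data.frame`.
#' @param params a [model_params()] object.
#' @return A list: `M_remote`, `M_total`, `contact_sum`, `gate`
#'   (all length `nrow(cells)`; gate/remote are `NA` for T cells),
#'   `velocity` (`n x 2`, zero rows for T cells), `max_speed`
#'   (over epithelial/cancer cells), `pairs` (contacting pairs as parallel
#'   vectors `a, b, h, M_contact, ux, uy`), and `alpha` per cell.
#' @export
mechanics_state <- function(cells, params = model_params()) {
  n <- nrow(cells)
  big <- cells$phenotype != "tcell"
  k <- pair_kernel_cpp(cells$x, cells$y, cells$radius, big,
                       params$M0, params$lambda_att, params$R,
                       params$d_hat, params$eps_runtime, params$E_c)
  pairs <- k[c("a", "b", "h", "M_contact", "ux", "uy")]
  csum <- k$csum
  alpha <- params$beta * cells$radius^3 / (params$mu * params$F_traction)

  vel <- matrix(0, n, 2L)
  zmat <- cbind(k$zx, k$zy)
  M_remote <- ifelse(big, k$M_remote, NA_real_)
  M_total <- ifelse(big, params$M0 + M_remote, NA_real_)
  gate <- ifelse(big, abs(M_total - csum), NA_real_)
  rep_res <- cbind(k$repx, k$repy)
  mhat <- ifelse(big, M_remote - csum, 0)
  znorm <- sqrt(rowSums(zmat^2))
  att <- big & mhat > 0 & znorm > 0
  if (any(att)) {
    vel[att, ] <- (alpha[att] * mhat[att] / znorm[att]) * zmat[att, , drop = FALSE]
  }
  rnorm2 <- sqrt(rowSums(rep_res^2))
  repm <- big & mhat < 0 & rnorm2 > 0
  if (any(repm)) {
    vel[repm, ] <- (alpha[repm] * -mhat[repm] / rnorm2[repm]) *
      rep_res[repm, , drop = FALSE]
  }
  speeds <- sqrt(rowSums(vel^2))
  list(M_remote = M_remote, M_total = M_total, contact_sum = csum,
       gate = gate, velocity = vel,
       max_speed = if (any(big)) max(speeds[big]) else 0,
       pairs = pairs, alpha = alpha)
}

.clamp_and_reflect <- function(old, disp, cap, boundary_radius) {
  nrm <- sqrt(rowSums(disp^2))
  f <- ifelse(nrm > cap, cap / nrm, 1)
  new <- old + disp * f
  if (is.finite(boundary_radius)) {
    r <- sqrt(rowSums(new^2))
    out <- r > boundary_radius
    if (any(out)) {
      new[out, ] <- new[out, ] * ((2 * boundary_radius - r[out]) / r[out])
    }
  }
  new
}

#' Euler--Maruyama step for epithelial and cancer cells
#'
#' Moves every epithelial/cancer cell by the lagged deterministic velocity
#' (attraction/repulsion evaluated at the previous positions) times `dt`
#' plus the Wiener increment `sqrt(2 D) dW` with per-component variance
#' `dt`. Each displacement is clamped to `R / 2`; positions leaving the
#' circular computational boundary are reflected radially. T-cell rows are
#' returned unchanged.
#'
#' @param cells cell population `data.frame`.
#' @param params a [model_params()] object.
#' @param dt step length, min.
#' @param state optional precomputed [mechanics_state()].
#' @param noise logical; disable to integrate the drift alone.
#' @param boundary_radius reflecting boundary radius, um (`Inf` to disable).
#' @return The population with updated positions.
#' @export
step_epithelial_cancer <- function(cells, params = model_params(), dt = 0.1,
                                   state = NULL, noise = TRUE,
                                   boundary_radius = Inf) {
  big <- which(cells$phenotype != "tcell")
  if (!length(big)) return(cells)
  if (is.null(state)) state <- mechanics_state(cells, params)
  disp <- state$velocity[big, , drop = FALSE] * dt
  if (noise) {
    disp <- disp + sqrt(2 * params$D) *
      matrix(stats::rnorm(2L * length(big), sd = sqrt(dt)), ncol = 2L)
  }
  new <- .clamp_and_reflect(cbind(cells$x[big], cells$y[big]), disp,
                            params$R / 2, boundary_radius)
  if (any(!is.finite(new))) {
    stop("non-finite position for cell id ",
         cells$id[big][which(!is.finite(rowSums(new)))[1L]], call. = FALSE)
  }
  cells$x[big] <- new[, 1L]
  cells$y[big] <- new[, 2L]
  cells
}

#' Euler--Maruyama step for T cells
#'
#' T cells move by chemotaxis along the chemokine gradient and random walk,
#' both filtered through the stromal orientation tensor evaluated at the
#' previous position, minus the pairwise contact repulsion:
#' `dr = Psi (beta grad(c) dt + sqrt(2D) dW) - sum_l alpha_t M^{jl} u_l dt`.
#' Displacements are clamped to `R_t / 2` and reflected at the boundary.
#' Epithelial/cancer rows are returned unchanged.
#'
#' @param cells cell population `data.frame` (mixed phenotypes allowed).
#' @param sources a [chemokine_sources()] object (live cancer cells).
#' @param geom a [stroma_geometry()] object.
#' @param params a [model_params()] object.
#' @param dt step length, min.
#' @param state optional precomputed [mechanics_state()] (for the contacts).
#' @param noise logical; disable to integrate the drift alone.
#' @param boundary_radius reflecting boundary radius, um.
#' @return The population with updated T-cell positions.
#' @export
step_tcells <- function(cells, sources, geom, params = model_params(),
                        dt = 0.1, state = NULL, noise = TRUE,
                        boundary_radius = Inf) {
  tc <- which(cells$phenotype == "tcell")
  if (!length(tc)) return(cells)
  if (is.null(state)) state <- mechanics_state(cells, params)
  alpha_t <- params$beta * params$R_t^3 / (params$mu * params$F_traction)

  grad <- chemokine_gradient(cbind(cells$x[tc], cells$y[tc]), sources)
  dW <- if (noise) {
    matrix(stats::rnorm(2L * length(tc), sd = sqrt(dt)), ncol = 2L)
  } else matrix(0, length(tc), 2L)

  # pairwise repulsion on T cells (away from every contacting partner)
  rep_rate <- matrix(0, nrow(cells), 2L)
  if (length(state$pairs$a)) {
    p <- state$pairs
    idx <- c(p$a, p$b)
    contrib <- alpha_t *
      cbind(c(-p$M_contact * p$ux, p$M_contact * p$ux),
            c(-p$M_contact * p$uy, p$M_contact * p$uy))
    istc <- cells$phenotype[idx] == "tcell"
    if (any(istc)) {
      acc <- rowsum(contrib[istc, , drop = FALSE], group = idx[istc])
      rep_rate[as.integer(rownames(acc)), ] <- acc
    }
  }

  # apply the orientation tensor row-wise:
  # Psi v = v0 lambda2 v + v0 (e^{-ks} lambda1 - lambda2) (w1.v) w1
  v <- params$beta * grad * dt + sqrt(2 * params$D) * dW
  relx <- cells$x[tc] - geom$center[1L]
  rely <- cells$y[tc] - geom$center[2L]
  r <- sqrt(relx^2 + rely^2)
  w1x <- ifelse(r > 0, relx / r, 1)
  w1y <- ifelse(r > 0, rely / r, 0)
  s <- ifelse(r < geom$islet_radius, 0,
              pmin(pmax(geom$outer_radius - r, 0), geom$thickness))
  radial_fac <- geom$v0 * exp(-geom$k * s) * geom$lambda1
  tang_fac <- geom$v0 * geom$lambda2
  dotp <- w1x * v[, 1L] + w1y * v[, 2L]
  disp <- cbind(tang_fac * v[, 1L] + (radial_fac - tang_fac) * dotp * w1x,
                tang_fac * v[, 2L] + (radial_fac - tang_fac) * dotp * w1y) +
    rep_rate[tc, , drop = FALSE] * dt
  new <- .clamp_and_reflect(cbind(cells$x[tc], cells$y[tc]), disp,
                            params$R_t / 2, boundary_radius)
  cells$x[tc] <- new[, 1L]
  cells$y[tc] <- new[, 2L]
  cells
}
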