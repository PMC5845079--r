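#' Annular stromal collagen geometry
#'
#' The desmoplastic stroma is an annulus of aligned collagen fibers wrapped
#' around the islet, fibers parallel to the islet boundary. A T cell at
#' penetration depth `s` (measured inward from the outer stromal boundary)
#' has its radial displacement attenuated by `exp(-k s)` while tangential
#' motion is untouched; outside the annulus, and inside the islet proper,
#' motion is isotropic.
#'
#' @param center islet centre, um.
#' @param islet_radius inner stroma boundary, um.
#' @param thickness stroma thickness, um.
#' @param k anisotropy attenuation constant.
#' @param v0 baseline speed multiplier.
#' @param lambda1,lambda2 radial/tangential eigen-weights.
#' @return An object of class `stroma_geometry` with the derived
#'   `outer_radius`.
#' @export
stroma_geometry <- function(center = c(0, 0), islet_radius = 35,
                            thickness = 15, k = 0, v0 = 1,
                            lambda1 = 1, lambda2 = 1) {
  if (thickness <= 0) stop("'thickness' must be positive", call. = FALSE)
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  structure(list(center = center, islet_radius = islet_radius,
                 thickness = thickness, k = k, v0 = v0,
                 lambda1 = lambda1, lambda2 = lambda2,
                 outer_radius = islet_radius + thickness),
            class = "stroma_geometry")
}

#' Penetration depth into the stroma
#'
#' `s = clamp(outer_radius - ||x - center||, 0, thickness)`: zero at and
#' outside the outer boundary, saturating at the full thickness at the inner
#' boundary.
#'
#' @param x length-2 position or `n x 2` matrix, um.
#' @param geom a [stroma_geometry()] object.
#' @return Penetration depth(s), um.
#' @export
penetration_depth <- function(x, geom) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  r <- sqrt((xm[, 1L] - geom$center[1L])^2 + (xm[, 2L] - geom$center[2L])^2)
  pmin(pmax(geom$outer_radius - r, 0), geom$thickness)
}

#' Radial speed attenuation
#'
#' `v = v0 * exp(-k s)`; `k = 0` recovers the isotropic case.
#'
#' @param v0 baseline speed multiplier.
#' @param k attenuation constant.
#' @param s penetration depth, um.
#' @return Attenuated multiplier (vectorised over `s`).
#' @export
radial_speed <- function(v0, k, s) {
  if (any(s < 0)) stop("'s' must be non-negative", call. = FALSE)
  v0 * exp(-k * s)
}

#' Orientation tensor of the stromal fiber field
#'
#' The symmetric 2x2 tensor
#' `Psi = v0 e^{-ks} lambda1 w1 w1' + v0 lambda2 w2 w2'`, with `w1` the local
#' radial and `w2` the tangential unit vector. With the default weights it
#' reduces to `v0 * I` wherever `s = 0`, and inside the islet proper
#' (`||x|| < islet_radius`) the fiber field does not exist, so the identity
#' scaling is restored there too.
#'
#' @param x length-2 position, um; must differ from the centre.
#' @param geom a [stroma_geometry()] object.
#' @return A 2x2 symmetric matrix.
#' @export
orientation_tensor <- function(x, geom) {
  dx <- x[1L] - geom$center[1L]
  dy <- x[2L] - geom$center[2L]
  r <- sqrt(dx^2 + dy^2)
  if (r == 0) stop("radial direction undefined at the islet centre",
                   call. = FALSE)
  inside_islet <- r < geom$islet_radius
  s <- if (inside_islet) 0 else penetration_depth(x, geom)
  w1 <- c(dx, dy) / r
  w2 <- c(-w1[2L], w1[1L])
  geom$v0 * exp(-geom$k * s) * geom$lambda1 * tcrossprod(w1) +
    geom$v0 * geom$lambda2 * tcrossprod(w2)
}
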