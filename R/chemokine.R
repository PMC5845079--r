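#' Chemokine point sources
#'
#' Live cancer cells secreting one chemokine species at rate `gamma`. The
#' steady state of the secretion--diffusion balance in the plane is the
#' logarithmic free-space kernel, so concentration and gradient are closed
#' forms summed over sources. Distances are clamped below by `r_min` to
#' regularize the kernel's singularity at a source centre.
#'
#' @param positions two-column matrix (or data.frame) of source positions, um.
#' @param gamma secretion rate per source, 1/min.
#' @param D_c chemokine diffusivity, um^2/min.
#' @param r_min regularization distance, um (default: the T-cell radius).
#' @return An object of class `chemokine_sources`.
#' @export
chemokine_sources <- function(positions, gamma = 10, D_c = 0.001, r_min = 2) {
  positions <- as.matrix(positions)
  if (length(positions) && ncol(positions) != 2L) {
    stop("'positions' must have two columns", call. = FALSE)
  }
  if (r_min <= 0) stop("'r_min' must be positive", call. = FALSE)
  structure(list(positions = positions, gamma = gamma, D_c = D_c,
                 r_min = r_min),
            class = "chemokine_sources")
}

#' Steady-state chemokine concentration
#'
#' `c(x) = -sum_j gamma / (2 pi D_c) * log(max(||x - r_j||, r_min))`
#' (arbitrary concentration units; only the gradient enters the dynamics).
#'
#' @param x length-2 position, um.
#' @param sources a [chemokine_sources()] object.
#' @return Scalar concentration.
#' @export
chemokine_concentration <- function(x, sources) {
  if (!nrow(sources$positions)) return(0)
  d <- sqrt((sources$positions[, 1L] - x[1L])^2 +
            (sources$positions[, 2L] - x[2L])^2)
  -sum(sources$gamma / (2 * pi * sources$D_c) * log(pmax(d, sources$r_min)))
}

#' Analytic chemokine gradient
#'
#' `grad c(x) = -sum_j gamma / (2 pi D_c) * (x - r_j) / ||x - r_j||^2`, with
#' the distance clamped below by `r_min`; the gradient points toward each
#' source.
#'
#' @param x length-2 position, um, or an `n x 2` matrix of positions.
#' @param sources a [chemokine_sources()] object.
#' @return Gradient vector (or `n x 2` matrix), concentration units per um.
#' @export
chemokine_gradient <- function(x, sources) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  out <- matrix(0, nrow(xm), 2L)
  if (nrow(sources$positions)) {
    coef <- sources$gamma / (2 * pi * sources$D_c)
    dx <- outer(xm[, 1L], sources$positions[, 1L], "-")
    dy <- outer(xm[, 2L], sources$positions[, 2L], "-")
    d2 <- pmax(dx * dx + dy * dy, sources$r_min^2)
    out <- cbind(-rowSums(coef * dx / d2), -rowSums(coef * dy / d2))
  }
  if (is.matrix(x)) out else out[1L, ]
}

#' Rasterize the chemokine field on a grid
#'
#' Convenience export for visualization: evaluates the concentration on a
#' regular grid and returns a long-format data.frame (or writes CSV).
#'
#' @param sources a [chemokine_sources()] object.
#' @param xlim,ylim ranges, um.
#' @param n grid points per axis.
#' @param path optional CSV output path.
#' @return `data.frame(x, y, concentration)`.
#' @export
chemokine_raster <- function(sources, xlim = c(-50, 50), ylim = c(-50, 50),
                             n = 51L, path = NULL) {
  gx <- seq(xlim[1L], xlim[2L], length.out = n)
  gy <- seq(ylim[1L], ylim[2L], length.out = n)
  g <- expand.grid(x = gx, y = gy)
  g$concentration <- vapply(seq_len(nrow(g)), function(i)
    chemokine_concentration(c(g$x[i], g$y[i]), sources), numeric(1))
  if (!is.null(path)) utils::write.csv(g, path, row.names = FALSE)
  g
}
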