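#' Indentation distance of two overlapping cells
#'
#' `h = max(R_a + R_b - dist, 0)`, um; for equal radii this is the published
#' `max(2R - ||r_ij||, 0)` overlap.
#'
#' @param dist centre distance(s), um (vectorised).
#' @param R_a,R_b radii of the two cells, um.
#' @return Indentation distance(s), um.
#' @export
overlap <- function(dist, R_a, R_b = R_a) {
  if (any(dist < 0)) stop("'dist' must be non-negative", call. = FALSE)
  pmax(R_a + R_b - dist, 0)
}

#' Invagination (contact) strain-energy density
#'
#' `M_contact = (4 / (15 sqrt(2))) * (E_c / pi) * (h / R)^(5/2)`. The kink at
#' `h = 0` makes the right-hand side only C^0 there, which is the reason the
#' integrator is restricted to the Euler--Maruyama scheme. For contacts of
#' unequal cells (T cell against a large cell) pass the smaller radius as
#' `R`.
#'
#' @param h indentation distance(s), um.
#' @param R reference radius, um.
#' @param E_c cell elastic modulus, kg/(um·min^2).
#' @return Energy density, kg·um/min^2 (vectorised over `h`).
#' @export
contact_energy <- function(h, R, E_c = 0.5e-5) {
  if (any(R <= 0)) stop("'R' must be positive", call. = FALSE)
  if (any(h < 0)) stop("'h' must be non-negative", call. = FALSE)
  if (any(h > 2 * R)) {
    warning("indentation exceeds the cell diameter; cells nearly coincide")
  }
  4 / (15 * sqrt(2)) * (E_c / pi) * (h / R)^2.5
}

#' Net (contact-corrected) strain-energy density
#'
#' Subtracts the summed contact energies from the sensed stimulus. Two
#' variants are used in the model: the *drift* variant
#' (`M_remote - sum(M_contact)`, signed, drives migration) and the *gating*
#' variant (`|M_total - sum(M_contact)|`, compared against the stochastic
#' event thresholds).
#'
#' @param stimulus `M_remote` (drift) or `M_total` (gating), kg·um/min^2.
#' @param contact_sum summed contact energy over all contacting partners.
#' @param variant `"drift"` (signed) or `"gate"` (absolute value).
#' @return Net energy density.
#' @export
net_energy <- function(stimulus, contact_sum = 0,
                       variant = c("drift", "gate")) {
  variant <- match.arg(variant)
  v <- stimulus - contact_sum
  if (variant == "gate") abs(v) else v
}

#' Two-cell equilibrium overlap
#'
#' Solves the balance between the remote attraction transmitted by the
#' partner, `M0 * exp(-lambda (2R - h) / R)`, and the contact repulsion
#' `contact_energy(h)`, for the indentation `h` on `(0, 2R)`. The balance
#' curve crosses zero twice under the calibrated parameters; the physically
#' reported equilibrium (the *maximum* equilibrium overlap) is the upper
#' crossing, so the bracket scan keeps the uppermost sign change and refines
#' it by bisection to `tol`.
#'
#' @param params a [model_params()] object.
#' @param tol absolute tolerance on `h`, um.
#' @return Equilibrium indentation `h*`, um.
#' @export
equilibrium_overlap <- function(params = model_params(), tol = 1e-6) {
  R <- params$R
  f <- function(h) {
    pairwise_energy(params$M0, params$lambda_att, 2 * R - h, R) -
      contact_energy(h, R, params$E_c)
  }
  grid <- seq(tol, 2 * R - tol, length.out = 4096L)
  fg <- f(grid)
  sc <- which(fg[-1L] * fg[-length(fg)] <= 0 & is.finite(fg[-1L]))
  if (!length(sc)) {
    stop("no equilibrium: the balance has no sign change on (0, 2R)",
         call. = FALSE)
  }
  j <- max(sc)
  stats::uniroot(f, c(grid[j], grid[j + 1L]), tol = tol)$root
}

# Contact bookkeeping for a full mixed population ---------------------------

# shared hot-path kernel: all-pairs distances and contacting pairs as plain
# vectors (column-major upper triangle), no data.frame overhead
.contacts <- function(x, y, radius, E_c) {
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  d <- sqrt(dx * dx + dy * dy)
  rsum <- outer(radius, radius, "+")
  hitm <- d < rsum
  hitm[lower.tri(hitm, diag = TRUE)] <- FALSE
  hit <- which(hitm)
  if (!length(hit)) {
    return(list(a = integer(), b = integer(), h = numeric(),
                M_contact = numeric(), ux = numeric(), uy = numeric(),
                d = d, dx = dx, dy = dy))
  }
  a <- ((hit - 1L) %% n) + 1L
  b <- ((hit - 1L) %/% n) + 1L
  dd <- d[hit]
  # nearly coincident centres: clamp indentation, fixed direction convention
  h <- pmin(rsum[hit] - dd, rsum[hit] - 0.1)
  rmin <- pmin(radius[a], radius[b])
  list(a = a, b = b, h = h,
       M_contact = 4 / (15 * sqrt(2)) * (E_c / pi) * (h / rmin)^2.5,
       ux = ifelse(dd > 0, -dx[hit] / dd, 1),
       uy = ifelse(dd > 0, -dy[hit] / dd, 0),
       d = d, dx = dx, dy = dy)
}

#' Enumerate contacting pairs and their energies
#'
#' All-pairs scan over a mixed population (epithelial, cancer, T cells).
#' For unequal radii the indentation is `R_a + R_b - dist` and the reference
#' radius in the energy law is `min(R_a, R_b)`.
#'
#' @param cells a cell population `data.frame`.
#' @param params a [model_params()] object.
#' @return A `data.frame` with columns `a, b` (row indices, `a < b`),
#'   `id_a, id_b`, `h`, `M_contact`, `ux, uy` (unit vector from a toward b).
#' @export
contact_pairs <- function(cells, params = model_params()) {
  if (nrow(cells) < 2L) {
    return(data.frame(a = integer(), b = integer(), id_a = integer(),
                      id_b = integer(), h = numeric(),
                      M_contact = numeric(), ux = numeric(), uy = numeric()))
  }
  ct <- .contacts(cells$x, cells$y, cells$radius, params$E_c)
  data.frame(a = ct$a, b = ct$b,
             id_a = cells$id[ct$a], id_b = cells$id[ct$b],
             h = ct$h, M_contact = ct$M_contact,
             ux = ct$ux, uy = ct$uy)
}

#' Per-cell summed contact energy
#'
#' @param pairs output of [contact_pairs()].
#' @param n number of cells (rows) in the population the pairs refer to.
#' @return Numeric vector: `sum(M_contact)` per cell row.
#' @export
contact_sums <- function(pairs, n) {
  s <- numeric(n)
  if (length(pairs$a)) {
    acc <- rowsum(c(pairs$M_contact, pairs$M_contact),
                  group = c(pairs$a, pairs$b))
    s[as.integer(rownames(acc))] <- acc[, 1L]
  }
  s
}

#' Pairwise repulsive displacement rates
#'
#' Converts each contact into equal-and-opposite displacement rates of
#' magnitude `alpha * M_contact` directed away from the partner (the
#' dimensional repair of the published T-cell contact term, using the same
#' mobility constant as the attraction drift).
#'
#' @param pairs output of [contact_pairs()].
#' @param n number of cells in the population.
#' @param alpha mobility per cell (vector of length `n` or scalar).
#' @return An `n x 2` matrix of displacement rates, um/min.
#' @export
repulsion_rates <- function(pairs, n, alpha) {
  out <- matrix(0, n, 2L)
  if (!length(pairs$a)) return(out)
  alpha <- rep_len(alpha, n)
  for (r in seq_along(pairs$a)) {
    a <- pairs$a[r]; b <- pairs$b[r]
    u <- c(pairs$ux[r], pairs$uy[r])
    out[a, ] <- out[a, ] - alpha[a] * pairs$M_contact[r] * u
    out[b, ] <- out[b, ] + alpha[b] * pairs$M_contact[r] * u
  }
  out
}
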