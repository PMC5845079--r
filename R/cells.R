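#' Construct a cell population table
#'
#' One row per live agent: position (um), phenotype (`"epithelial"`,
#' `"cancer"` or `"tcell"`), radius, growth clock (min since birth or last
#' division), and the number of divisions performed by the lineage. Dead
#' cells are removed from the table immediately, so every row is alive.
#'
#' @param x,y numeric vectors of positions, um.
#' @param phenotype character vector, recycled.
#' @param params a [model_params()] object supplying radii.
#' @param clock growth clocks, min (recycled, default 0).
#' @param divisions divisions already performed (recycled, default 0).
#' @param id integer ids; default `seq_along(x)`.
#' @return A `data.frame` with columns `id, x, y, phenotype, radius,
#'   clock, divisions`.
#' @export
cell_population <- function(x, y, phenotype = "epithelial",
                            params = model_params(),
                            clock = 0, divisions = 0L,
                            id = seq_along(x)) {
  stopifnot(length(x) == length(y))
  phenotype <- rep_len(phenotype, length(x))
  if (!all(phenotype %in% c("epithelial", "cancer", "tcell"))) {
    stop("unknown phenotype", call. = FALSE)
  }
  data.frame(
    id = as.integer(id),
    x = as.numeric(x), y = as.numeric(y),
    phenotype = phenotype,
    radius = ifelse(phenotype == "tcell", params$R_t, params$R),
    clock = rep_len(as.numeric(clock), length(x)),
    divisions = rep_len(as.integer(divisions), length(x)),
    stringsAsFactors = FALSE
  )
}

# deterministic fixtures used throughout the tests and examples

#' Small deterministic cell configurations
#'
#' `two_cell_fixture()` places two epithelial cells a given centre distance
#' apart; `hexagon_fixture()` places one cell at the origin surrounded by six
#' cells on a regular hexagon of circumradius `spacing`.
#'
#' @param dist,spacing centre-to-centre distance, um.
#' @param params a [model_params()] object.
#' @return A cell population `data.frame` (see [cell_population()]).
#' @export
two_cell_fixture <- function(dist = 5, params = model_params()) {
  cell_population(c(0, dist), c(0, 0), "epithelial", params)
}

#' @rdname two_cell_fixture
#' @export
hexagon_fixture <- function(spacing = 5, params = model_params()) {
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  cell_population(c(0, spacing * cos(ang)), c(0, spacing * sin(ang)),
                  "epithelial", params)
}
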