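#' Physical model parameters
#'
#' Builds the validated parameter object holding every physical constant of
#' the model in a fixed kg--micrometre--minute unit system. Two quantities are
#' derived and cached: the strain-energy amplitude `M0 = F^2 / (2 pi^2 E_s R^4)`
#' and the signal attenuation ratio `lambda_att = E_s / E_c`.
#'
#' The default traction force `F` is the calibrated value `F*` for which `M0`
#' equals `2.596e-2` kg·um/min^2, the amplitude that reproduces the printed
#' detection threshold `1.99e-54` at `lambda = 10`, `d_hat = 30` um,
#' `R = 2.5` um. The literature alternatives (`F = 10`, used for the
#' simulation scenarios, and `F = (10--25)e2`) can be passed explicitly.
#'
#' @param R radius of epithelial and cancer cells, um.
#' @param R_t radius of T cells, um.
#' @param F_traction cell traction force, kg·um/min^2. Default: calibrated `F*`.
#' @param E_s substrate elastic modulus, kg/(um·min^2).
#' @param E_c cell elastic modulus, kg/(um·min^2).
#' @param beta cell mobility / chemotactic coefficient, 1/min.
#' @param mu cell--substrate friction coefficient, dimensionless.
#' @param D cell diffusivity (variance rate of the random walk), um^2/min.
#' @param D_c chemokine diffusivity, um^2/min.
#' @param gamma chemokine secretion rate per cancer cell, 1/min.
#' @param d_hat largest detection distance, um (used for the detection
#'   threshold and as the neighbour-list radius).
#' @param eps_runtime runtime detection cutoff for remote signals; default 0.
#'
#' @return An object of class `model_params`: a named list of the above plus
#'   the derived `M0` and `lambda_att`.
#' @examples
#' p <- model_params()
#' p$lambda_att # 10
#' p$M0         # 2.596e-2
#' @export
model_params <- function(R = 2.5,
                         R_t = 2,
                         F_traction = NULL,
                         E_s = 5e-5,
                         E_c = 0.5e-5,
                         beta = 1,
                         mu = 0.2,
                         D = 0.005,
                         D_c = 0.001,
                         gamma = 10,
                         d_hat = 30,
                         eps_runtime = 0) {
  for (nm in c("R", "E_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (is.null(F_traction)) {
    # calibrated F*: M0 = 2.596e-2 exactly under the supplied E_s and R
    F_traction <- sqrt(2.596e-2 * 2 * pi^2 * E_s * R^4)
  }
  vals <- list(R = R, R_t = R_t, F_traction = F_traction, E_s = E_s,
               E_c = E_c, beta = beta, mu = mu, D = D, D_c = D_c,
               gamma = gamma, d_hat = d_hat)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(eps_runtime) || eps_runtime < 0) {
    stop("model parameter 'eps_runtime' must be a non-negative number",
         call. = FALSE)
  }
  out <- c(vals, list(
    eps_runtime = eps_runtime,
    M0 = F_traction^2 / (2 * pi^2 * E_s * R^4),
    lambda_att = E_s / E_c
  ))
  class(out) <- "model_params"
  out
}

#' Scenario configuration
#'
#' Geometry, immunity level, anisotropy and run switches for one simulation
#' scenario. Defaults follow the published setup: a 35-um tumor islet wrapped
#' in a 15-um stromal annulus, weak/strong immune systems with
#' `N_s = 2 N_w` T cells, and a run horizon of 400 min.
#'
#' @param islet_radius islet (inner stroma boundary) radius, um.
#' @param stroma_thickness stromal annulus thickness, um.
#' @param k anisotropy attenuation constant (radial speed decays as
#'   `exp(-k s)` with penetration depth `s`).
#' @param immunity one of `"strong"`, `"weak"`, `"none"`.
#' @param n_tcells_weak number of T cells in the weak immune system (`N_w`).
#' @param n_tcells_strong number in the strong system; defaults to `2 * N_w`.
#' @param t_end simulated end time, min.
#' @param dt_max maximum (default) time step, min.
#' @param seed integer seed for the replicate.
#' @param packing_factor initial hexagonal lattice spacing as a fraction of
#'   the cell diameter `2R`; values below 1 start the monolayer compressed.
#' @param division_cap_epithelial maximum divisions of an epithelial lineage,
#'   in 50--100.
#' @param totals_include_tcells if `TRUE` (default) the cancer-fraction
#'   denominator counts all live cells including T cells.
#' @param F_scenario traction force used for scenario runs, kg·um/min^2.
#'   Defaults to 10, the value the source literature singles out as the
#'   reasonable choice for whole-islet simulations (see the methods
#'   vignette); set `NULL` to keep the calibrated desk value.
#' @param seed_cancer_at optional time (min) at which one central epithelial
#'   cell is switched to cancer deterministically; `NA` (default) leaves
#'   mutation fully endogenous.
#' @param tcell_spawn_margin T cells spawn on the circle
#'   `outer stroma radius + tcell_spawn_margin`, um.
#' @param tcell_homing_radius within this distance of the nearest cancer
#'   cell a T cell homes on that cell directly (near-field chemotaxis /
#'   synapse arrest), um; default two cell diameters.
#' @param boundary_margin reflecting computational boundary sits at
#'   `outer stroma radius + boundary_margin`, um.
#' @param record_every record the time series every this many steps.
#' @param early_exit stop once no cancer cell is left after the first
#'   mutation and no mutation pressure remains; default `FALSE` so that all
#'   replicates share a common time grid.
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(islet_radius = 35,
                            stroma_thickness = 15,
                            k = 0,
                            immunity = c("strong", "weak", "none"),
                            n_tcells_weak = 10,
                            n_tcells_strong = NULL,
                            t_end = 400,
                            dt_max = 0.1,
                            seed = 1L,
                            packing_factor = 0.9,
                            division_cap_epithelial = 50,
                            totals_include_tcells = TRUE,
                            F_scenario = 10,
                            seed_cancer_at = NA_real_,
                            tcell_spawn_margin = 5,
                            tcell_homing_radius = 10,
                            boundary_margin = 10,
                            record_every = 1L,
                            early_exit = FALSE) {
  immunity <- match.arg(immunity)
  if (is.null(n_tcells_strong)) n_tcells_strong <- 2L * as.integer(n_tcells_weak)
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  if (stroma_thickness <= 0 || islet_radius <= 0) {
    stop("islet radius and stroma thickness must be positive", call. = FALSE)
  }
  if (t_end < 0 || dt_max <= 0) stop("bad time settings", call. = FALSE)
  if (packing_factor <= 0) stop("'packing_factor' must be positive", call. = FALSE)
  if (division_cap_epithelial < 50 || division_cap_epithelial > 100) {
    stop("'division_cap_epithelial' must lie in [50, 100]", call. = FALSE)
  }
  out <- list(islet_radius = islet_radius,
              stroma_thickness = stroma_thickness,
              k = k, immunity = immunity,
              n_tcells_weak = as.integer(n_tcells_weak),
              n_tcells_strong = as.integer(n_tcells_strong),
              t_end = t_end, dt_max = dt_max, seed = as.integer(seed),
              packing_factor = packing_factor,
              division_cap_epithelial = as.integer(division_cap_epithelial),
              totals_include_tcells = isTRUE(totals_include_tcells),
              F_scenario = F_scenario,
              seed_cancer_at = seed_cancer_at,
              tcell_spawn_margin = tcell_spawn_margin,
              tcell_homing_radius = tcell_homing_radius,
              boundary_margin = boundary_margin,
              record_every = as.integer(record_every),
              early_exit = isTRUE(early_exit))
  class(out) <- "scenario_config"
  out
}

#' Load model and scenario configuration from a YAML file
#'
#' Key names match the argument names of [model_params()] and
#' [scenario_config()]; keys may live at the top level or under `params:` /
#' `scenario:` sections. Unknown keys raise a configuration error naming the
#' field; non-positive physical constants raise a validation error.
#'
#' @param config_source path to a YAML file, or a YAML string, or a named
#'   list already parsed.
#' @return `list(params = <model_params>, scenario = <scenario_config>)`.
#' @export
load_config <- function(config_source = NULL) {
  raw <- if (is.null(config_source)) {
    list()
  } else if (is.list(config_source)) {
    config_source
  } else if (is.character(config_source) && length(config_source) == 1L) {
    parsed <- tryCatch(
      if (file.exists(config_source)) yaml::read_yaml(config_source)
      else yaml::yaml.load(config_source),
      error = function(e) stop("configuration parse failure: ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(parsed)) list() else parsed
  } else {
    stop("configuration parse failure: unsupported source", call. = FALSE)
  }
  p_keys <- names(formals(model_params))
  s_keys <- names(formals(scenario_config))
  p_raw <- if (!is.null(raw$params)) raw$params else list()
  s_raw <- if (!is.null(raw$scenario)) raw$scenario else list()
  flat <- raw[setdiff(names(raw), c("params", "scenario"))]
  for (nm in names(flat)) {
    if (nm %in% p_keys) p_raw[[nm]] <- flat[[nm]]
    else if (nm %in% s_keys) s_raw[[nm]] <- flat[[nm]]
    else stop("configuration error: unknown field '", nm, "'", call. = FALSE)
  }
  bad_p <- setdiff(names(p_raw), p_keys)
  bad_s <- setdiff(names(s_raw), s_keys)
  if (length(bad_p) || length(bad_s)) {
    stop("configuration error: unknown field '",
         c(bad_p, bad_s)[1L], "'", call. = FALSE)
  }
  list(params = do.call(model_params, p_raw),
       scenario = do.call(scenario_config, s_raw))
}

#' Serialize the effective configuration to JSON
#'
#' Writes the full effective configuration (after defaulting and derivation)
#' so that every output directory carries an exact record of its run.
#'
#' @param params a `model_params` object.
#' @param scenario a `scenario_config` object.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
write_config_json <- function(params, scenario, path = NULL) {
  obj <- list(params = unclass(params), scenario = unclass(scenario))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (kg-um-min units)\n")
  cat(sprintf("  R = %g um, R_t = %g um, F = %g kg·um/min^2\n",
              x$R, x$R_t, x$F_traction))
  cat(sprintf("  E_s = %g, E_c = %g kg/(um·min^2)  (lambda = %g)\n",
              x$E_s, x$E_c, x$lambda_att))
  cat(sprintf("  M0 = %g kg·um/min^2, D = %g um^2/min, D_c = %g um^2/min\n",
              x$M0, x$D, x$D_c))
  cat(sprintf("  beta = %g /min, mu = %g, gamma = %g /min, d_hat = %g um\n",
              x$beta, x$mu, x$gamma, x$d_hat))
  invisible(x)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: islet %g um + stroma %g um, k = %g, immunity = %s\n",
    x$islet_radius, x$stroma_thickness, x$k, x$immunity))
  cat(sprintf("  N_w = %d, N_s = %d, t_end = %g min, seed = %d\n",
              x$n_tcells_weak, x$n_tcells_strong, x$t_end, x$seed))
  invisible(x)
}
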