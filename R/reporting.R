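#' Normal-approximation 95% confidence interval
#'
#' `mean +/- 1.96 * sd / sqrt(n)` with the sample standard deviation — the
#' normal-approximation interval (deliberately not a t-interval, matching
#' how the replicate ensembles are summarised). A single sample yields a
#' degenerate interval of zero width with a warning.
#'
#' @param samples numeric vector, `n >= 1`.
#' @return A list with `mean`, `lower`, `upper`, `n`.
#' @export
confidence_interval <- function(samples) {
  n <- length(samples)
  if (n == 0L) stop("empty sample", call. = FALSE)
  m <- mean(samples)
  if (n == 1L) {
    warning("single sample: degenerate zero-width interval")
    return(list(mean = m, lower = m, upper = m, n = 1L))
  }
  half <- 1.96 * stats::sd(samples) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Ensemble cancer-fraction series with confidence band
#'
#' Resamples every replicate's series onto a common time grid by
#' previous-value (step-function) interpolation and computes, per time
#' point, the 95% normal-approximation interval of the cancer fraction over
#' replicates. All replicates must come from the same scenario settings
#' (seed aside).
#'
#' @param summaries list of [run_simulation()] results.
#' @param times optional common time grid; defaults to the first
#'   replicate's recorded times.
#' @return `data.frame(time, mean, lower, upper)`.
#' @export
cancer_fraction_series <- function(summaries, times = NULL) {
  if (!length(summaries)) stop("no replicates supplied", call. = FALSE)
  key <- function(s) {
    sc <- s$scenario
    paste(sc$islet_radius, sc$stroma_thickness, sc$k, sc$immunity,
          sc$n_tcells_weak, sc$t_end, sc$packing_factor)
  }
  if (length(unique(vapply(summaries, key, character(1)))) != 1L) {
    stop("replicates come from mismatched scenarios", call. = FALSE)
  }
  if (is.null(times)) times <- summaries[[1L]]$series$time
  vals <- vapply(summaries, function(s) {
    stats::approx(s$series$time, s$series$cancer_fraction, xout = times,
                  method = "constant", f = 0, rule = 2)$y
  }, numeric(length(times)))
  vals <- matrix(vals, nrow = length(times))
  n <- ncol(vals)
  m <- rowMeans(vals)
  half <- if (n > 1L) 1.96 * apply(vals, 1L, stats::sd) / sqrt(n) else 0
  data.frame(time = times, mean = m, lower = m - half, upper = m + half)
}

#' Write the recorded time series to CSV
#'
#' Columns `time_min, n_epithelial, n_cancer, n_tcell, cancer_fraction`;
#' [read_series_csv()] round-trips the file back to the in-memory series.
#'
#' @param summary a [run_simulation()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(summary, path) {
  s <- summary$series
  names(s)[names(s) == "time"] <- "time_min"
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  s <- utils::read.csv(path)
  names(s)[names(s) == "time_min"] <- "time"
  s
}

#' Write a cell snapshot to CSV
#'
#' Columns `id, x_um, y_um, phenotype, radius_um`.
#'
#' @param cells a cell population `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot_csv <- function(cells, path) {
  utils::write.csv(
    data.frame(id = cells$id, x_um = cells$x, y_um = cells$y,
               phenotype = cells$phenotype, radius_um = cells$radius),
    path, row.names = FALSE)
  invisible(path)
}

#' Summarise a k-sweep into per-k ensemble statistics
#'
#' @param sweep output of [k_sweep()].
#' @return One row per `k`: mean and 95% CI of the immune response time and
#'   of the maximum cancer fraction, plus the number of censored replicates.
#' @export
summarize_sweep <- function(sweep) {
  do.call(rbind, lapply(split(sweep, sweep$k), function(g) {
    ci_t <- confidence_interval(g$immune_response_time)
    ci_f <- confidence_interval(g$max_cancer_fraction)
    data.frame(k = g$k[1L], n = nrow(g),
               response_mean = ci_t$mean, response_lower = ci_t$lower,
               response_upper = ci_t$upper,
               n_censored = sum(g$response_censored),
               max_fraction_mean = ci_f$mean,
               max_fraction_lower = ci_f$lower,
               max_fraction_upper = ci_f$upper)
  }))
}

#' Desk-scale calibration report
#'
#' Composes the closed-form diagnostics of a parameter set: the amplitude
#' `M0`, the detection threshold at `d_hat`, the two-cell equilibrium
#' overlap and the total sensed stimulus at that equilibrium.
#'
#' @param params a [model_params()] object.
#' @return A named list; printed by the `calibrate` CLI subcommand.
#' @export
calibration_report <- function(params = model_params()) {
  hstar <- equilibrium_overlap(params)
  list(
    M0 = params$M0,
    lambda = params$lambda_att,
    detection_threshold = detection_threshold(params$M0, params$lambda_att,
                                              params$d_hat, params$R),
    equilibrium_overlap = hstar,
    equilibrium_stimulus = params$M0 +
      pairwise_energy(params$M0, params$lambda_att, 2 * params$R - hstar,
                      params$R)
  )
}
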