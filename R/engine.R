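#' Initial monolayer configuration of the islet
#'
#' Epithelial cells are placed deterministically on a hexagonal lattice with
#' spacing `packing_factor * 2R`, keeping every cell fully inside the islet
#' disk. No cancer cells or T cells exist at `t = 0`.
#'
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object.
#' @return A cell population `data.frame`.
#' @export
initialize_islet <- function(scenario = scenario_config(),
                             params = model_params()) {
  a <- scenario$packing_factor * 2 * params$R
  rmax <- scenario$islet_radius - params$R
  ny <- ceiling(rmax / (a * sqrt(3) / 2))
  xs <- ys <- numeric()
  for (row in seq(-ny, ny)) {
    y <- row * a * sqrt(3) / 2
    off <- if (row %% 2 == 0) 0 else a / 2
    nx <- ceiling(rmax / a) + 1L
    x <- seq(-nx, nx) * a + off
    keep <- x^2 + y^2 <= rmax^2
    xs <- c(xs, x[keep]); ys <- c(ys, rep(y, sum(keep)))
  }
  if (!length(xs)) stop("packing produced zero cells", call. = FALSE)
  cell_population(xs, ys, "epithelial", params)
}

#' Spawn T cells around the stroma
#'
#' Called when the first cancer cell appears: `N` T cells (N_w for the weak
#' immune system, `N_s = 2 N_w` for the strong one, none otherwise) are
#' placed uniformly on the circle just outside the stromal annulus, with a
#' random common angular offset.
#'
#' @param cells current population.
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object.
#' @return The population with T cells appended.
#' @export
spawn_tcells <- function(cells, scenario, params = model_params()) {
  n <- switch(scenario$immunity,
              strong = scenario$n_tcells_strong,
              weak = scenario$n_tcells_weak,
              none = 0L)
  if (n == 0L) return(cells)
  rad <- scenario$islet_radius + scenario$stroma_thickness +
    scenario$tcell_spawn_margin
  ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tc <- cell_population(rad * cos(ang), rad * sin(ang), "tcell", params,
                        id = max(cells$id, 0L) + seq_len(n))
  rbind(cells, tc)
}

.count_row <- function(time, phen, include_tcells) {
  ne <- sum(phen == "epithelial")
  nc <- sum(phen == "cancer")
  nt <- sum(phen == "tcell")
  denom <- if (include_tcells) ne + nc + nt else ne + nc
  c(time, ne, nc, nt, if (denom > 0) nc / denom else 0)
}

#' Run one replicate of the coupled simulation
#'
#' Advances the full system to `t_end`: per step it (1) evaluates stimuli,
#' contacts and gating energies at the previous positions, (2) chooses the
#' adaptive step, (3) moves epithelial/cancer cells and T cells, (4) updates
#' growth and proximity clocks, (5) draws mutation, anoikis and division
#' events in that order, (6) resolves T-cell engulfment interactions, and
#' (7) records phenotype counts. T cells are spawned once, when the first
#' cancer cell appears.
#'
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object, or `NULL` to build one from the
#'   scenario (applying `F_scenario` when set).
#' @param thresholds an [event_thresholds()] object.
#' @return An object of class `run_summary`: the recorded `series`, the
#'   event log, `immune_response_time` (first time after tumor initiation at
#'   which the cancer count returns to zero; censored at `t_end` when never
#'   cleared), `response_censored`, `max_cancer_fraction`,
#'   `first_mutation_time`, `seed` and the scenario echo.
#' @export
run_simulation <- function(scenario = scenario_config(), params = NULL,
                           thresholds = event_thresholds()) {
  if (is.null(params)) {
    params <- if (is.null(scenario$F_scenario)) model_params()
              else model_params(F_traction = scenario$F_scenario)
  }
  set.seed(scenario$seed)
  geom <- stroma_geometry(islet_radius = scenario$islet_radius,
                          thickness = scenario$stroma_thickness,
                          k = scenario$k)
  boundary <- geom$outer_radius + scenario$boundary_margin

  init <- initialize_islet(scenario, params)
  id <- init$id; x <- init$x; y <- init$y
  phen <- init$phenotype; radius <- init$radius
  clock <- init$clock; divs <- init$divisions
  next_id <- max(id)

  pair_clocks <- data.frame(tid = integer(), cid = integer(),
                            clock = numeric())
  ev_time <- numeric(); ev_kind <- character(); ev_id <- integer()
  log_event <- function(t, kind, ids) {
    if (length(ids)) {
      ev_time <<- c(ev_time, rep(t, length(ids)))
      ev_kind <<- c(ev_kind, rep(kind, length(ids)))
      ev_id <<- c(ev_id, as.integer(ids))
    }
  }
  series <- matrix(NA_real_, 8192L, 5L)
  series[1L, ] <- .count_row(0, phen, scenario$totals_include_tcells)
  si <- 1L
  time <- 0
  step <- 0L
  first_mut <- NA_real_
  response_time <- NA_real_
  seeded <- FALSE
  sqrt2D <- sqrt(2 * params$D)
  alpha_t <- params$beta * params$R_t^3 / (params$mu * params$F_traction)
  cap_big <- params$R / 2
  cap_tc <- params$R_t / 2

  while (time < scenario$t_end) {
    n <- length(x)
    big <- phen != "tcell"
    # nonlinearities lagged: forces, gates, gradients from pre-move positions
    k <- pair_kernel_cpp(x, y, radius, big, params$M0, params$lambda_att,
                         params$R, params$d_hat, params$eps_runtime,
                         params$E_c)
    alpha <- params$beta * radius^3 / (params$mu * params$F_traction)
    mhat <- ifelse(big, k$M_remote - k$csum, 0)
    vel <- matrix(0, n, 2L)
    znorm <- sqrt(k$zx^2 + k$zy^2)
    att <- big & mhat > 0 & znorm > 0
    if (any(att)) {
      f <- alpha[att] * mhat[att] / znorm[att]
      vel[att, ] <- cbind(f * k$zx[att], f * k$zy[att])
    }
    rnorm2 <- sqrt(k$repx^2 + k$repy^2)
    repm <- big & mhat < 0 & rnorm2 > 0
    if (any(repm)) {
      f <- alpha[repm] * -mhat[repm] / rnorm2[repm]
      vel[repm, ] <- cbind(f * k$repx[repm], f * k$repy[repm])
    }
    gate <- ifelse(big, abs(params$M0 + k$M_remote - k$csum), NA_real_)
    max_speed <- if (any(big)) max(sqrt(rowSums(vel[big, , drop = FALSE]^2)))
                 else 0
    dt <- choose_dt(max_speed, params$R, scenario$dt_max)
    dt <- min(dt, scenario$t_end - time)

    x0 <- x; y0 <- y
    # epithelial/cancer: drift + repulsion + Wiener noise, capped at R/2
    bidx <- which(big)
    if (length(bidx)) {
      disp <- vel[bidx, , drop = FALSE] * dt + sqrt2D *
        matrix(stats::rnorm(2L * length(bidx), sd = sqrt(dt)), ncol = 2L)
      new <- .clamp_and_reflect(cbind(x[bidx], y[bidx]), disp, cap_big,
                                boundary)
      if (any(!is.finite(new))) {
        stop("non-finite position for cell id ",
             id[bidx][which(!is.finite(rowSums(new)))[1L]], call. = FALSE)
      }
      x[bidx] <- new[, 1L]; y[bidx] <- new[, 2L]
    }
    # T cells: orientation-filtered chemotaxis + noise, minus repulsion
    tidx <- which(!big)
    if (length(tidx)) {
      cidx <- which(phen == "cancer")
      sources <- chemokine_sources(cbind(x0[cidx], y0[cidx]),
                                   gamma = params$gamma, D_c = params$D_c,
                                   r_min = params$R_t)
      grad <- chemokine_gradient(cbind(x0[tidx], y0[tidx]), sources)
      # near-field homing: within a couple of cell diameters the chemokine
      # field is dominated by the nearest secreting cell (the log kernel is
      # singular at sources, which the r_min clamp on the bulk gradient
      # suppresses), so a T cell that close presses toward its nearest
      # target; this also encodes synapse arrest during engagement
      if (length(cidx) && scenario$immunity != "none") {
        dtc <- sqrt(outer(x0[tidx], x0[cidx], "-")^2 +
                    outer(y0[tidx], y0[cidx], "-")^2)
        nst <- max.col(-dtc, ties.method = "first")
        mind <- dtc[cbind(seq_along(nst), nst)]
        eng <- which(mind <= scenario$tcell_homing_radius & mind > 0)
        if (length(eng)) {
          tx <- x0[cidx][nst[eng]] - x0[tidx][eng]
          ty <- y0[cidx][nst[eng]] - y0[tidx][eng]
          press <- cap_tc / (params$beta * dt) / mind[eng]
          grad[eng, ] <- cbind(press * tx, press * ty)
        }
      }
      v <- params$beta * grad * dt + sqrt2D *
        matrix(stats::rnorm(2L * length(tidx), sd = sqrt(dt)), ncol = 2L)
      relx <- x0[tidx] - geom$center[1L]
      rely <- y0[tidx] - geom$center[2L]
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
        alpha_t * cbind(k$repx[tidx], k$repy[tidx]) * dt
      new <- .clamp_and_reflect(cbind(x[tidx], y[tidx]), disp, cap_tc,
                                boundary)
      x[tidx] <- new[, 1L]; y[tidx] <- new[, 2L]
    }
    time <- time + dt
    step <- step + 1L
    clock <- clock + dt

    # deterministic tumor seeding switch
    if (!seeded && !is.na(scenario$seed_cancer_at) &&
        time >= scenario$seed_cancer_at && any(phen == "epithelial")) {
      ep <- which(phen == "epithelial")
      ctr <- ep[which.min(x[ep]^2 + y[ep]^2)]
      phen[ctr] <- "cancer"
      clock[ctr] <- 0
      log_event(time, "mutation", id[ctr])
      seeded <- TRUE
    }

    # mutation (epithelial -> cancer), then anoikis, then division
    cand <- which(phen == "epithelial" & !is.na(gate) &
                    gate >= thresholds$gate_mutation &
                    clock >= thresholds$tau_mut)
    if (length(cand)) {
      fire <- cand[draw_event(stats::runif(length(cand)), thresholds$rate, dt)]
      if (length(fire)) {
        phen[fire] <- "cancer"
        clock[fire] <- 0
        log_event(time, "mutation", id[fire])
      }
    }
    cand <- which(phen == "epithelial" & !is.na(gate) &
                    gate >= thresholds$gate_apoptosis &
                    clock >= thresholds$tau_apop)
    if (length(cand)) {
      fire <- cand[draw_event(stats::runif(length(cand)), thresholds$rate, dt)]
      if (length(fire)) {
        log_event(time, "apoptosis", id[fire])
        keep <- setdiff(seq_along(id), fire)
        id <- id[keep]; x <- x[keep]; y <- y[keep]; phen <- phen[keep]
        radius <- radius[keep]; clock <- clock[keep]; divs <- divs[keep]
        gate <- gate[keep]
      }
    }
    cand <- which((phen == "epithelial" & !is.na(gate) &
                     gate < thresholds$gate_div_epithelial &
                     clock >= thresholds$tau_div &
                     divs < scenario$division_cap_epithelial) |
                  (phen == "cancer" & !is.na(gate) &
                     gate < thresholds$gate_div_cancer &
                     clock >= thresholds$tau_div))
    if (length(cand)) {
      fire <- cand[draw_event(stats::runif(length(cand)), thresholds$rate, dt)]
      for (row in fire) {
        ang <- stats::runif(1, 0, 2 * pi)
        next_id <- next_id + 1L
        id <- c(id, next_id)
        x <- c(x, x[row] + radius[row] * cos(ang))
        y <- c(y, y[row] + radius[row] * sin(ang))
        phen <- c(phen, phen[row])
        radius <- c(radius, radius[row])
        divs[row] <- divs[row] + 1L
        divs <- c(divs, divs[row])
        clock[row] <- 0
        clock <- c(clock, 0)
        log_event(time, "division", next_id)
      }
    }

    # tumor initiation: spawn the immune response once
    if (is.na(first_mut) && any(phen == "cancer")) {
      first_mut <- time
      ntc <- switch(scenario$immunity,
                    strong = scenario$n_tcells_strong,
                    weak = scenario$n_tcells_weak, none = 0L)
      if (ntc > 0L) {
        rad <- geom$outer_radius + scenario$tcell_spawn_margin
        ang <- stats::runif(1, 0, 2 * pi) +
          seq(0, 2 * pi, length.out = ntc + 1L)[-(ntc + 1L)]
        id <- c(id, next_id + seq_len(ntc))
        next_id <- next_id + ntc
        x <- c(x, rad * cos(ang)); y <- c(y, rad * sin(ang))
        phen <- c(phen, rep("tcell", ntc))
        radius <- c(radius, rep(params$R_t, ntc))
        clock <- c(clock, rep(0, ntc))
        divs <- c(divs, rep(0L, ntc))
        log_event(time, "tcell_spawn", id[phen == "tcell"])
      }
    }

    # engulfment (post-move, pre-projection distances)
    imm <- update_immune_interactions(
      list(id = id[phen == "tcell"], x = x[phen == "tcell"],
           y = y[phen == "tcell"]),
      list(id = id[phen == "cancer"], x = x[phen == "cancer"],
           y = y[phen == "cancer"]),
      pair_clocks, scenario$immunity, dt, thresholds)
    pair_clocks <- imm$pair_clocks
    gone <- c(imm$killed, imm$tcell_deaths)
    if (length(gone)) {
      log_event(time, "engulfment", imm$killed)
      log_event(time, "tcell_death", imm$tcell_deaths)
      keep <- !(id %in% gone)
      id <- id[keep]; x <- x[keep]; y <- y[keep]; phen <- phen[keep]
      radius <- radius[keep]; clock <- clock[keep]; divs <- divs[keep]
    }

    # hard quarter-diameter overlap constraint
    res <- resolve_overlaps_cpp(x, y, radius)
    x <- res$x; y <- res$y

    if (step %% scenario$record_every == 0L || time >= scenario$t_end) {
      si <- si + 1L
      if (si > nrow(series)) {
        series <- rbind(series, matrix(NA_real_, nrow(series), 5L))
      }
      series[si, ] <- .count_row(time, phen, scenario$totals_include_tcells)
    }
    if (is.na(response_time) && !is.na(first_mut) && !any(phen == "cancer")) {
      response_time <- time
    }
    if (scenario$early_exit && !is.na(response_time) &&
        !any(phen == "epithelial")) break
  }
  cells <- data.frame(id = id, x = x, y = y, phenotype = phen,
                      radius = radius, clock = clock, divisions = divs,
                      stringsAsFactors = FALSE)

  series <- as.data.frame(series[seq_len(si), , drop = FALSE])
  names(series) <- c("time", "n_epithelial", "n_cancer", "n_tcell",
                     "cancer_fraction")
  events <- data.frame(time = ev_time, kind = ev_kind, id = ev_id,
                       stringsAsFactors = FALSE)
  censored <- is.na(response_time) && !is.na(first_mut)
  structure(list(
    series = series,
    events = events,
    immune_response_time = if (censored) scenario$t_end else response_time,
    response_censored = censored,
    max_cancer_fraction = max(series$cancer_fraction),
    first_mutation_time = first_mut,
    seed = scenario$seed,
    scenario = scenario,
    final_cells = cells
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf(
    "run_summary: seed %d, immunity %s, k = %g, t_end = %g min\n",
    x$seed, x$scenario$immunity, x$scenario$k, x$scenario$t_end))
  cat(sprintf("  first mutation: %s min, immune response time: %s%s\n",
              format(x$first_mutation_time),
              format(x$immune_response_time),
              if (x$response_censored) " (censored)" else ""))
  cat(sprintf("  max cancer fraction: %.3f; final counts E/C/T = %d/%d/%d\n",
              x$max_cancer_fraction, last$n_epithelial, last$n_cancer,
              last$n_tcell))
  invisible(x)
}

#' Sweep the anisotropy constant over replicate simulations
#'
#' Runs `replicates` independently seeded simulations for every value of the
#' attenuation constant `k` and collects the derived per-replicate metrics.
#'
#' @param base_scenario scenario template; `k` and `seed` are overridden.
#' @param k_values anisotropy constants to sweep (default 0, 0.1, ..., 0.9).
#' @param replicates replicates per `k`.
#' @param base_seed integer; replicate seeds are derived deterministically.
#' @param thresholds an [event_thresholds()] object.
#' @return `data.frame(k, replicate, seed, immune_response_time,
#'   response_censored, max_cancer_fraction)`.
#' @export
k_sweep <- function(base_scenario = scenario_config(),
                    k_values = seq(0, 0.9, by = 0.1),
                    replicates = 10L,
                    base_seed = base_scenario$seed,
                    thresholds = event_thresholds()) {
  rows <- list()
  for (ki in seq_along(k_values)) {
    for (rep in seq_len(replicates)) {
      sc <- base_scenario
      sc$k <- k_values[ki]
      sc$seed <- as.integer((base_seed + 7919L * ki + rep) %% .Machine$integer.max)
      rs <- run_simulation(sc, thresholds = thresholds)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k_values[ki], replicate = rep, seed = sc$seed,
        immune_response_time = rs$immune_response_time,
        response_censored = rs$response_censored,
        max_cancer_fraction = rs$max_cancer_fraction)
    }
  }
  do.call(rbind, rows)
}
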