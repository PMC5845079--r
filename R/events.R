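#' Stochastic event thresholds and rates
#'
#' Collects the gates and clocks of the memoryless event model: strain-energy
#' gates for division/apoptosis/mutation (compared against the gating net
#' energy `|M_total - sum(M_contact)|`), minimum growth times, the common
#' probability rate, and the immune engulfment rules (proximity distance and
#' dwell time per immunity level, plus the T-cell death probability per
#' engulfment).
#'
#' The weak immune system uses the stricter proximity rule (2.5 um over
#' 10 min); the strong one engulfs at 3.5 um after 5 min.
#'
#' @param rate probability rate of every gated event, 1/min.
#' @param gate_div_epithelial,gate_div_cancer division gates, kg·um/min^2
#'   (division fires while the gating energy is *below* the gate).
#' @param gate_apoptosis,gate_mutation anoikis and mutation gates (fire at or
#'   *above* the gate; epithelial cells only).
#' @param tau_div,tau_mut,tau_apop minimum growth times, min.
#' @param kill_distance_weak,kill_time_weak,kill_distance_strong,kill_time_strong
#'   engulfment proximity rules, um and min.
#' @param tcell_death_prob probability that the engulfing T cell dies with
#'   each engulfment event.
#' @return An object of class `event_thresholds`.
#' @export
event_thresholds <- function(rate = 10,
                             gate_div_epithelial = 0.03,
                             gate_div_cancer = 0.04,
                             gate_apoptosis = 0.1,
                             gate_mutation = 0.05,
                             tau_div = 5,
                             tau_mut = 10,
                             tau_apop = 10,
                             kill_distance_weak = 2.5,
                             kill_time_weak = 10,
                             kill_distance_strong = 3.5,
                             kill_time_strong = 5,
                             tcell_death_prob = 0.1) {
  vals <- list(rate = rate, gate_div_epithelial = gate_div_epithelial,
               gate_div_cancer = gate_div_cancer,
               gate_apoptosis = gate_apoptosis,
               gate_mutation = gate_mutation,
               tau_div = tau_div, tau_mut = tau_mut, tau_apop = tau_apop,
               kill_distance_weak = kill_distance_weak,
               kill_time_weak = kill_time_weak,
               kill_distance_strong = kill_distance_strong,
               kill_time_strong = kill_time_strong,
               tcell_death_prob = tcell_death_prob)
  if (any(unlist(vals) < 0)) stop("thresholds must be non-negative", call. = FALSE)
  if (kill_distance_weak > kill_distance_strong ||
      kill_time_weak < kill_time_strong) {
    stop("weak-immunity rules must be stricter than strong ones", call. = FALSE)
  }
  structure(vals, class = "event_thresholds")
}

#' Probability of a memoryless event within one step
#'
#' `P = 1 - exp(-rate * dt)`, from the exponential inter-event distribution.
#' At `rate = 10` per min and `dt = 0.1` min this is about 0.6321; for
#' `rate * dt << 1` it reduces to `rate * dt` to first order.
#'
#' @param rate probability rate, 1/min.
#' @param dt step length, min.
#' @return Event probability in `[0, 1)` (vectorised).
#' @export
event_probability <- function(rate, dt) {
  if (any(rate < 0) || any(dt < 0)) {
    stop("'rate' and 'dt' must be non-negative", call. = FALSE)
  }
  1 - exp(-rate * dt)
}

#' Bernoulli draw of a gated event
#'
#' The event fires iff the uniform variate satisfies
#' `xi <= 1 - exp(-rate * dt)`.
#'
#' @param xi uniform variate(s) in `[0, 1]`.
#' @param rate probability rate, 1/min.
#' @param dt step length, min.
#' @return Logical (vectorised over `xi`).
#' @export
draw_event <- function(xi, rate, dt) {
  if (any(xi < 0) || any(xi > 1)) stop("'xi' must lie in [0, 1]", call. = FALSE)
  xi <= event_probability(rate, dt)
}

#' Events a cell is eligible for this step
#'
#' Applies the strain-energy gates and growth clocks:
#' * `divide`: epithelial with gate energy `< 0.03`, clock `>= 5` min and
#'   fewer divisions than the cap; or cancer with gate `< 0.04` and clock
#'   `>= 5` (no cap: cancer lineages are immortal).
#' * `die` (anoikis): epithelial with gate `>= 0.1` and clock `>= 10`.
#'   Cancer cells die only by engulfment.
#' * `mutate`: epithelial with gate `>= 0.05` and clock `>= 10`.
#'
#' T cells are eligible for none of these.
#'
#' @param phenotype `"epithelial"`, `"cancer"` or `"tcell"`.
#' @param gate_energy gating net energy `|M_total - sum(M_contact)|`.
#' @param clock growth clock, min.
#' @param divisions divisions already performed by the lineage.
#' @param thresholds an [event_thresholds()] object.
#' @param division_cap epithelial division cap.
#' @return Character vector, a subset of `c("mutate", "die", "divide")` in
#'   resolution order (mutation, then apoptosis, then division).
#' @export
eligible_events <- function(phenotype, gate_energy, clock, divisions = 0L,
                            thresholds = event_thresholds(),
                            division_cap = 50L) {
  if (phenotype == "tcell") return(character())
  ev <- character()
  if (phenotype == "epithelial") {
    if (gate_energy >= thresholds$gate_mutation && clock >= thresholds$tau_mut)
      ev <- c(ev, "mutate")
    if (gate_energy >= thresholds$gate_apoptosis && clock >= thresholds$tau_apop)
      ev <- c(ev, "die")
    if (gate_energy < thresholds$gate_div_epithelial &&
        clock >= thresholds$tau_div && divisions < division_cap)
      ev <- c(ev, "divide")
  } else { # cancer
    if (gate_energy < thresholds$gate_div_cancer && clock >= thresholds$tau_div)
      ev <- c(ev, "divide")
  }
  ev
}

#' Apply one cell division
#'
#' The daughter is placed at distance `R` from the mother in a uniformly
#' random direction (initial indentation `h = R`; the contact repulsion then
#' separates the pair). Both growth clocks reset to zero; the mother's
#' division count is incremented and inherited by the daughter, so a lineage
#' ages as a whole.
#'
#' @param cells cell population `data.frame`.
#' @param row row index of the mother.
#' @param angle direction of placement, radians; drawn uniformly if missing.
#' @return The population with the daughter appended.
#' @export
apply_division <- function(cells, row, angle = stats::runif(1, 0, 2 * pi)) {
  mother <- cells[row, ]
  cells$clock[row] <- 0
  cells$divisions[row] <- mother$divisions + 1L
  daughter <- mother
  daughter$id <- max(cells$id) + 1L
  daughter$x <- mother$x + mother$radius * cos(angle)
  daughter$y <- mother$y + mother$radius * sin(angle)
  daughter$clock <- 0
  daughter$divisions <- mother$divisions + 1L
  rbind(cells, daughter)
}

#' Update T-cell / cancer-cell engulfment interactions
#'
#' Each T cell carries a contact clock: while its distance to the *nearest*
#' cancer cell is at most the immunity-dependent kill distance the clock
#' accrues `dt`, otherwise it resets. (The clock measures sustained contact
#' with the tumor, not with one fixed partner: cells in contact exchange
#' nearest neighbours on the advection timescale, so a partner-keyed clock
#' would reset on every exchange and the published "in contact for some
#' time" rule could never fire.) Once a T cell's clock reaches the kill
#' time, the engulfment event is drawn each step with probability
#' `1 - exp(-rate dt)`; on success the nearest cancer cell is removed, the
#' T cell dies with probability `tcell_death_prob`, and a surviving T cell's
#' clock restarts.
#'
#' @param tcells,cancers `data.frame`s (or lists) with elements `id, x, y`.
#' @param pair_clocks `data.frame(tid, cid, clock)` carried between steps;
#'   one row per T cell in sustained contact, `cid` its current nearest
#'   target.
#' @param immunity `"strong"`, `"weak"` or `"none"`.
#' @param dt step length, min.
#' @param thresholds an [event_thresholds()] object.
#' @return A list: updated `pair_clocks`, `killed` (cancer ids engulfed this
#'   step) and `tcell_deaths` (T-cell ids that died).
#' @export
update_immune_interactions <- function(tcells, cancers, pair_clocks,
                                       immunity, dt,
                                       thresholds = event_thresholds()) {
  empty <- data.frame(tid = integer(), cid = integer(), clock = numeric())
  if (immunity == "none" || length(tcells$id) == 0L ||
      length(cancers$id) == 0L) {
    return(list(pair_clocks = empty, killed = integer(),
                tcell_deaths = integer()))
  }
  kd <- if (immunity == "strong") thresholds$kill_distance_strong
        else thresholds$kill_distance_weak
  kt <- if (immunity == "strong") thresholds$kill_time_strong
        else thresholds$kill_time_weak
  d <- sqrt(outer(tcells$x, cancers$x, "-")^2 +
            outer(tcells$y, cancers$y, "-")^2)
  nearest <- max.col(-d, ties.method = "first")
  mind <- d[cbind(seq_along(nearest), nearest)]
  close <- which(mind <= kd)
  if (!length(close)) {
    return(list(pair_clocks = empty, killed = integer(),
                tcell_deaths = integer()))
  }
  tid <- tcells$id[close]
  cid <- cancers$id[nearest[close]]
  prev <- pair_clocks$clock[match(tid, pair_clocks$tid)]
  clk <- ifelse(is.na(prev), 0, prev) + dt
  # T cells that lost contact are dropped (their clocks reset implicitly)
  killed <- integer(); tdead <- integer()
  for (r in which(clk >= kt)) {
    if (cid[r] %in% killed) next
    if (draw_event(stats::runif(1), thresholds$rate, dt)) {
      killed <- c(killed, cid[r])
      clk[r] <- 0
      if (stats::runif(1) < thresholds$tcell_death_prob) {
        tdead <- c(tdead, tid[r])
      }
    }
  }
  keep <- !(tid %in% tdead)
  list(pair_clocks = data.frame(tid = tid[keep], cid = cid[keep],
                                clock = clk[keep]),
       killed = killed, tcell_deaths = tdead)
}
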