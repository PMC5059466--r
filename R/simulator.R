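#' Simulation settings
#'
#' @param t_end integration horizon (model time units).
#' @param eval_window length of the stationary evaluation window at the end
#'   of the run; sampled on a unit output grid.
#' @param abs_tol,rel_tol solver error tolerances.
#' @param extinction_threshold biomass density at or below which a species
#'   is immediately set to zero and treated as permanently extinct.
#' @param check_interval spacing of the output/extinction-check grid.
#' @param transient_stride spacing at which pre-window states are retained
#'   in the returned trajectory (0 disables transient storage).
#' @param max_steps solver step budget before the run is flagged as failed.
#' @param method `"radau"` (implicit 3-stage Radau IIA collocation, order 5,
#'   L-stable; the default, suited to the stiff modes of this system) or
#'   `"dopri"` (explicit Dormand-Prince 5(4); kept as an independent
#'   cross-check route).
#' @param h_max step-size cap for the implicit method (bounds the stretch
#'   over which dense-output extinction checks interpolate).
#' @return An object of class `atn_settings`.
#' @export
simulation_settings <- function(t_end = 150000,
                                eval_window = 10000,
                                abs_tol = 1e-10,
                                rel_tol = 1e-10,
                                extinction_threshold = 1e-6,
                                check_interval = 1,
                                transient_stride = 100,
                                max_steps = 5e7,
                                method = c("radau", "dopri"),
                                h_max = 100) {
  stopifnot(t_end > eval_window, eval_window > 0,
            abs_tol > 0, rel_tol > 0, check_interval > 0, h_max > 0)
  structure(list(t_end = t_end, eval_window = eval_window,
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 extinction_threshold = extinction_threshold,
                 check_interval = check_interval,
                 transient_stride = transient_stride,
                 max_steps = max_steps,
                 method = match.arg(method),
                 h_max = h_max),
            class = "atn_settings")
}

#' Draw an initial state
#'
#' Nutrients are initialized uniformly on `[S_l / 2, S_l]`; every plant and
#' animal biomass density uniformly on `(0, 10]`.
#'
#' @param community a linked `atn_community`.
#' @param p an `atn_parameters` object (supplies `S_supply`).
#' @return An `atn_state`.
#' @export
initialize_state <- function(community, p) {
  atn_state(
    A = 10 - stats::runif(community$S_A, 0, 10),   # (0, 10]
    P = 10 - stats::runif(community$S_P, 0, 10),
    N = stats::runif(2, p$S_supply / 2, p$S_supply)
  )
}

#' Integrate a community to its stationary state
#'
#' Runs the coupled plant-animal-nutrient system from `state0` to
#' `settings$t_end` with an adaptive embedded Runge-Kutta (Dormand-Prince
#' 5(4)) at the configured tolerances. On every point of the output grid
#' (spacing `settings$check_interval`) any biomass at or below the
#' extinction threshold is set to exactly zero and the integration restarts
#' from the modified state; extinction is absorbing. The returned trajectory
#' holds the full unit-grid evaluation window plus strided transient
#' samples.
#'
#' @param community a linked `atn_community`.
#' @param cache matching [rate_cache()].
#' @param p an `atn_parameters` object.
#' @param settings a [simulation_settings()] object.
#' @param state0 initial `atn_state`.
#' @return An object of class `atn_trajectory` with elements `times`,
#'   `A` (time x species), `P`, `N`, `extinctions` (data frame), `status`
#'   (`"ok"`, `"max_steps"` or `"non_finite"`), `n_steps`, and the
#'   originating `community`/`settings`.
#' @export
integrate_community <- function(community, cache, p, settings, state0) {
  check_state(state0, community)
  S_P <- community$S_P
  S_A <- community$S_A
  y0 <- c(state0$P, state0$A, state0$N)
  args <- list(
    S_P, S_A, community$masses_animals,
    cache$b, cache$b * cache$h, community$omega,
    cache$x_animals, cache$x_plants, cache$r, p$K,
    p$c, p$q, p$e_P, p$e_A, p$D, p$v, p$S_supply,
    y0, settings$t_end, settings$t_end - settings$eval_window,
    settings$check_interval, settings$transient_stride,
    settings$abs_tol, settings$rel_tol,
    settings$extinction_threshold, settings$max_steps)
  res <- if (identical(settings$method, "dopri")) {
    do.call(atn_integrate_dopri_cpp, args)
  } else {
    do.call(atn_integrate_radau_cpp, c(args, settings$h_max))
  }
  st <- res$states
  guild <- c(rep("plant", S_P), rep("animal", S_A))
  ext <- data.frame(
    guild = guild[res$ext_index],
    species = ifelse(res$ext_index > S_P, res$ext_index - S_P,
                     res$ext_index),
    time = res$ext_time
  )
  structure(list(
    times = res$times,
    P = st[, seq_len(S_P), drop = FALSE],
    A = st[, S_P + seq_len(S_A), drop = FALSE],
    N = st[, S_P + S_A + (1:2), drop = FALSE],
    extinctions = ext,
    status = c("ok", "max_steps", "non_finite")[res$status + 1],
    n_steps = res$n_steps,
    t_last = res$t_last,
    final_state = atn_state(
      A = pmax(res$final_state[S_P + seq_len(S_A)], 0),
      P = pmax(res$final_state[seq_len(S_P)], 0),
      N = pmax(res$final_state[S_P + S_A + (1:2)], 0)),
    window_start = settings$t_end - settings$eval_window,
    community = community,
    settings = settings
  ), class = "atn_trajectory")
}

#' @export
print.atn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory to t = %g (%s), %d stored samples\n",
              x$t_last, x$status, length(x$times)))
  cat(sprintf("  survivors: %d/%d plants, %d/%d animals; %d extinction events\n",
              sum(x$final_state$P > 0), ncol(x$P),
              sum(x$final_state$A > 0), ncol(x$A),
              nrow(x$extinctions)))
  invisible(x)
}

window_indices <- function(traj) {
  idx <- which(traj$times >= traj$window_start - 1e-9)
  if (!length(idx))
    stop("trajectory does not cover the evaluation window", call. = FALSE)
  idx
}

#' Consumer-free basal species discard rule
#'
#' A replicate is discarded when, at the end of the simulation, some plant
#' with positive biomass has no extant animal consumer (a pruned-in link to
#' an animal with positive final biomass). Such inedible plants would grow
#' uncontrolled and outcompete the rest of the basal guild, a qualitatively
#' different ecosystem. If all plants are extinct the rule is vacuously
#' false.
#'
#' @param traj an `atn_trajectory`.
#' @param community the community it was integrated from (defaults to the
#'   one stored in the trajectory).
#' @return `TRUE` if the replicate must be discarded from the statistics.
#' @export
is_discarded <- function(traj, community = traj$community) {
  Pfin <- traj$final_state$P
  Afin <- traj$final_state$A
  alive_p <- which(Pfin > 0)
  if (!length(alive_p)) return(FALSE)
  L <- community$link_efficiency
  for (i in alive_p) {
    has_consumer <- any(L[, i] > 0 & Afin > 0)
    if (!has_consumer) return(TRUE)
  }
  FALSE
}

#' Export a trajectory as tidy tables
#'
#' @param traj an `atn_trajectory`.
#' @param file optional path for the time-series CSV; the extinction log is
#'   written alongside with suffix `_extinctions.csv`.
#' @return Invisibly, a list with the time-series and extinction-log data
#'   frames (long format: time, guild, species, biomass; nutrients included
#'   as guild `"nutrient"`).
#' @export
export_trajectory <- function(traj, file = NULL) {
  long <- function(mat, guild) {
    data.frame(
      time = rep(traj$times, ncol(mat)),
      guild = guild,
      species = rep(seq_len(ncol(mat)), each = length(traj$times)),
      biomass = as.vector(mat)
    )
  }
  ts <- rbind(long(traj$P, "plant"), long(traj$A, "animal"),
              long(traj$N, "nutrient"))
  if (!is.null(file)) {
    utils::write.csv(ts, file, row.names = FALSE)
    utils::write.csv(traj$extinctions,
                     sub("\\.csv$", "_extinctions.csv", file),
                     row.names = FALSE)
  }
  invisible(list(timeseries = ts, extinctions = traj$extinctions))
}
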