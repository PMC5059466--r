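#' Richness-gradient sweep design
#'
#' The published experiment varies initial animal richness over all integer
#' levels 10..100 with 300 replicates each on 30 plant species; desk-scale
#' presets subsample levels and replicates (see [sweep_preset()]).
#'
#' @param S_A_values initial animal richness levels.
#' @param replicates replicates per level.
#' @param S_P number of plant species.
#' @param master_seed master seed; every replicate derives its own seed from
#'   it (see [replicate_seed()]).
#' @param herbivore_fraction fraction of animals per replicate forced to
#'   strict herbivory (sensitivity variant; 0 disables).
#' @param cfg an [sampling_config()]; override entries (e.g. `D`, `supply`,
#'   `beta_cons`) here for the sensitivity variants.
#' @return An object of class `atn_design`.
#' @export
sweep_design <- function(S_A_values = 10:100,
                         replicates = 300,
                         S_P = 30,
                         master_seed = 1,
                         herbivore_fraction = 0,
                         cfg = sampling_config()) {
  stopifnot(all(S_A_values >= 1), replicates >= 1, S_P >= 1,
            herbivore_fraction >= 0, herbivore_fraction <= 1)
  structure(list(S_A_values = as.integer(S_A_values),
                 replicates = as.integer(replicates),
                 S_P = as.integer(S_P),
                 master_seed = as.integer(master_seed),
                 herbivore_fraction = herbivore_fraction,
                 cfg = cfg),
            class = "atn_design")
}

#' Desk-scale sweep presets
#'
#' @param name `"desk"` (5 levels x 10 replicates) or `"mini"` (3 levels x
#'   2 replicates, for smoke tests).
#' @param master_seed master seed passed through to [sweep_design()].
#' @param ... further arguments to [sweep_design()].
#' @return An `atn_design`.
#' @export
sweep_preset <- function(name = c("desk", "mini"), master_seed = 1, ...) {
  name <- match.arg(name)
  switch(name,
    desk = sweep_design(S_A_values = c(10, 30, 50, 70, 90), replicates = 10,
                        master_seed = master_seed, ...),
    mini = sweep_design(S_A_values = c(10, 40, 80), replicates = 2,
                        master_seed = master_seed, ...))
}

#' Derive a replicate seed
#'
#' Deterministic, collision-avoiding map from (master seed, richness level,
#' replicate index) to a 31-bit seed. Stable across versions: changing it
#' would change every published table.
#'
#' @param master_seed integer master seed.
#' @param S_A richness level of the replicate.
#' @param rep replicate index within the level (1-based).
#' @return A positive integer seed < 2^31.
#' @export
replicate_seed <- function(master_seed, S_A, rep) {
  # doubles are exact up to 2^53, so this stays exact before the modulus
  s <- (as.numeric(master_seed) * 2654435761 +
        as.numeric(S_A) * 97003 + as.numeric(rep) * 101) %% 2147483647
  as.integer(s) + 1L
}

#' Sample and simulate one replicate
#'
#' Seeds the RNG, then draws in a fixed, documented order: body masses,
#' parameter set (including nutrient constants), the strict-herbivore mask
#' if requested, and the initial state; builds the pruned web and rate
#' cache; integrates; and summarises the run as a [function_record()].
#'
#' @param S_A,S_P initial richness of the two guilds.
#' @param cfg an [sampling_config()].
#' @param settings a [simulation_settings()].
#' @param seed integer seed for this replicate.
#' @param herbivore_fraction fraction of animals forced to strict herbivory.
#' @param keep_trajectory return the trajectory alongside the record.
#' @return A list with `record` (one-row data frame), `community`,
#'   `parameters`, and optionally `trajectory`.
#' @export
simulate_replicate <- function(S_A, S_P = 30, cfg = sampling_config(),
                               settings = simulation_settings(),
                               seed = 1, herbivore_fraction = 0,
                               keep_trajectory = FALSE) {
  set.seed(seed)
  community <- sample_body_masses(S_P, S_A, cfg)
  p <- sample_parameters(cfg, S_P = S_P)
  if (herbivore_fraction > 0) {
    n_strict <- round(herbivore_fraction * S_A)
    mask <- rep(FALSE, S_A)
    mask[sample.int(S_A, n_strict)] <- TRUE
    community$herbivore_only <- mask
  }
  community <- build_food_web(community, eps = cfg$prune_epsilon,
                              R_opt = cfg$R_opt, gamma = cfg$gamma)
  state0 <- initialize_state(community, p)
  cache <- rate_cache(community, p)
  traj <- integrate_community(community, cache, p, settings, state0)
  rec <- function_record(traj, community, cache, p, seed = seed)
  out <- list(record = rec, community = community, parameters = p)
  if (keep_trajectory) out$trajectory <- traj
  out
}

#' Run a richness-gradient sweep
#'
#' Simulates every (level, replicate) cell of the design and stacks the
#' per-replicate [function_record()]s. The table is a pure function of the
#' design (including its master seed). Integration failures are caught and
#' recorded as rows with `status` set accordingly, never fatal to the
#' sweep.
#'
#' @param design an [sweep_design()] or [sweep_preset()].
#' @param settings a [simulation_settings()].
#' @param cores parallel workers via `parallel::mclapply` (seeds are
#'   assigned up front, so results are identical for any worker count).
#' @param progress print one line per completed level.
#' @return A `data.frame` of records with the design attached as attribute
#'   `"design"`.
#' @export
run_sweep <- function(design, settings = simulation_settings(), cores = 1,
                      progress = FALSE) {
  stopifnot(inherits(design, "atn_design"))
  cells <- expand.grid(rep = seq_len(design$replicates),
                       S_A = design$S_A_values)
  cells$seed <- replicate_seed(design$master_seed, cells$S_A, cells$rep)
  one <- function(k) {
    sa <- cells$S_A[k]
    sd_ <- cells$seed[k]
    rec <- tryCatch(
      simulate_replicate(sa, design$S_P, design$cfg, settings,
                         seed = sd_,
                         herbivore_fraction = design$herbivore_fraction
                        )$record,
      error = function(e) {
        r <- empty_record()
        r$seed <- sd_
        r$S_A_init <- sa
        r$S_P_init <- design$S_P
        r$status <- paste0("error: ", conditionMessage(e))
        r
      })
    rec$replicate <- cells$rep[k]
    rec
  }
  ks <- seq_len(nrow(cells))
  recs <- if (cores > 1) {
    parallel::mclapply(ks, one, mc.cores = cores, mc.preschedule = TRUE)
  } else {
    lapply(ks, function(k) {
      r <- one(k)
      if (progress && cells$rep[k] == design$replicates)
        message(sprintf("level S_A = %d done", cells$S_A[k]))
      r
    })
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

empty_record <- function() {
  data.frame(seed = NA_integer_, S_A_init = NA_integer_,
             S_P_init = NA_integer_, S_A_final = NA_integer_,
             S_P_final = NA_integer_, A_total = NA_real_,
             P_total = NA_real_, F_P = NA_real_, F_A = NA_real_,
             X_A = NA_real_, X_P = NA_real_,
             mean_mass_animals = NA_real_, mean_mass_plants = NA_real_,
             mean_mass_animals_bw = NA_real_, mean_mass_plants_bw = NA_real_,
             discarded = NA, status = "failed")
}

#' Fit a diversity-function power law
#'
#' Ordinary least squares on the log-log transformed relationship
#' `log(x) = log(a) + alpha * log(S_A)` between a response column of a
#' sweep table and initial animal richness. Discarded and failed rows are
#' excluded; for the intraguild-predation response `F_A` (and any response
#' with non-positive values) offending rows are omitted with a message, as
#' in the published analysis. Natural logs are used; the intercept is
#' reported as `a = exp(intercept)` on the natural scale.
#'
#' @param records a sweep table from [run_sweep()].
#' @param response one of `A_total`, `P_total`, `F_P`, `F_A`, `X_A`, `X_P`,
#'   `mean_mass_animals`, `mean_mass_plants`.
#' @return An object of class `atn_powerlaw_fit`: list with `a`, `alpha`,
#'   `alpha_se` (standard error of the exponent), `resid_se` (residual
#'   standard error), `r_squared`, `n_used`, `n_zero_omitted`, `response`,
#'   and the underlying `lm` fit.
#' @export
fit_power_law <- function(records,
                          response = c("A_total", "P_total", "F_P", "F_A",
                                       "X_A", "X_P", "mean_mass_animals",
                                       "mean_mass_plants")) {
  response <- match.arg(response)
  ok <- records$status == "ok" & !is.na(records$discarded) &
    !records$discarded & !is.na(records[[response]])
  d <- records[ok, , drop = FALSE]
  nz <- d[[response]] > 0
  n_zero <- sum(!nz)
  if (n_zero > 0)
    message(sprintf("fit_power_law: omitting %d replicate(s) with %s <= 0",
                    n_zero, response))
  d <- d[nz, , drop = FALSE]
  if (nrow(d) < 3)
    stop("fewer than 3 usable records for the fit", call. = FALSE)
  fit <- stats::lm(log(d[[response]]) ~ log(d$S_A_init))
  sm <- summary(fit)
  structure(list(
    response = response,
    a = exp(unname(stats::coef(fit)[1])),
    alpha = unname(stats::coef(fit)[2]),
    alpha_se = unname(sm$coefficients[2, 2]),
    resid_se = sm$sigma,
    r_squared = sm$r.squared,
    n_used = nrow(d),
    n_zero_omitted = n_zero,
    lm = fit
  ), class = "atn_powerlaw_fit")
}

#' @export
print.atn_powerlaw_fit <- function(x, ...) {
  cat(sprintf("%s = %.4g * S_A ^ %.3f  (se(alpha) = %.3g, R^2 = %.3f, n = %d)\n",
              x$response, x$a, x$alpha, x$alpha_se, x$r_squared, x$n_used))
  if (x$n_zero_omitted > 0)
    cat(sprintf("  %d zero-valued replicate(s) omitted\n", x$n_zero_omitted))
  invisible(x)
}

#' Fit power laws for all six ecosystem functions
#'
#' @param records a sweep table from [run_sweep()].
#' @param responses columns to fit.
#' @return A data frame with one row per response (a, alpha, alpha_se,
#'   resid_se, r_squared, n_used, n_zero_omitted).
#' @export
fit_all_power_laws <- function(records,
                               responses = c("A_total", "P_total", "F_P",
                                             "F_A", "X_A", "X_P")) {
  rows <- lapply(responses, function(r) {
    f <- fit_power_law(records, r)
    data.frame(response = r, a = f$a, alpha = f$alpha,
               alpha_se = f$alpha_se, resid_se = f$resid_se,
               r_squared = f$r_squared, n_used = f$n_used,
               n_zero_omitted = f$n_zero_omitted)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
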