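#' @name ecosystem_functions
#' @title Community-level ecosystem functions over the evaluation window
#'
#' @description
#' Six aggregate functions summarise one replicate at stationarity, all as
#' time averages over the unit-sampled evaluation window: the summed
#' biomass stocks of animals (`A_total`) and plants (`P_total`); the gross
#' biomass flows from plants to animals (`F_P`, herbivory) and within the
#' animal guild (`F_A`, intraguild predation), both before assimilation
#' losses; and the summed metabolic losses of the two guilds (`X_A`,
#' `X_P`), computed as metabolic rate times window-mean biomass per
#' species. Flows are recomputed from the stored states with the same
#' functional response that drove the dynamics.
NULL

#' @rdname ecosystem_functions
#' @param traj an `atn_trajectory` covering the evaluation window.
#' @param community the community (defaults to the trajectory's).
#' @return `window_average_stocks`: named vector `c(A_total, P_total)`.
#' @export
window_average_stocks <- function(traj, community = traj$community) {
  idx <- window_indices(traj)
  c(A_total = mean(rowSums(traj$A[idx, , drop = FALSE])),
    P_total = mean(rowSums(traj$P[idx, , drop = FALSE])))
}

#' @rdname ecosystem_functions
#' @param cache matching [rate_cache()].
#' @param p parameter set.
#' @return `window_average_flows`: named vector `c(F_P, F_A)` in biomass
#'   per unit time.
#' @export
window_average_flows <- function(traj, community = traj$community, cache, p) {
  idx <- window_indices(traj)
  A <- pmax(traj$A[idx, , drop = FALSE], 0)
  P <- pmax(traj$P[idx, , drop = FALSE], 0)
  S_P <- community$S_P
  Rpow <- cbind(P, A)^(1 + p$q)
  bh <- cache$b * cache$h
  # denominator per (time, consumer)
  sat <- Rpow %*% t(bh)
  denom <- 1 + p$c * A + sweep(sat, 2, community$omega, "*")
  # per-consumer summed numerators over plant / animal resources
  numP <- Rpow[, seq_len(S_P), drop = FALSE] %*%
    t(cache$b[, seq_len(S_P), drop = FALSE])
  numA <- Rpow[, S_P + seq_len(community$S_A), drop = FALSE] %*%
    t(cache$b[, S_P + seq_len(community$S_A), drop = FALSE])
  wA <- sweep(A / denom, 2,
              community$omega / community$masses_animals, "*")
  c(F_P = mean(rowSums(wA * numP)),
    F_A = mean(rowSums(wA * numA)))
}

#' @rdname ecosystem_functions
#' @return `window_average_metabolism`: named vector `c(X_A, X_P)`.
#' @export
window_average_metabolism <- function(traj, community = traj$community, p) {
  idx <- window_indices(traj)
  xA <- metabolic_rate(community$masses_animals, p$x_A, p$metab_exp)
  xP <- metabolic_rate(community$masses_plants, p$x_P, p$metab_exp)
  c(X_A = sum(xA * colMeans(traj$A[idx, , drop = FALSE])),
    X_P = sum(xP * colMeans(traj$P[idx, , drop = FALSE])))
}

#' Average individual body mass of a guild
#'
#' Two definitions are supported. The default, `"numbers"`, is total
#' biomass over total individual density, `sum(B_i) / sum(B_i / m_i)` --
#' the mass of the average individual. The alternative, `"biomass"`, is the
#' biomass-weighted mean `sum(m_i B_i) / sum(B_i)` -- the mass of the
#' average unit of biomass. Both use window-mean biomasses.
#'
#' @param mean_biomass window-mean biomass per species of one guild.
#' @param masses body masses of the same species.
#' @param type `"numbers"` (default) or `"biomass"`.
#' @return The average individual body mass, or `NA` if the guild carries
#'   no biomass.
#' @export
mean_individual_mass <- function(mean_biomass, masses,
                                 type = c("numbers", "biomass")) {
  type <- match.arg(type)
  tot <- sum(mean_biomass)
  if (tot <= 0) return(NA_real_)
  if (type == "numbers") tot / sum(mean_biomass / masses)
  else sum(masses * mean_biomass) / tot
}

#' Per-replicate ecosystem-function record
#'
#' Assembles the one-row summary used by the richness sweep: initial and
#' surviving richness, the six ecosystem functions, both average body-mass
#' definitions per guild, the discard flag and solver status. Discarded
#' replicates are computed and stored but flagged; exclusion happens at the
#' statistics stage.
#'
#' @param traj an `atn_trajectory`.
#' @param community,cache,p the replicate's community, rate cache and
#'   parameters.
#' @param seed the replicate seed (bookkeeping only).
#' @return A one-row `data.frame`.
#' @export
function_record <- function(traj, community = traj$community, cache, p,
                            seed = NA_integer_) {
  stocks <- window_average_stocks(traj, community)
  flows <- window_average_flows(traj, community, cache, p)
  metab <- window_average_metabolism(traj, community, p)
  idx <- window_indices(traj)
  meanA <- colMeans(traj$A[idx, , drop = FALSE])
  meanP <- colMeans(traj$P[idx, , drop = FALSE])
  data.frame(
    seed = seed,
    S_A_init = community$S_A,
    S_P_init = community$S_P,
    S_A_final = sum(traj$final_state$A > 0),
    S_P_final = sum(traj$final_state$P > 0),
    A_total = stocks[["A_total"]],
    P_total = stocks[["P_total"]],
    F_P = flows[["F_P"]],
    F_A = flows[["F_A"]],
    X_A = metab[["X_A"]],
    X_P = metab[["X_P"]],
    mean_mass_animals = mean_individual_mass(meanA, community$masses_animals),
    mean_mass_plants = mean_individual_mass(meanP, community$masses_plants),
    mean_mass_animals_bw = mean_individual_mass(meanA,
                                                community$masses_animals,
                                                "biomass"),
    mean_mass_plants_bw = mean_individual_mass(meanP,
                                               community$masses_plants,
                                               "biomass"),
    discarded = is_discarded(traj, community),
    status = traj$status
  )
}
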