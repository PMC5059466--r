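#' Capture coefficient
#'
#' Mass-scaled encounter/attack factor of the functional response:
#' `b_ij = b0 * m_i^beta_i * m_j^beta_j * L_ij`, where the resource exponent
#' is `p$beta_res_animal` for animal resources and the constant
#' `p$beta_res_plant` for sessile plant resources. A pruned link
#' (`L_ij = 0`) carries no capture.
#'
#' @param m_cons,m_res consumer and resource body masses.
#' @param is_plant_resource logical; TRUE where the resource is a plant.
#' @param L feeding efficiency in \[0, 1\] (see [feeding_efficiency()]).
#' @param p an `atn_parameters` object.
#' @return Capture coefficients (same shape as the recycled inputs).
#' @export
capture_coefficient <- function(m_cons, m_res, is_plant_resource, L, p) {
  if (any(m_cons <= 0) || any(m_res <= 0))
    stop("body masses must be positive", call. = FALSE)
  beta_res <- ifelse(is_plant_resource, p$beta_res_plant, p$beta_res_animal)
  p$b0 * m_cons^p$beta_cons * m_res^beta_res * L
}

#' Handling time
#'
#' Time a consumer is occupied per unit of resource biomass consumed:
#' `h_ij = h0 * m_i^eta_i * m_j^eta_j`. Sets the saturation level of the
#' functional response (maximum intake `1 / h_ij` per capita).
#'
#' @inheritParams capture_coefficient
#' @return Handling times.
#' @export
handling_time <- function(m_cons, m_res, p) {
  if (any(m_cons <= 0) || any(m_res <= 0))
    stop("body masses must be positive", call. = FALSE)
  p$h0 * m_cons^p$eta_cons * m_res^p$eta_res
}

#' Per-unit-biomass metabolic rate
#'
#' `x(m) = x0 * m^metab_exp` with `metab_exp = -1/4` by default, the
#' per-unit-biomass counterpart of 3/4-power per-capita metabolic scaling.
#'
#' @param m body mass (> 0).
#' @param x0 guild scaling constant (0.314 for animals, 0.138 for plants by
#'   default).
#' @param metab_exp mass exponent.
#' @return Metabolic loss rate per unit biomass.
#' @export
metabolic_rate <- function(m, x0, metab_exp = -0.25) {
  if (any(m <= 0)) stop("body mass must be positive", call. = FALSE)
  x0 * m^metab_exp
}

#' Liebig nutrient growth factor
#'
#' Plant growth limitation by the scarcest nutrient: the minimum over
#' nutrients of Monod terms `N_l / (K_il + N_l)`. Approaches 1 at high
#' concentrations of both nutrients and is 0 whenever the limiting nutrient
#' is absent.
#'
#' @param N nutrient concentrations (length 2, >= 0).
#' @param K half-saturation densities: a length-2 vector for one plant or an
#'   `S_P` x 2 matrix for the whole guild.
#' @return Growth factor(s) in \[0, 1).
#' @export
growth_factor <- function(N, K) {
  if (any(N < 0)) stop("negative nutrient concentration", call. = FALSE)
  if (is.matrix(K)) {
    pmin(N[1] / (K[, 1] + N[1]), N[2] / (K[, 2] + N[2]))
  } else {
    min(N / (K + N))
  }
}

#' Precompute the per-replicate rate cache
#'
#' Builds the capture-coefficient matrix `b`, handling-time matrix `h`
#' (animals x resources, plant columns first, both zeroed on pruned links
#' for `b`), the per-unit-biomass metabolic rates of both guilds, and the
#' intrinsic plant growth rates `r_i = r0 * m_i^growth_exp`. The cache is a
#' pure function of (community, parameters) and is never serialized as
#' ground truth.
#'
#' @param community a linked `atn_community` (after [build_food_web()]).
#' @param p an `atn_parameters` object.
#' @return An object of class `atn_rate_cache`.
#' @export
rate_cache <- function(community, p) {
  stopifnot(inherits(community, "atn_community"),
            !is.null(community$link_efficiency))
  m_res <- c(community$masses_plants, community$masses_animals)
  is_plant <- c(rep(TRUE, community$S_P), rep(FALSE, community$S_A))
  ma <- community$masses_animals
  b <- p$b0 * outer(ma^p$beta_cons,
                    m_res^ifelse(is_plant, p$beta_res_plant,
                                 p$beta_res_animal)) *
    community$link_efficiency
  h <- p$h0 * outer(ma^p$eta_cons, m_res^p$eta_res)
  structure(list(
    b = b, h = h,
    x_animals = metabolic_rate(ma, p$x_A, p$metab_exp),
    x_plants = metabolic_rate(community$masses_plants, p$x_P, p$metab_exp),
    r = p$r0 * community$masses_plants^p$growth_exp
  ), class = "atn_rate_cache")
}

#' Multi-prey functional response of one consumer
#'
#' Per-unit-consumer-biomass feeding rates of animal `consumer_index` on
#' every resource, from a Beddington-DeAngelis-type multi-prey response with
#' Hill exponent `1 + q`:
#' \deqn{F_{ij} = \frac{\omega_i b_{ij} R_j^{1+q}}{m_i\,(1 + c A_i +
#'   \omega_i \sum_k b_{ik} h_{ik} R_k^{1+q})}}
#' The `c A_i` term is intra-specific interference; the Hill exponent
#' interpolates between type II (`q = 0`) and type III (`q = 1`) responses.
#'
#' @param consumer_index animal index (1-based).
#' @param state an `atn_state` (see [initialize_state()]).
#' @param community linked community.
#' @param cache [rate_cache()] for the same community and parameters.
#' @param p parameter set.
#' @return Vector of feeding rates over resources (plants first), in units
#'   of resource biomass per unit consumer biomass per unit time.
#' @export
feeding_rates <- function(consumer_index, state, community, cache, p) {
  Fm <- feeding_matrix(state, community, cache, p)
  Fm[consumer_index, ]
}

#' All pairwise feeding rates at one state
#'
#' Matrix version of [feeding_rates()]: rows are animal consumers, columns
#' resources (plants first). Negative biomasses are rejected; extinct
#' (zero-biomass) resources yield exactly zero rates.
#'
#' @inheritParams feeding_rates
#' @return `S_A` x `(S_P + S_A)` matrix of feeding rates.
#' @export
feeding_matrix <- function(state, community, cache, p) {
  A <- state$A
  R <- c(state$P, state$A)
  if (any(R < 0) || any(state$N < 0))
    stop("negative biomass or nutrient in state", call. = FALSE)
  Rpow <- R^(1 + p$q)
  sat <- as.vector((cache$b * cache$h) %*% Rpow)         # per-consumer sum
  denom <- community$masses_animals *
    (1 + p$c * A + community$omega * sat)
  sweep(cache$b, 2, Rpow, "*") * (community$omega / denom)
}
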