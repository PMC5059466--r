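#' @name dynamics
#' @title Right-hand side of the plant-animal-nutrient system
#'
#' @description
#' The coupled differential system has three blocks. Animals gain biomass
#' from herbivory and carnivory (discounted by the assimilation efficiencies
#' `e_P` and `e_A`), lose it to predation by other animals and to
#' metabolism:
#' \deqn{\dot A_i = A_i\,(e_P \sum_{j \in plants} F_{ij} +
#'   e_A \sum_{j \in animals} F_{ij}) - \sum_k F_{ki} A_k - x_i A_i.}
#' Plants grow by nutrient uptake and lose biomass to grazing and
#' metabolism:
#' \deqn{\dot P_i = r_i G_i(N) P_i - \sum_k F_{ki} A_k - x_i P_i.}
#' Nutrients relax toward their supply concentration and are drained by
#' plant growth in proportion to their relative content `v_l` in plant
#' biomass:
#' \deqn{\dot N_l = D (S_l - N_l) - v_l \sum_i r_i G_i(N) P_i.}
#' A species at exactly zero biomass has zero derivative: extinction is
#' absorbing. All feeding rates and growth factors are evaluated once per
#' call and shared between gain, mortality and uptake terms, so the
#' assimilation bookkeeping (animal gains equal `e` times resource losses)
#' holds to machine precision.
#'
#' These R functions are the reference implementation; the integrator uses
#' an equivalent compiled version which the test suite cross-checks against
#' them on random states.
NULL

#' State constructor
#'
#' @param A,P animal and plant biomass densities (>= 0).
#' @param N nutrient concentrations (length 2, >= 0).
#' @return An object of class `atn_state`.
#' @export
atn_state <- function(A, P, N) {
  stopifnot(length(N) == 2)
  if (any(!is.finite(c(A, P, N)))) stop("non-finite state", call. = FALSE)
  structure(list(A = as.numeric(A), P = as.numeric(P), N = as.numeric(N)),
            class = "atn_state")
}

check_state <- function(state, community) {
  if (!all(is.finite(c(state$A, state$P, state$N))))
    stop("non-finite value in state", call. = FALSE)
  if (length(state$A) != community$S_A || length(state$P) != community$S_P)
    stop("state dimensions do not match the community", call. = FALSE)
  invisible(state)
}

#' @rdname dynamics
#' @param state an `atn_state`.
#' @param community a linked `atn_community`.
#' @param cache a [rate_cache()].
#' @param p an `atn_parameters` object.
#' @return `animal_derivatives`, `plant_derivatives` and
#'   `nutrient_derivatives` return numeric vectors; `rhs` returns a list
#'   with components `dA`, `dP`, `dN` computed from one shared evaluation of
#'   the feeding matrix and growth factors.
#' @export
rhs <- function(state, community, cache, p) {
  check_state(state, community)
  S_P <- community$S_P
  Fm <- feeding_matrix(state, community, cache, p)    # S_A x (S_P + S_A)
  G <- growth_factor(state$N, p$K)
  gains <- p$e_P * rowSums(Fm[, seq_len(S_P), drop = FALSE]) +
    p$e_A * rowSums(Fm[, S_P + seq_len(community$S_A), drop = FALSE])
  loss <- as.vector(crossprod(Fm, state$A))           # predation on each resource
  uptake <- cache$r * G * state$P
  list(
    dA = state$A * gains - loss[S_P + seq_len(community$S_A)] -
      cache$x_animals * state$A,
    dP = uptake - loss[seq_len(S_P)] - cache$x_plants * state$P,
    dN = p$D * (p$S_supply - state$N) - p$v * sum(uptake)
  )
}

#' @rdname dynamics
#' @export
animal_derivatives <- function(state, community, cache, p) {
  rhs(state, community, cache, p)$dA
}

#' @rdname dynamics
#' @export
plant_derivatives <- function(state, community, cache, p) {
  rhs(state, community, cache, p)$dP
}

#' @rdname dynamics
#' @export
nutrient_derivatives <- function(state, community, cache, p) {
  rhs(state, community, cache, p)$dN
}
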