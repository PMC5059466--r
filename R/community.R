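#' Sampling configuration for allometric food-web replicates
#'
#' Collects every constant and sampling distribution needed to draw one
#' food-web replicate: body-mass ranges, the allometric exponent
#' distributions of the capture coefficient and handling time, the Hill
#' exponent and interference distributions, the Ricker kernel shape, and the
#' nutrient model constants.
#'
#' Defaults follow the published allometric food-web model. The means and
#' standard deviations of the capture exponents (`beta_cons`,
#' `beta_res_animal`) and handling exponents (`eta_cons`, `eta_res`) are
#' sourced from the released simulation code of that model (they trace back
#' to meta-analytic estimates of feeding-rate allometries); they are exposed
#' here so sensitivity variants can override them.
#'
#' @param mass_range_plants log10 body-mass range for plants (inclusive).
#' @param mass_range_animals log10 body-mass range for animals (inclusive).
#' @param beta_cons,beta_res_animal `c(mean, sd)` of the normal distributions
#'   for the consumer and animal-resource capture exponents; draws are
#'   truncated to the exclusive interval mean +/- 3 sd.
#' @param beta_res_plant constant capture exponent for plant resources
#'   (plants do not move, so encounter rates do not scale with their mass).
#' @param eta_cons,eta_res `c(mean, sd)` for the handling-time exponents,
#'   truncated like the capture exponents.
#' @param q `c(mean, sd)` for the Hill-exponent modifier, truncated to the
#'   inclusive interval \[0, 1\].
#' @param interference `c(mean, sd)` for the consumer interference constant
#'   `c`; truncated to mean +/- 3 sd to keep the interference term positive.
#' @param supply `c(mean, sd)` of the nutrient supply concentrations,
#'   truncated to be strictly positive.
#' @param gamma width of the Ricker feeding kernel.
#' @param R_opt optimal consumer/resource body-mass ratio.
#' @param b0 capture-coefficient scaling constant.
#' @param h0 handling-time scaling constant.
#' @param e_P,e_A assimilation efficiencies for herbivory and carnivory.
#' @param x_A,x_P metabolic-rate constants for animals and plants.
#' @param metab_exp per-unit-biomass metabolic mass exponent (the -1/4 of
#'   3/4-power per-capita metabolic scaling).
#' @param r0,growth_exp scaling constant and mass exponent of the intrinsic
#'   plant growth rate.
#' @param D nutrient turnover rate.
#' @param v relative nutrient content of plant biomass, one value per
#'   nutrient.
#' @param K_range inclusive uniform range of the nutrient half-saturation
#'   densities.
#' @param prune_epsilon feeding-efficiency threshold below which links are
#'   removed from the network.
#' @param max_redraws retry budget per truncated draw before an error is
#'   raised (guards against mis-configured distributions).
#' @return An object of class `atn_config` (a named list).
#' @export
sampling_config <- function(mass_range_plants = c(0, 6),
                            mass_range_animals = c(2, 12),
                            beta_cons = c(mean = 0.42, sd = 0.05),
                            beta_res_animal = c(mean = 0.19, sd = 0.04),
                            beta_res_plant = 0,
                            eta_cons = c(mean = -0.48, sd = 0.03),
                            eta_res = c(mean = -0.66, sd = 0.02),
                            q = c(mean = 0.5, sd = 0.2),
                            interference = c(mean = 0.8, sd = 0.2),
                            supply = c(mean = 10, sd = 2),
                            gamma = 2,
                            R_opt = 100,
                            b0 = 50,
                            h0 = 0.4,
                            e_P = 0.45,
                            e_A = 0.85,
                            x_A = 0.314,
                            x_P = 0.138,
                            metab_exp = -0.25,
                            r0 = 1,
                            growth_exp = -0.25,
                            D = 0.25,
                            v = c(1, 0.5),
                            K_range = c(0.1, 0.2),
                            prune_epsilon = 0.01,
                            max_redraws = 10000) {
  two <- function(x, nm) {
    x <- unname(as.numeric(x))
    if (length(x) != 2 || anyNA(x) || x[2] < 0)
      stop(sprintf("'%s' must be c(mean, sd) with sd >= 0", nm), call. = FALSE)
    c(mean = x[1], sd = x[2])
  }
  cfg <- list(
    mass_range_plants = as.numeric(mass_range_plants),
    mass_range_animals = as.numeric(mass_range_animals),
    beta_cons = two(beta_cons, "beta_cons"),
    beta_res_animal = two(beta_res_animal, "beta_res_animal"),
    beta_res_plant = as.numeric(beta_res_plant),
    eta_cons = two(eta_cons, "eta_cons"),
    eta_res = two(eta_res, "eta_res"),
    q = two(q, "q"),
    interference = two(interference, "interference"),
    supply = two(supply, "supply"),
    gamma = gamma, R_opt = R_opt, b0 = b0, h0 = h0,
    e_P = e_P, e_A = e_A, x_A = x_A, x_P = x_P,
    metab_exp = metab_exp, r0 = r0, growth_exp = growth_exp,
    D = D, v = as.numeric(v), K_range = as.numeric(K_range),
    prune_epsilon = prune_epsilon,
    max_redraws = as.integer(max_redraws)
  )
  stopifnot(cfg$gamma > 0, cfg$R_opt > 0, length(cfg$v) == 2,
            cfg$K_range[1] <= cfg$K_range[2], cfg$max_redraws >= 1)
  class(cfg) <- "atn_config"
  cfg
}

#' Ricker feeding-efficiency kernel
#'
#' Success probability of a consumer attacking and capturing an encountered
#' resource, as a hump-shaped asymmetric (Ricker) function of the
#' consumer/resource body-mass ratio. It is maximal (exactly 1) when the
#' ratio equals `R_opt` and decays to zero for much smaller or much larger
#' resources; decay is exponential above the optimum and power-law-tempered
#' below it. The kernel depends on the two masses only through their ratio.
#'
#' @param m_cons,m_res consumer and resource body masses (recycled).
#' @param R_opt optimal consumer/resource mass ratio.
#' @param gamma kernel width exponent.
#' @return Feeding efficiencies in \[0, 1\].
#' @examples
#' feeding_efficiency(100, 1)      # at the optimum: 1
#' feeding_efficiency(200, 1)      # above the optimum: (2 * exp(-1))^2
#' @export
feeding_efficiency <- function(m_cons, m_res, R_opt = 100, gamma = 2) {
  if (any(m_cons <= 0) || any(m_res <= 0))
    stop("body masses must be positive", call. = FALSE)
  rho <- m_cons / (m_res * R_opt)
  (rho * exp(1 - rho))^gamma
}

#' Sample body masses for one community
#'
#' Draws log10 body masses from independent uniform distributions, on
#' `cfg$mass_range_plants` for plants and `cfg$mass_range_animals` for
#' animals, and returns them on the linear scale as an unlinked community
#' skeleton. Draws come from R's global RNG; seed upstream for
#' reproducibility.
#'
#' @param S_P,S_A number of plant and animal species (>= 1).
#' @param cfg an [sampling_config()] object.
#' @return An `atn_community` with masses only; call [build_food_web()] to
#'   attach the link structure.
#' @export
sample_body_masses <- function(S_P, S_A, cfg = sampling_config()) {
  if (length(S_P) != 1 || length(S_A) != 1 || is.na(S_P) || is.na(S_A) ||
      S_P < 1 || S_A < 1)
    stop("S_P and S_A must be positive counts", call. = FALSE)
  mp <- 10^stats::runif(S_P, cfg$mass_range_plants[1], cfg$mass_range_plants[2])
  ma <- 10^stats::runif(S_A, cfg$mass_range_animals[1], cfg$mass_range_animals[2])
  new_community(mp, ma)
}

new_community <- function(masses_plants, masses_animals,
                          herbivore_only = NULL) {
  stopifnot(all(masses_plants > 0), all(masses_animals > 0))
  if (is.null(herbivore_only))
    herbivore_only <- rep(FALSE, length(masses_animals))
  structure(list(
    masses_plants = as.numeric(masses_plants),
    masses_animals = as.numeric(masses_animals),
    S_P = length(masses_plants),
    S_A = length(masses_animals),
    link_efficiency = NULL,
    omega = NULL,
    herbivore_only = as.logical(herbivore_only)
  ), class = "atn_community")
}

#' @export
print.atn_community <- function(x, ...) {
  cat(sprintf("Allometric community: %d plants, %d animals\n", x$S_P, x$S_A))
  cat(sprintf("  plant masses : [%.3g, %.3g]\n",
              min(x$masses_plants), max(x$masses_plants)))
  cat(sprintf("  animal masses: [%.3g, %.3g]\n",
              min(x$masses_animals), max(x$masses_animals)))
  if (!is.null(x$link_efficiency)) {
    nl <- sum(x$link_efficiency > 0)
    cat(sprintf("  links        : %d (connectance %.3f)\n", nl,
                nl / (x$S_A * (x$S_P + x$S_A))))
  } else {
    cat("  links        : not built (run build_food_web)\n")
  }
  if (any(x$herbivore_only))
    cat(sprintf("  strict herbivores: %d\n", sum(x$herbivore_only)))
  invisible(x)
}

#' Assemble the pruned feeding network
#'
#' Computes the Ricker feeding efficiency for every (animal, resource) pair,
#' resources being all plants followed by all animals, removes weak links
#' with efficiency below `eps`, excludes self-links, and assigns each animal
#' the relative consumption weight `omega = 1 / number of resource species`
#' (0 for animals left without resources, which will starve dynamically).
#' Animals flagged in `community$herbivore_only` have all their
#' animal-resource links removed before weights are computed (strict
#' herbivory sensitivity variant).
#'
#' @param community an `atn_community` with masses populated.
#' @param eps pruning threshold on the feeding efficiency.
#' @param R_opt,gamma Ricker kernel parameters.
#' @return The community with `link_efficiency` (`S_A` x `S_P + S_A` matrix,
#'   plant columns first) and `omega` filled in.
#' @export
build_food_web <- function(community, eps = 0.01, R_opt = 100, gamma = 2) {
  stopifnot(inherits(community, "atn_community"))
  m_res <- c(community$masses_plants, community$masses_animals)
  L <- outer(community$masses_animals, m_res,
             function(mc, mr) feeding_efficiency(mc, mr, R_opt, gamma))
  S_P <- community$S_P
  # self-predation is excluded regardless of eps
  L[cbind(seq_len(community$S_A), S_P + seq_len(community$S_A))] <- 0
  if (any(community$herbivore_only))
    L[community$herbivore_only, S_P + seq_len(community$S_A)] <- 0
  L[L < eps] <- 0
  nres <- rowSums(L > 0)
  community$link_efficiency <- L
  community$omega <- ifelse(nres > 0, 1 / nres, 0)
  community$prune_epsilon <- eps
  community
}

# truncated-normal draw by redraw; bounds checked per `exclusive`
rnorm_trunc <- function(n, mean, sd, lower, upper, exclusive = TRUE,
                        max_redraws = 10000) {
  mean <- unname(mean); sd <- unname(sd)
  lower <- unname(lower); upper <- unname(upper)
  if (sd == 0) {
    if (mean < lower || mean > upper ||
        (exclusive && (mean <= lower || mean >= upper) && lower != upper))
      stop("degenerate distribution outside truncation bounds", call. = FALSE)
    return(rep(mean, n))
  }
  inside <- if (exclusive) function(x) x > lower & x < upper
            else function(x) x >= lower & x <= upper
  out <- rep(NA_real_, n)
  need <- seq_len(n)
  for (i in seq_len(max_redraws)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- inside(draw)
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (!length(need)) return(out)
  }
  stop("truncated sampling failed: retry budget exhausted ",
       "(check the configured distribution)", call. = FALSE)
}

#' Sample the per-replicate parameter set
#'
#' Draws one value per food-web replicate (not per species) of each sampled
#' constant: the capture exponents `beta_i` (consumer) and `beta_j` (animal
#' resource), the handling exponents `eta_i` and `eta_j` (all truncated to
#' the exclusive interval mean +/- 3 sd), the Hill modifier `q` (truncated to
#' the inclusive interval \[0, 1\]), the interference constant `c`, the two
#' nutrient supply concentrations (truncated > 0), and the per-plant
#' half-saturation densities `K` (uniform on `cfg$K_range`). All fixed
#' constants are copied from `cfg`.
#'
#' @param cfg an [sampling_config()].
#' @param S_P number of plant species (sets the rows of `K`).
#' @return An object of class `atn_parameters`.
#' @export
sample_parameters <- function(cfg = sampling_config(), S_P = 30) {
  tr3 <- function(d) rnorm_trunc(1, d["mean"], d["sd"],
                                 d["mean"] - 3 * d["sd"],
                                 d["mean"] + 3 * d["sd"],
                                 exclusive = TRUE,
                                 max_redraws = cfg$max_redraws)
  p <- list(
    beta_cons = tr3(cfg$beta_cons),
    beta_res_animal = tr3(cfg$beta_res_animal),
    beta_res_plant = cfg$beta_res_plant,
    eta_cons = tr3(cfg$eta_cons),
    eta_res = tr3(cfg$eta_res),
    q = rnorm_trunc(1, cfg$q["mean"], cfg$q["sd"], 0, 1,
                    exclusive = FALSE, max_redraws = cfg$max_redraws),
    c = tr3(cfg$interference),
    gamma = cfg$gamma, R_opt = cfg$R_opt,
    b0 = cfg$b0, h0 = cfg$h0,
    e_P = cfg$e_P, e_A = cfg$e_A,
    x_A = cfg$x_A, x_P = cfg$x_P, metab_exp = cfg$metab_exp,
    r0 = cfg$r0, growth_exp = cfg$growth_exp,
    D = cfg$D, v = cfg$v,
    S_supply = rnorm_trunc(2, cfg$supply["mean"], cfg$supply["sd"],
                           0, Inf, exclusive = TRUE,
                           max_redraws = cfg$max_redraws),
    K = matrix(stats::runif(S_P * 2, cfg$K_range[1], cfg$K_range[2]),
               nrow = S_P, ncol = 2)
  )
  class(p) <- "atn_parameters"
  p
}

#' @export
print.atn_parameters <- function(x, ...) {
  cat("Replicate parameter set\n")
  cat(sprintf("  capture : b0=%g beta_i=%.4f beta_j=%.4f (plants: %g)\n",
              x$b0, x$beta_cons, x$beta_res_animal, x$beta_res_plant))
  cat(sprintf("  handling: h0=%g eta_i=%.4f eta_j=%.4f\n",
              x$h0, x$eta_cons, x$eta_res))
  cat(sprintf("  response: q=%.4f c=%.4f\n", x$q, x$c))
  cat(sprintf("  nutrients: D=%g S=(%.3f, %.3f) v=(%g, %g)\n",
              x$D, x$S_supply[1], x$S_supply[2], x$v[1], x$v[2]))
  invisible(x)
}
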