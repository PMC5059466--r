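# shared helpers: tiny deterministic fixtures and independent oracles

# parameter set with all sampled quantities pinned to their means
fixed_parameters <- function(S_P = 3, q = 0.5, cc = 0.8) {
  cfg <- sampling_config(beta_cons = c(0.42, 0), beta_res_animal = c(0.19, 0),
                         eta_cons = c(-0.48, 0), eta_res = c(-0.66, 0),
                         q = c(q, 0), interference = c(cc, 0),
                         supply = c(10, 0), K_range = c(0.15, 0.15))
  sample_parameters(cfg, S_P = S_P)
}

# small linked community with deterministic masses
tiny_community <- function(masses_plants = c(1, 50, 2500),
                           masses_animals = c(1e2, 5e3, 2.5e5),
                           eps = 0.01, herbivore_only = NULL) {
  comm <- atnsim:::new_community(masses_plants, masses_animals,
                                 herbivore_only = herbivore_only)
  build_food_web(comm, eps = eps)
}

random_state <- function(community, p, scale = 10) {
  atn_state(A = stats::runif(community$S_A, 0, scale),
            P = stats::runif(community$S_P, 0, scale),
            N = stats::runif(2, 0.1, max(p$S_supply)))
}

# independent, naive per-pair evaluation of the functional response: scalar
# loops straight from the formula, sharing no code with feeding_matrix()
naive_feeding_matrix <- function(state, community, cache, p) {
  S_P <- community$S_P
  S_A <- community$S_A
  R <- c(state$P, state$A)
  Fm <- matrix(0, S_A, S_P + S_A)
  for (i in seq_len(S_A)) {
    sat <- 0
    for (k in seq_len(S_P + S_A))
      sat <- sat + cache$b[i, k] * cache$h[i, k] * R[k]^(1 + p$q)
    den <- community$masses_animals[i] *
      (1 + p$c * state$A[i] + community$omega[i] * sat)
    for (j in seq_len(S_P + S_A))
      Fm[i, j] <- community$omega[i] * cache$b[i, j] * R[j]^(1 + p$q) / den
  }
  Fm
}

# independent assembly of the three derivative blocks from a feeding matrix
naive_rhs <- function(state, community, cache, p) {
  Fm <- naive_feeding_matrix(state, community, cache, p)
  S_P <- community$S_P
  S_A <- community$S_A
  G <- vapply(seq_len(S_P), function(i)
    min(state$N[1] / (p$K[i, 1] + state$N[1]),
        state$N[2] / (p$K[i, 2] + state$N[2])), 0)
  dA <- numeric(S_A)
  dP <- numeric(S_P)
  for (i in seq_len(S_A)) {
    gain <- p$e_P * sum(Fm[i, seq_len(S_P)]) +
      p$e_A * sum(Fm[i, S_P + seq_len(S_A)])
    pred <- sum(Fm[, S_P + i] * state$A)
    dA[i] <- state$A[i] * gain - pred - cache$x_animals[i] * state$A[i]
  }
  upt <- numeric(S_P)
  for (i in seq_len(S_P)) {
    upt[i] <- cache$r[i] * G[i] * state$P[i]
    dP[i] <- upt[i] - sum(Fm[, i] * state$A) - cache$x_plants[i] * state$P[i]
  }
  list(dA = dA, dP = dP,
       dN = p$D * (p$S_supply - state$N) - p$v * sum(upt))
}

# synthetic trajectory object for the windowing functions
fake_trajectory <- function(times, A, P, N, community,
                            final_state = NULL) {
  if (is.null(final_state))
    final_state <- atn_state(A = A[nrow(A), ], P = P[nrow(P), ],
                             N = N[nrow(N), ])
  structure(list(times = times, A = A, P = P, N = N,
                 extinctions = data.frame(),
                 status = "ok", n_steps = 0, t_last = max(times),
                 final_state = final_state,
                 window_start = min(times),
                 community = community,
                 settings = NULL),
            class = "atn_trajectory")
}

fast_settings <- function(t_end = 2000, eval_window = 500, ...) {
  simulation_settings(t_end = t_end, eval_window = eval_window, ...)
}
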