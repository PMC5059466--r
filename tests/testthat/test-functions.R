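test_that("window averages of stocks recover injected signals", {
  comm <- tiny_community()
  tt <- 0:1000
  # constant trajectory: the average is the constant sum
  A <- matrix(rep(c(1, 2, 3), each = length(tt)), ncol = 3)
  P <- matrix(rep(c(4, 5, 6), each = length(tt)), ncol = 3)
  N <- matrix(1, length(tt), 2)
  traj <- fake_trajectory(tt, A, P, N, comm)
  s <- window_average_stocks(traj)
  expect_identical(s[["A_total"]], 6)
  expect_identical(s[["P_total"]], 15)
  # all animals extinct
  traj0 <- fake_trajectory(tt, A * 0, P, N, comm)
  expect_identical(window_average_stocks(traj0)[["A_total"]], 0)
  # sinusoid of known mean, integer number of periods over the window
  A2 <- A; A2[, 1] <- 1 + 0.5 * sin(2 * pi * tt / 100)
  s2 <- window_average_stocks(fake_trajectory(tt, A2, P, N, comm))
  expect_equal(s2[["A_total"]], 6, tolerance = 1e-3)
})

test_that("window flows equal standalone functional-response evaluations", {
  pair <- tiny_community(masses_plants = 50, masses_animals = 5000)
  p <- fixed_parameters(S_P = 1)
  cache <- rate_cache(pair, p)
  tt <- 0:100
  A <- matrix(2, length(tt), 1)
  P <- matrix(7, length(tt), 1)
  N <- matrix(5, length(tt), 2)
  traj <- fake_trajectory(tt, A, P, N, pair)
  fl <- window_average_flows(traj, pair, cache = cache, p = p)
  Fij <- feeding_rates(1, atn_state(A = 2, P = 7, N = c(5, 5)),
                       pair, cache, p)
  expect_equal(fl[["F_P"]], Fij[1] * 2, tolerance = 1e-12)
  expect_identical(fl[["F_A"]], 0)
  # no surviving animals: both flows vanish
  fl0 <- window_average_flows(fake_trajectory(tt, A * 0, P, N, pair),
                              pair, cache = cache, p = p)
  expect_identical(unname(fl0), c(0, 0))
  # strict-herbivore web: F_A is exactly zero even with animals present
  commh <- tiny_community(herbivore_only = rep(TRUE, 3))
  ph <- fixed_parameters()
  cacheh <- rate_cache(commh, ph)
  A3 <- matrix(2, length(tt), 3); P3 <- matrix(3, length(tt), 3)
  flh <- window_average_flows(fake_trajectory(tt, A3, P3, N, commh),
                              commh, cache = cacheh, p = ph)
  expect_identical(flh[["F_A"]], 0)
})

test_that("flows recomputed on the grid match a naive per-sample loop", {
  res <- simulate_replicate(5, 4, seed = 42,
                            settings = fast_settings(t_end = 600,
                                                     eval_window = 50),
                            keep_trajectory = TRUE)
  traj <- res$trajectory
  comm <- res$community
  cache <- rate_cache(comm, res$parameters)
  fl <- window_average_flows(traj, comm, cache = cache, p = res$parameters)
  idx <- which(traj$times >= traj$window_start - 1e-9)
  fp <- fa <- numeric(length(idx))
  for (k in seq_along(idx)) {
    st <- atn_state(A = traj$A[idx[k], ], P = traj$P[idx[k], ],
                    N = traj$N[idx[k], ])
    Fm <- naive_feeding_matrix(st, comm, cache, res$parameters)
    fp[k] <- sum(st$A * rowSums(Fm[, seq_len(comm$S_P), drop = FALSE]))
    fa[k] <- sum(st$A * rowSums(Fm[, -seq_len(comm$S_P), drop = FALSE]))
  }
  expect_equal(fl[["F_P"]], mean(fp), tolerance = 1e-10)
  expect_equal(fl[["F_A"]], mean(fa), tolerance = 1e-10)
})

test_that("metabolic losses scale with window-mean biomass", {
  one <- tiny_community(masses_plants = 1, masses_animals = 1)
  p <- fixed_parameters(S_P = 1)
  tt <- 0:10
  traj <- fake_trajectory(tt, matrix(2, 11, 1), matrix(0, 11, 1),
                          matrix(5, 11, 2), one)
  xm <- window_average_metabolism(traj, one, p = p)
  expect_equal(xm[["X_A"]], 0.628, tolerance = 1e-12)
  expect_identical(xm[["X_P"]], 0)
  # linearity in biomass
  traj3 <- fake_trajectory(tt, matrix(6, 11, 1), matrix(0, 11, 1),
                           matrix(5, 11, 2), one)
  expect_equal(window_average_metabolism(traj3, one, p = p)[["X_A"]],
               3 * xm[["X_A"]], tolerance = 1e-12)
})

test_that("mean individual mass supports both definitions", {
  expect_identical(mean_individual_mass(3, 42), 42)
  expect_identical(mean_individual_mass(3, 42, "biomass"), 42)
  # two species, equal biomass, masses 10 and 1000
  expect_equal(mean_individual_mass(c(1, 1), c(10, 1000)),
               2 / (1 / 10 + 1 / 1000), tolerance = 1e-12)
  expect_equal(mean_individual_mass(c(1, 1), c(10, 1000), "biomass"), 505)
  # shifting biomass toward the heavier species raises both definitions
  w <- seq(0.1, 0.9, by = 0.1)
  mm <- vapply(w, function(x)
    mean_individual_mass(c(1 - x, x), c(10, 1000)), 0)
  expect_true(all(diff(mm) > 0))
  expect_true(is.na(mean_individual_mass(c(0, 0), c(10, 1000))))
})

test_that("ecosystem functions are invariant to species permutation", {
  res <- simulate_replicate(6, 5, seed = 77,
                            settings = fast_settings(t_end = 600,
                                                     eval_window = 50),
                            keep_trajectory = TRUE)
  traj <- res$trajectory
  comm <- res$community
  p <- res$parameters
  cache <- rate_cache(comm, p)
  rec <- function_record(traj, comm, cache, p)
  # permute plants and animals consistently everywhere
  ip <- sample(comm$S_P); ia <- sample(comm$S_A)
  comm2 <- atnsim:::new_community(comm$masses_plants[ip],
                                  comm$masses_animals[ia],
                                  comm$herbivore_only[ia])
  comm2 <- build_food_web(comm2, eps = 0.01)
  p2 <- p; p2$K <- p$K[ip, , drop = FALSE]
  cache2 <- rate_cache(comm2, p2)
  traj2 <- traj
  traj2$A <- traj$A[, ia, drop = FALSE]
  traj2$P <- traj$P[, ip, drop = FALSE]
  traj2$community <- comm2
  traj2$final_state <- atn_state(A = traj$final_state$A[ia],
                                 P = traj$final_state$P[ip],
                                 N = traj$final_state$N)
  rec2 <- function_record(traj2, comm2, cache2, p2)
  for (col in c("A_total", "P_total", "F_P", "F_A", "X_A", "X_P",
                "mean_mass_animals", "mean_mass_plants"))
    expect_equal(rec2[[col]], rec[[col]], tolerance = 1e-10)
  expect_identical(rec2$discarded, rec$discarded)
})
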