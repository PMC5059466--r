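test_that("body masses fall in the configured log-uniform ranges", {
  set.seed(11)
  for (sa in c(10, 55, 100)) {
    comm <- sample_body_masses(30, sa)
    expect_length(comm$masses_plants, 30)
    expect_length(comm$masses_animals, sa)
    expect_true(all(comm$masses_plants >= 1 & comm$masses_plants <= 1e6))
    expect_true(all(comm$masses_animals >= 1e2 & comm$masses_animals <= 1e12))
  }
  # degenerate (zero-width) range collapses to the exact point mass
  cfg <- sampling_config(mass_range_plants = c(2, 2),
                         mass_range_animals = c(5, 5))
  comm <- sample_body_masses(1, 1, cfg)
  expect_identical(comm$masses_plants, 100)
  expect_identical(comm$masses_animals, 1e5)
  # determinism under a fixed seed
  set.seed(99); m1 <- sample_body_masses(10, 10)
  set.seed(99); m2 <- sample_body_masses(10, 10)
  expect_identical(m1, m2)
  expect_error(sample_body_masses(0, 5), "positive")
})

test_that("Ricker feeding efficiency has the closed form and its geometry", {
  # maximum exactly 1 at the optimal ratio
  expect_identical(feeding_efficiency(100, 1), 1)
  expect_equal(feeding_efficiency(5e7, 5e5), 1)
  # frozen closed-form value at ratio 200: rho = 2, L = (2 e^-1)^2
  expect_equal(feeding_efficiency(200, 1), (2 * exp(-1))^2, tolerance = 1e-15)
  # limits
  expect_lt(feeding_efficiency(1e12, 1), 1e-300)
  expect_lt(feeding_efficiency(1.0001, 1e6), 1e-10)
  # scale invariance: depends only on the mass ratio
  set.seed(4)
  for (i in 1:50) {
    mc <- 10^runif(1, 2, 12); mr <- 10^runif(1, 0, 6); k <- 10^runif(1, -3, 3)
    expect_equal(feeding_efficiency(k * mc, k * mr),
                 feeding_efficiency(mc, mr), tolerance = 1e-12)
  }
  # bounded by 1, equality only at the optimum
  ratios <- 10^seq(-2, 6, length.out = 200)
  L <- feeding_efficiency(ratios, 1)
  expect_true(all(L <= 1))
  expect_true(all(L[abs(ratios - 100) > 1e-9] < 1))
  # asymmetry: slower decay below the optimum than above
  expect_gt(feeding_efficiency(100 / 8, 1), feeding_efficiency(100 * 8, 1))
  expect_error(feeding_efficiency(-1, 1), "positive")
})

test_that("food-web assembly prunes, excludes self-links and sets omega", {
  comm <- tiny_community()
  L <- comm$link_efficiency
  # brute-force recomputation reproduces every entry
  m_res <- c(comm$masses_plants, comm$masses_animals)
  for (i in seq_len(comm$S_A))
    for (j in seq_along(m_res)) {
      raw <- feeding_efficiency(comm$masses_animals[i], m_res[j])
      if (j == comm$S_P + i) raw <- 0            # self-link exclusion
      expected <- if (raw < 0.01) 0 else raw
      expect_identical(L[i, j], expected)
    }
  # every retained link is at or above the threshold
  expect_true(all(L[L > 0] >= 0.01))
  # omega bookkeeping: weights of linked resources sum to one
  for (i in seq_len(comm$S_A)) {
    nres <- sum(L[i, ] > 0)
    if (nres > 0) expect_equal(comm$omega[i] * nres, 1)
  }
  # identical masses give identical rows (redundant species)
  comm2 <- tiny_community(masses_animals = c(1e4, 1e4, 1e7))
  expect_identical(comm2$link_efficiency[1, -(comm2$S_P + 1:2)],
                   comm2$link_efficiency[2, -(comm2$S_P + 1:2)])
  # eps = 0 keeps every pair except self-links (masses close enough that
  # the kernel does not underflow to an exact floating-point zero)
  comm3 <- tiny_community(masses_plants = c(1, 5, 10),
                          masses_animals = c(100, 500, 1000), eps = 0)
  offdiag <- comm3$link_efficiency[cbind(1:3, comm3$S_P + 1:3)]
  expect_identical(offdiag, rep(0, 3))
  expect_true(all(comm3$link_efficiency[, seq_len(comm3$S_P)] > 0))
  expect_true(all(comm3$link_efficiency[upper.tri(matrix(0, 3, 3))] >= 0))
  # a consumer with exactly three resources gets omega = 1/3
  comm4 <- tiny_community(masses_plants = c(10, 20, 40),
                          masses_animals = c(2000, 1e9, 2e9))
  expect_equal(sum(comm4$link_efficiency[1, ] > 0), 3)
  expect_equal(comm4$omega[1], 1 / 3)
  # strict herbivores lose all animal-resource links before omega
  commh <- tiny_community(masses_animals = c(1e2, 1e4, 1e6),
                          herbivore_only = c(FALSE, FALSE, TRUE))
  expect_true(all(commh$link_efficiency[3, commh$S_P + 1:3] == 0))
  expect_equal(commh$omega[3],
               1 / sum(commh$link_efficiency[3, seq_len(commh$S_P)] > 0))
})

test_that("parameter sampling honours distributions and truncation", {
  # degenerate distributions return the configured means exactly
  p <- fixed_parameters()
  expect_identical(p$beta_cons, 0.42)
  expect_identical(p$eta_res, -0.66)
  expect_identical(p$q, 0.5)
  expect_identical(p$c, 0.8)
  expect_identical(p$S_supply, c(10, 10))
  # bulk draws respect the stated truncation rules
  set.seed(21)
  q_draws <- atnsim:::rnorm_trunc(1e4, 0.5, 0.2, 0, 1, exclusive = FALSE)
  expect_true(all(q_draws >= 0 & q_draws <= 1))
  b_draws <- atnsim:::rnorm_trunc(1e4, 0.42, 0.05,
                                  0.42 - 0.15, 0.42 + 0.15, exclusive = TRUE)
  expect_true(all(b_draws > 0.27 & b_draws < 0.57))
  # full parameter draws: every sampled exponent strictly within +/- 3 sigma
  cfg <- sampling_config()
  set.seed(22)
  ps <- replicate(300, sample_parameters(cfg, S_P = 2), simplify = FALSE)
  for (nm in c("beta_cons", "beta_res_animal", "eta_cons", "eta_res")) {
    d <- cfg[[nm]]
    vals <- vapply(ps, `[[`, 0, nm)
    expect_true(all(abs(vals - d["mean"]) < 3 * d["sd"]))
  }
  expect_true(all(vapply(ps, `[[`, 0, "q") >= 0 &
                  vapply(ps, `[[`, 0, "q") <= 1))
  expect_true(all(vapply(ps, function(x) all(x$S_supply > 0), NA)))
  expect_true(all(vapply(ps, function(x)
    all(x$K >= 0.1 & x$K <= 0.2), NA)))
  # impossible truncation exhausts the retry budget with an error
  expect_error(atnsim:::rnorm_trunc(1, 0, 1, 50, 60, max_redraws = 50),
               "budget")
})

test_that("a full replicate is bit-reproducible under its seed", {
  r1 <- simulate_replicate(8, 5, seed = 31, settings = fast_settings())
  r2 <- simulate_replicate(8, 5, seed = 31, settings = fast_settings())
  expect_identical(r1$community, r2$community)
  expect_identical(r1$parameters, r2$parameters)
  expect_identical(r1$record, r2$record)
})
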