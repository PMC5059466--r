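test_that("sweep bookkeeping: rows, seeds, determinism", {
  design <- sweep_design(S_A_values = c(4, 6), replicates = 2, S_P = 3,
                         master_seed = 9)
  recs <- run_sweep(design, fast_settings(t_end = 300, eval_window = 50))
  expect_equal(nrow(recs), 4)
  expect_equal(length(unique(recs$seed)), 4)
  expect_equal(sort(unique(recs$S_A_init)), c(4, 6))
  recs2 <- run_sweep(design, fast_settings(t_end = 300, eval_window = 50))
  expect_identical(recs, recs2)
  # derived seeds are valid 31-bit integers and collision-free over a grid
  seeds <- outer(10:100, 1:50, function(s, r) replicate_seed(1, s, r))
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("power-law fits are exact on noiseless laws and match normal equations", {
  S <- rep(10:100, each = 3)
  recs <- data.frame(S_A_init = S, A_total = 2 * S^0.5,
                     discarded = FALSE, status = "ok")
  f <- suppressWarnings(fit_power_law(recs, "A_total"))  # perfect-fit warning
  expect_equal(f$a, 2, tolerance = 1e-12)
  expect_equal(f$alpha, 0.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$n_used, length(S))
  # independent closed-form OLS on the log-log data
  x <- log(S); y <- log(2 * S^0.5)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intc <- mean(y) - beta * mean(x)
  expect_equal(f$alpha, beta, tolerance = 1e-10)
  expect_equal(log(f$a), intc, tolerance = 1e-10)
  # zero responses are omitted with a message, not propagated
  recs$F_A <- recs$A_total; recs$F_A[c(1, 5)] <- 0
  expect_message(f2 <- suppressWarnings(fit_power_law(recs, "F_A")),
                 "omitting 2")
  expect_equal(f2$n_zero_omitted, 2)
  expect_equal(f2$n_used, length(S) - 2)
  expect_true(is.finite(f2$alpha))
  # discarded and failed rows are excluded
  recs$discarded[1:30] <- TRUE
  f3 <- suppressWarnings(fit_power_law(recs, "A_total"))
  expect_equal(f3$n_used, length(S) - 30)
  # too few rows is an error
  expect_error(fit_power_law(recs[1:2, ], "A_total"), "fewer than 3")
})

test_that("noisy fits recover the exponent without bias", {
  set.seed(314)
  alphas <- ses <- numeric(60)
  for (i in 1:60) {
    S <- rep(seq(10, 100, by = 10), each = 4)
    y <- 0.35 * S^1.2 * exp(rnorm(length(S), 0, 0.7))
    recs <- data.frame(S_A_init = S, A_total = y,
                       discarded = FALSE, status = "ok")
    f <- fit_power_law(recs, "A_total")
    alphas[i] <- f$alpha; ses[i] <- f$alpha_se
  }
  # each fit should cover the truth at 3 s.e. almost always
  expect_gte(mean(abs(alphas - 1.2) <= 3 * ses), 0.9)
  # and the estimator is unbiased within Monte-Carlo error
  expect_lt(abs(mean(alphas) - 1.2), 3 * sd(alphas) / sqrt(length(alphas)))
})

test_that("sensitivity variant switches propagate", {
  # strict-herbivore fraction removes exactly the flagged animals' links
  res <- simulate_replicate(10, 4, seed = 5, herbivore_fraction = 0.5,
                            settings = fast_settings(t_end = 300,
                                                     eval_window = 50))
  comm <- res$community
  expect_equal(sum(comm$herbivore_only), 5)
  expect_true(all(comm$link_efficiency[comm$herbivore_only, -(1:4)] == 0))
  # D and S_P overrides reach the sampled replicate
  cfg <- sampling_config(D = 0.5)
  res2 <- simulate_replicate(4, 10, cfg = cfg, seed = 5,
                             settings = fast_settings(t_end = 300,
                                                      eval_window = 50))
  expect_equal(res2$parameters$D, 0.5)
  expect_equal(res2$community$S_P, 10)
  expect_equal(nrow(res2$parameters$K), 10)
  # beta_i mean override
  cfg2 <- sampling_config(beta_cons = c(0.3, 0))
  res3 <- simulate_replicate(4, 3, cfg = cfg2, seed = 5,
                             settings = fast_settings(t_end = 300,
                                                      eval_window = 50))
  expect_identical(res3$parameters$beta_cons, 0.3)
})

test_that("the CLI runs its subcommands end to end", {
  out <- file.path(tempdir(), "atn-cli-test")
  unlink(out, recursive = TRUE)
  dir.create(out)
  # one tiny replicate
  st <- atn_cli(c("simulate", "--seed", "1", "--sa", "4", "--sp", "3",
                  "--t-end", "300", "--out", file.path(out, "run")))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(out, "run", "record.csv")))
  expect_true(file.exists(file.path(out, "run", "trajectory.csv")))
  # determinism of the record across two invocations
  atn_cli(c("simulate", "--seed", "1", "--sa", "4", "--sp", "3",
            "--t-end", "300", "--out", file.path(out, "run2")))
  expect_identical(readLines(file.path(out, "run", "record.csv")),
                   readLines(file.path(out, "run2", "record.csv")))
  # mini sweep + manifest + fit round trip
  recfile <- file.path(out, "records.csv")
  st2 <- atn_cli(c("sweep", "--preset", "mini", "--seed", "3",
                   "--t-end", "300", "--out", recfile))
  expect_identical(st2, 0L)
  expect_true(file.exists(recfile))
  man <- jsonlite::read_json(sub("\\.csv$", "_manifest.json", recfile))
  expect_equal(man$master_seed, 3)
  expect_equal(man$n_records, 6)
  # fit subcommand on a well-posed records table reproduces known laws
  S <- rep(seq(10, 100, by = 10), each = 3)
  synth <- data.frame(S_A_init = S, A_total = 0.35 * S^1.2,
                      P_total = 29.75 * S^-0.08, F_P = 0.1 * S^0.61,
                      F_A = 0.004 * S^0.92, X_A = 0.05 * S^0.58,
                      X_P = 6.72 * S^-0.54, discarded = FALSE, status = "ok")
  synthfile <- file.path(out, "synth.csv")
  write_records(synth, synthfile)
  st3 <- suppressWarnings(atn_cli(c("fit", "--records", synthfile,
                                    "--out", file.path(out, "fits.csv"))))
  expect_identical(st3, 0L)
  fits <- read_records(file.path(out, "fits.csv"))
  expect_equal(nrow(fits), 6)
  expect_equal(fits$alpha, c(1.2, -0.08, 0.61, 0.92, 0.58, -0.54),
               tolerance = 1e-8)
  # fixtures subcommand writes deterministic communities
  st4 <- atn_cli(c("fixtures", "--out", file.path(out, "fx")))
  expect_identical(st4, 0L)
  fx <- read_community(file.path(out, "fx", "community_3p3a.tsv"))
  expect_equal(fx$S_P, 3)
  # bad usage returns nonzero without throwing
  expect_identical(suppressMessages(atn_cli(character())), 1L)
  expect_identical(suppressMessages(atn_cli("frobnicate")), 1L)
})
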