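test_that("the default scenario reproduces the study design", {
  scen <- redstart_scenario()
  expect_s3_class(scen, "ms_scenario")
  expect_equal(scen$n_occasions, 11L)
  expect_equal(sum(scen$cohorts$n), 656) # 211 females + 445 males
  by_class <- dplyr::count(scen$cohorts, .data$sex, .data$age, wt = .data$n)
  expect_setequal(by_class$n, c(117, 94, 261, 184))
  # no marking in the final year
  expect_true(all(scen$cohorts$year <= 10))
  # release allocation follows the published density weights
  cv <- redstart_covariates()
  fshare <- sum(scen$cohorts$n[scen$cohorts$state == "F"]) / 656
  wshare <- sum(cv$density_F[1:10]) / sum(cv$density_F[1:10] + cv$density_C[1:10])
  expect_lt(abs(fshare - wshare), 0.02)
})

test_that("the generating betas reproduce the class truths exactly", {
  scen <- redstart_scenario()
  sim <- ms_simulate(scen, seed = 1)
  d <- msmark:::compile_design(scen$spec, sim$histories, NULL, scen$control)
  beta <- msmark:::resolve_beta(d, scen$beta)
  ra <- msmark:::real_arrays(d, beta)
  fr <- d$blocks$phi$frame
  pick <- function(sex, age) unique(ra$phi[fr$sex == sex & fr$age == age])
  expect_equal(pick("female", "ASY"), 0.39, tolerance = 1e-12)
  expect_equal(pick("male", "SY"), 0.15, tolerance = 1e-12)
  frp <- d$blocks$p$frame
  expect_equal(unique(ra$p[frp$sex == "male" & frp$state == "C"]), 0.91,
               tolerance = 1e-12)
  frs <- d$blocks$psi$frame
  expect_equal(unique(ra$psi[frs$sex == "male" & frs$age == "SY" &
                               frs$state == "F"]), 0.18, tolerance = 1e-12)
})

test_that("the default scenario yields a study-scale number of returners", {
  # the field study re-observed 127 of 656 marked birds at least once
  for (s in 1:3) {
    sim <- ms_simulate(redstart_scenario(), seed = 500 + s)
    ret <- sum(vapply(gregexpr("[FC]", sim$histories$ch), length, 0L) > 1)
    expect_gt(ret, 80)
    expect_lt(ret, 200)
  }
})

test_that("simulation is deterministic given the seed", {
  scen <- redstart_scenario(cohort_scale = 0.2)
  a <- ms_simulate(scen, seed = 77)
  b <- ms_simulate(scen, seed = 77)
  c <- ms_simulate(scen, seed = 78)
  expect_identical(a$histories$ch, b$histories$ch)
  expect_false(identical(a$histories$ch, c$histories$ch))
})

test_that("degenerate parameter values produce the forced histories", {
  full <- ms_simulate(scalar_scenario(50, phi = 1, psi = 0, p = 1, T = 5),
                      seed = 3)
  expect_true(all(full$histories$ch == "FFFFF"))
  dead <- ms_simulate(scalar_scenario(50, phi = 0, psi = 0.5, p = 1, T = 5),
                      seed = 3)
  expect_true(all(dead$histories$ch == "F0000"))
})

test_that("first-interval return frequency matches the binomial expectation", {
  # SY males with phi = 0.15 and p = 0.9 in either state: the chance of
  # being seen the next year is 0.135 regardless of movement
  scen <- scalar_scenario(10000, phi = 0.15, psi = 0.18, p = 0.9, T = 3)
  sim <- ms_simulate(scen, seed = 9)
  seen2 <- mean(substr(sim$histories$ch, 2, 2) != "0")
  se <- sqrt(0.135 * (1 - 0.135) / 10000)
  expect_lt(abs(seen2 - 0.135), 3 * se)
})

test_that("simulated data prefer their generating parameters (KL direction)", {
  scen <- redstart_scenario(cohort_scale = 0.5)
  better <- 0
  for (s in 1:5) {
    sim <- ms_simulate(scen, seed = 40 + s)
    d <- msmark:::compile_design(scen$spec, sim$histories, NULL, scen$control)
    beta <- msmark:::resolve_beta(d, scen$beta)
    ll_true <- neg2_log_likelihood(sim$histories, scen$spec, beta)
    set.seed(s)
    ll_pert <- neg2_log_likelihood(sim$histories, scen$spec,
                                   beta + rnorm(length(beta), 0, 0.4))
    if (ll_true < ll_pert) better <- better + 1
  }
  expect_gte(better, 4)
})

test_that("scenario validation rejects impossible designs", {
  expect_error(scalar_scenario(-5, 0.5, 0.1, 0.5), "non-negative")
  expect_error(ms_scenario(
    tibble::tibble(year = 5, sex = "male", age = "SY", state = "F", n = 3),
    ms_spec(), rep(0, 3), n_occasions = 5), "marking years")
})
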