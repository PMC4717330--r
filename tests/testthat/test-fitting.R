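test_that("with perfect detection and no movement, phi-hat is the return fraction", {
  scen <- scalar_scenario(400, phi = 0.6, psi = 0, p = 1, T = 4)
  sim <- ms_simulate(scen, seed = 21)
  fit <- ms_fit(sim, ms_spec(), control = fast_control())
  # with p = 1 every survival outcome is observed: the MLE of a constant
  # phi is survivals / exposures, both countable directly from the data
  m <- msmark:::ch_matrix(sim$histories)
  T <- ncol(m)
  surv <- exposed <- 0
  for (i in seq_len(nrow(m))) {
    f <- which(m[i, ] > 0)[1]
    l <- max(which(m[i, ] > 0))
    surv <- surv + (l - f)
    exposed <- exposed + (l - f) + (if (l < T) 1 else 0)
  }
  expect_equal(unname(plogis(fit$beta[1])), surv / exposed, tolerance = 1e-5)
})

test_that("refitting from the optimum is a fixed point and order does not matter", {
  sim <- ms_simulate(redstart_scenario(cohort_scale = 0.3), seed = 5)
  spec <- ms_spec(phi = ~sex, p = ~ sex + state, psi = ~1)
  fit <- ms_fit(sim, spec, control = fast_control())
  expect_true(fit$converged)
  # -2lnL at the reported optimum equals the reported value
  expect_equal(neg2_log_likelihood(sim$histories, spec, fit$beta),
               fit$neg2lnl, tolerance = 1e-6)
  # permuting individuals changes nothing
  perm <- sim$histories[rev(seq_len(nrow(sim$histories))), ]
  fit2 <- ms_fit(perm, spec, control = fast_control())
  expect_equal(fit2$neg2lnl, fit$neg2lnl, tolerance = 1e-6)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-3)
})

test_that("nested models never beat the nesting model's likelihood", {
  sim <- ms_simulate(redstart_scenario(cohort_scale = 0.3), seed = 9)
  small <- ms_fit(sim, ms_spec(phi = ~1, p = ~ sex + state, psi = ~1),
                  control = fast_control())
  big <- ms_fit(sim, ms_spec(phi = ~sex, p = ~ sex + state, psi = ~1),
                control = fast_control())
  expect_gte(small$neg2lnl, big$neg2lnl - 1e-6)
})

test_that("real estimates back-transform with delta-method intervals", {
  sim <- ms_simulate(redstart_scenario(cohort_scale = 0.5), seed = 2)
  fit <- ms_fit(sim, ms_spec(phi = ~sex, p = ~ sex + state, psi = ~1),
                control = fast_control())
  est <- real_estimates(fit, "phi")
  expect_true(all(est$lcl >= 0 & est$ucl <= 1))
  expect_true(all(est$lcl <= est$estimate & est$estimate <= est$ucl))
  # overdispersion scaling: chat = 4 doubles the link-scale SE, so the
  # real-scale SE doubles too
  e1 <- real_estimates(fit, "phi")
  e4 <- real_estimates(fit, "phi", chat = 4)
  expect_equal(e4$se, 2 * e1$se, tolerance = 1e-10)
  expect_equal(e4$estimate, e1$estimate)

  # a cell with zero link-scale variance has a degenerate interval
  fit0 <- fit
  fit0$vcov[] <- 0
  e0 <- real_estimates(fit0, "phi", tibble::tibble(sex = "female", age = "ASY",
                                                   state = "F"))
  expect_equal(e0$lcl, e0$estimate)
  expect_equal(e0$ucl, e0$estimate)
})

test_that("estimates concentrate as cohort sizes grow", {
  # bias of phi-hat shrinks when cohorts are multiplied by 10
  spec <- ms_spec(phi = ~1, p = ~1, psi = ~1)
  bias_at <- function(scale, seeds) {
    est <- vapply(seeds, function(s) {
      sim <- ms_simulate(scalar_scenario(round(60 * scale), phi = 0.4,
                                         psi = 0.1, p = 0.8, T = 5), seed = s)
      fit <- ms_fit(sim, spec, control = fast_control())
      plogis(fit$beta[1])
    }, 0)
    abs(mean(est) - 0.4)
  }
  expect_lt(bias_at(10, 1:15), bias_at(1, 1:15) + 0.02)
  expect_lt(bias_at(10, 1:15), 0.02)
})

test_that("tidy and glance report the fit on the expected scales", {
  sim <- ms_simulate(redstart_scenario(cohort_scale = 0.3), seed = 4)
  fit <- ms_fit(sim, ms_spec(phi = ~sex, p = ~ sex + state, psi = ~1),
                control = fast_control())
  td <- tidy(fit)
  expect_equal(nrow(td), fit$k)
  expect_setequal(unique(td$block), c("phi", "p", "psi"))
  gl <- glance(fit)
  expect_equal(gl$neg2lnl, fit$neg2lnl)
  expect_equal(gl$qaicc, qaicc(fit$neg2lnl, 1, fit$k, fit$ess))
  # ess counts releases: initial captures plus live re-encounters
  m <- msmark:::ch_matrix(sim$histories)
  expect_equal(fit$ess, sum(m > 0))
})
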