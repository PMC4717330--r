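test_that("single-history probabilities match hand-enumerated paths", {
  p <- tiny_params()
  # survive, stay, detected: 0.5 * 0.8 * 0.7
  expect_equal(history_probability("FF", p), 0.28)
  # two latent paths through the unobserved occasion
  expect_equal(history_probability("F0C", p), 0.0146055)
  # degenerate certainty
  expect_equal(
    history_probability("FFFFF", list(phi = 1, psi = 0, p = 1)), 1)
})

test_that("dataset -2lnL is additive and zero on empty data", {
  p <- tiny_params()
  spec <- state_spec()
  beta <- state_beta(p)
  one <- hist_tbl("FF")
  expect_equal(neg2_log_likelihood(one, spec, beta), -2 * log(0.28),
               tolerance = 1e-10)
  two <- hist_tbl(c("FF", "FF"))
  expect_equal(neg2_log_likelihood(two, spec, beta),
               2 * neg2_log_likelihood(one, spec, beta))
  empty <- ms_histories(hist_tbl(character()), n_occasions = 2)
  expect_equal(neg2_log_likelihood(empty, spec, beta), 0)
})

test_that("impossible histories yield infinite -2lnL with a diagnostic", {
  h <- hist_tbl("FC")
  beta <- state_beta(list(phi = c(1, 1), psi = c(0, 0), p = c(1, 1)))
  expect_warning(v <- neg2_log_likelihood(h, state_spec(), beta),
                 "probability zero")
  expect_identical(v, Inf)
})

test_that("observable histories conserve probability and match enumeration", {
  set.seed(42)
  for (T in 2:4) {
    for (rel in c("F", "C")) {
      for (rep in 1:25) {
        pp <- random_params()
        e <- enumerate_histories(T, 1, rel, pp)
        expect_lt(abs(sum(e$prob) - 1), 1e-12)
        # forward recursion equals brute-force path enumeration
        fwd <- vapply(e$ch, history_probability, 0, params = pp)
        expect_lt(max(abs(fwd - e$prob)), 1e-12)
      }
    }
  }
  # release later than occasion 1
  pp <- random_params()
  e2 <- enumerate_histories(4, 2, "C", pp)
  expect_lt(abs(sum(e2$prob) - 1), 1e-12)
  expect_equal(nrow(e2), 3^2)
  expect_error(enumerate_histories(6, 1, "F", pp), "T <= 5")
})

test_that("the compiled likelihood agrees with enumeration for all T=4 histories", {
  set.seed(7)
  pp <- random_params()
  e <- enumerate_histories(4, 1, "F", pp)
  h <- ms_histories(hist_tbl(e$ch))
  spec <- state_spec()
  beta <- state_beta(pp)
  for (i in seq_len(nrow(e))) {
    got <- exp(-neg2_log_likelihood(h[i, ], spec, beta) / 2)
    expect_equal(got, e$prob[i], tolerance = 1e-12)
  }
})

test_that("with no movement and one state the model collapses to CJS", {
  # independent CJS probability via the standard chi recursion
  cjs_prob <- function(ch, phi, p) {
    T <- nchar(ch)
    x <- as.integer(strsplit(ch, "")[[1]] != "0")
    f <- which(x == 1)[1]
    l <- max(which(x == 1))
    chi <- numeric(T + 1)
    chi[T] <- 1
    for (t in (T - 1):1) chi[t] <- (1 - phi) + phi * (1 - p) * chi[t + 1]
    pr <- 1
    if (l > f) {
      for (t in f:(l - 1)) pr <- pr * phi * (if (x[t + 1] == 1) p else 1 - p)
    }
    pr * chi[l]
  }
  set.seed(3)
  for (rep in 1:20) {
    phi <- runif(1, 0.1, 0.9)
    p <- runif(1, 0.1, 0.9)
    ch <- paste(c("F", sample(c("F", "0"), 4, replace = TRUE)), collapse = "")
    got <- history_probability(ch, list(phi = phi, psi = 0, p = p))
    expect_equal(got, cjs_prob(ch, phi, p), tolerance = 1e-12)
  }
})

test_that("raising detection at one occasion moves history probability the right way", {
  base <- tiny_params()
  pmat <- function(occ3) {
    m <- matrix(rep(base$p, each = 3), 3, 2)
    m[occ3, ] <- 0.95
    m
  }
  pp <- function(m) list(phi = base$phi, psi = base$psi, p = m)
  flat <- matrix(rep(base$p, each = 3), 3, 2)
  # detected at occasion 3: raising p there increases the probability
  expect_gt(history_probability("F0F", pp(pmat(3))),
            history_probability("F0F", pp(flat)))
  # missed at occasion 2: raising p there decreases it
  expect_lt(history_probability("F0F", pp(pmat(2))),
            history_probability("F0F", pp(flat)))
})
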