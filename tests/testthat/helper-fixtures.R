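## Shared fixtures: everything is generated in code at test time.

## a small deterministic set of real parameters
tiny_params <- function() {
  list(phi = c(0.5, 0.5), psi = c(0.2, 0.1), p = c(0.7, 0.91))
}

## random real-parameter draws away from the boundary
random_params <- function() {
  list(phi = runif(2, 0.05, 0.95), psi = runif(2, 0.05, 0.95),
       p = runif(2, 0.05, 0.95))
}

## histories tibble from character vector + one class
hist_tbl <- function(ch, sex = "female", age = "ASY") {
  tibble::tibble(id = paste0("h", seq_along(ch)), ch = ch,
                 sex = sex, age = age)
}

## state-saturated spec whose beta maps directly onto state-specific
## scalars, for checking the dataset likelihood against single-history
## computations
state_spec <- function() {
  ms_spec(phi = ~state, p = ~state, psi = ~state)
}

state_beta <- function(params) {
  lg <- function(v) c(qlogis(v[1]), qlogis(v[2]) - qlogis(v[1]))
  c(lg(params$phi), lg(params$p), lg(params$psi))
}

## fast-fitting control for tests
fast_control <- function(...) ms_control(n_starts = 1, ...)

## scenario with a single release cohort and scalar truths
scalar_scenario <- function(n, phi, psi, p, sex = "male", age = "SY",
                            state = "F", T = 3, year = 1) {
  ms_scenario(
    cohorts = tibble::tibble(year = year, sex = sex, age = age,
                             state = state, n = n),
    spec = ms_spec(phi = ~1, p = ~1, psi = ~1),
    beta = list(phi = c("(Intercept)" = qlogis(phi)),
                p = c("(Intercept)" = qlogis(p)),
                psi = c("(Intercept)" = qlogis(psi))),
    n_occasions = T)
}
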