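#' Parameter-recovery experiment on simulated datasets
#'
#' Simulates `n_rep` datasets from a scenario, fits the class-structured
#' model to each, and collects the back-transformed estimates of every
#' sex-by-age survival and movement cell and every sex-by-habitat
#' recapture cell. Used to verify that the estimator recovers the
#' generating probabilities of the study design.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Base seed; replicate r uses `seed * 1e5 + r`.
#' @param scenario Generating scenario, default [redstart_scenario()].
#' @param spec Fitted model, default the saturated class model
#'   `phi(sex*age) p(sex*state) psi(sex*age)`.
#' @param control Fitting control (multistart optimizer settings).
#' @return A tibble with one row per (replicate, cell): `rep`, `param`,
#'   `sex`, `age`, `state`, `estimate`, `converged`.
#' @seealso [summarize_recovery()]
#' @export
recovery_experiment <- function(n_rep = 100, seed = 1,
                                scenario = redstart_scenario(),
                                spec = ms_spec(phi = ~ sex * age,
                                               p = ~ sex * state,
                                               psi = ~ sex * age),
                                control = ms_control()) {
  cells <- list(
    phi = tidyr::expand_grid(sex = .ms_sexes, age = .ms_ages, state = "F"),
    p = tidyr::expand_grid(sex = .ms_sexes, age = "ASY", state = .ms_states),
    psi = tidyr::expand_grid(sex = .ms_sexes, age = .ms_ages, state = "F"))
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sim <- ms_simulate(scenario, seed = seed * 1e5 + r)
    fit <- tryCatch(ms_fit(sim, spec, control = control),
                    error = function(e) NULL)
    if (is.null(fit)) next
    est <- dplyr::bind_rows(lapply(names(cells), function(par) {
      e <- real_estimates(fit, par, cells[[par]])
      e[, c("param", "sex", "age", "state", "estimate")]
    }))
    est$rep <- r
    est$converged <- fit$converged
    out[[r]] <- est
  }
  dplyr::bind_rows(out)
}

#' Summarize a recovery experiment against its generating truths
#'
#' @param results Output of [recovery_experiment()].
#' @param scenario The scenario the results were generated from.
#' @return One row per cell with `truth`, `mean`, `sd` across replicates,
#'   the Monte-Carlo standard error `mc_se = sd / sqrt(n)`, and the
#'   z-score `(mean - truth) / mc_se`.
#' @export
summarize_recovery <- function(results, scenario = redstart_scenario()) {
  tr <- scenario$truths
  if (is.null(tr)) stop("scenario carries no class truths", call. = FALSE)
  cls <- function(sex, age) match(paste(sex, age),
                                  c("female ASY", "female SY",
                                    "male ASY", "male SY"))
  truth_of <- function(param, sex, age, state) {
    switch(param,
           phi = tr$phi[cls(sex, age)],
           psi = ifelse(state == "F", tr$psi_fc[cls(sex, age)],
                        tr$psi_cf[cls(sex, age)]),
           p = tr$p[match(paste(sex, state),
                          c("female F", "female C", "male F", "male C"))])
  }
  sm <- dplyr::summarise(
    dplyr::group_by(results, .data$param, .data$sex, .data$age, .data$state),
    mean = mean(.data$estimate), sd = sd(.data$estimate),
    n = dplyr::n(), .groups = "drop")
  sm$truth <- vapply(seq_len(nrow(sm)), function(i) {
    truth_of(sm$param[i], sm$sex[i], sm$age[i], sm$state[i])
  }, 0)
  sm$mc_se <- sm$sd / sqrt(sm$n)
  sm$z <- (sm$mean - sm$truth) / sm$mc_se
  sm[, c("param", "sex", "age", "state", "truth", "mean", "sd", "n",
         "mc_se", "z")]
}
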