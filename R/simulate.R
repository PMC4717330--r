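#' Define a simulation scenario
#'
#' A scenario bundles everything needed to generate encounter histories:
#' the release design (how many individuals of each sex/age class are
#' first marked in each year and habitat), the generating model (an
#' [ms_spec()] plus logit-scale coefficients), and the annual covariate
#' source. Fates are generated in the order the model assumes: each
#' interval an individual first survives with the origin-state survival
#' probability, then moves between habitats, then is detected (or not) in
#' its destination state.
#'
#' @param cohorts Tibble with columns `year` (marking occasion, 1-based),
#'   `sex`, `age` (class at marking), `state` (release habitat) and `n`.
#' @param spec Generating [ms_spec()].
#' @param beta Generating coefficient vector (logit scale), ordered as the
#'   compiled design (phi block, p block, psi block).
#' @param n_occasions Number of study occasions.
#' @param covariates `NULL`, a standardized covariate tibble, or
#'   `"simulated"` to draw iid standard-normal annual covariates at
#'   simulation time (columns `soi`, `rain`, `temp`, `ndvi_west`,
#'   `ndvi_east`, `density_F`, `density_C`, `fledge_F`, `fledge_C`).
#' @param control An [ms_control()] (age handling and psi density timing).
#' @return An object of class `ms_scenario`.
#' @seealso [redstart_scenario()], [ms_simulate()]
#' @export
ms_scenario <- function(cohorts, spec, beta, n_occasions,
                        covariates = NULL, control = ms_control()) {
  cohorts <- as_tibble(cohorts)
  need <- c("year", "sex", "age", "state", "n")
  miss <- setdiff(need, names(cohorts))
  if (length(miss) > 0) {
    stop("cohorts are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(cohorts$n < 0) || any(cohorts$n != round(cohorts$n))) {
    stop("cohort sizes must be non-negative integers", call. = FALSE)
  }
  if (any(cohorts$year < 1 | cohorts$year >= n_occasions)) {
    stop("marking years must lie in 1..(n_occasions - 1)", call. = FALSE)
  }
  cohorts$sex <- check_level(cohorts$sex, .ms_sexes, "sex")
  cohorts$age <- check_level(cohorts$age, .ms_ages, "age")
  cohorts$state <- check_level(cohorts$state, .ms_states, "state")
  if (is.list(beta)) {
    stopifnot(setequal(names(beta), c("phi", "p", "psi")))
  } else {
    beta <- as.numeric(beta)
  }
  structure(list(cohorts = cohorts, spec = spec, beta = beta,
                 n_occasions = as.integer(n_occasions),
                 covariates = covariates, control = control),
            class = "ms_scenario")
}

#' @export
print.ms_scenario <- function(x, ...) {
  cat("<ms_scenario> ", format(x$spec), "\n", sep = "")
  cat("  ", sum(x$cohorts$n), " releases over ", x$n_occasions,
      " occasions\n", sep = "")
  invisible(x)
}

#' Solve logit-scale coefficients that reproduce class probabilities
#'
#' Given a saturated (full-rank) formula over factor cells and the target
#' probability per cell, returns the treatment-coded coefficients whose
#' inverse-logit predictions equal the targets exactly.
#'
#' @param formula One-sided formula over `sex`, `age`, `state`.
#' @param cells Tibble of factor cells with a `prob` column.
#' @return Named coefficient vector.
#' @export
solve_class_beta <- function(formula, cells) {
  cells <- as_tibble(cells)
  if ("sex" %in% names(cells)) cells$sex <- check_level(cells$sex, .ms_sexes, "sex")
  if ("age" %in% names(cells)) cells$age <- check_level(cells$age, .ms_ages, "age")
  if ("state" %in% names(cells)) cells$state <- check_level(cells$state, .ms_states, "state")
  X <- model.matrix(formula, cells)
  if (nrow(X) != ncol(X)) {
    stop("cells must define a square full-rank system for the formula",
         call. = FALSE)
  }
  beta <- solve(X, qlogis(cells$prob))
  setNames(as.numeric(beta), colnames(X))
}

#' The default redstart study scenario
#'
#' Emulates the two-habitat American redstart study design: 11 annual
#' occasions, marking in years 1-10 with class totals of 117 ASY females,
#' 94 SY females, 261 ASY males and 184 SY males, allocated across
#' (year, habitat) release cells proportionally to the published annual
#' territory densities. Generating probabilities are the published
#' class-specific estimates: survival (ASY-f, SY-f, ASY-m, SY-m) =
#' (0.39, 0.35, 0.33, 0.15); forest-to-campground movement =
#' (0.03, 0.09, 0.07, 0.18), with campground-to-forest equal by default;
#' recapture by sex and habitat = female (F 0.21, C 0.53), male
#' (F 0.70, C 0.91). Age classes are current-age (an SY bird graduates to
#' ASY after one interval).
#'
#' @param phi,psi_fc Class truths in order (ASY-female, SY-female,
#'   ASY-male, SY-male).
#' @param psi_cf Campground-to-forest truths; default equal to `psi_fc`
#'   (the study reported no support for directional asymmetry).
#' @param p Recapture truths in order (female-F, female-C, male-F, male-C).
#' @param cohort_scale Multiplier on all cohort sizes (rounded).
#' @param phi_covariates,psi_covariates Optional named numeric vectors of
#'   extra logit-scale covariate effects, e.g.
#'   `phi_covariates = c("soi" = 0.22, "I(soi^2)" = -0.37)` or
#'   `psi_covariates = c("density:male" = -0.63)`. Adding any covariate
#'   effect switches the covariate source to `"simulated"` unless a
#'   covariate table is supplied.
#' @param covariates Optional covariate source passed to [ms_scenario()].
#' @param control An [ms_control()].
#' @return An `ms_scenario`.
#' @export
redstart_scenario <- function(phi = c(0.39, 0.35, 0.33, 0.15),
                              psi_fc = c(0.03, 0.09, 0.07, 0.18),
                              psi_cf = NULL,
                              p = c(0.21, 0.53, 0.70, 0.91),
                              cohort_scale = 1,
                              phi_covariates = NULL,
                              psi_covariates = NULL,
                              covariates = NULL,
                              control = ms_control()) {
  n_occasions <- 11L
  totals <- tibble(
    sex = c("female", "female", "male", "male"),
    age = c("ASY", "SY", "ASY", "SY"),
    total = round(c(117, 94, 261, 184) * cohort_scale))
  dens <- redstart_covariates()
  years <- seq_len(n_occasions - 1L)
  wt <- tibble(
    year = rep(years, 2),
    state = rep(c("F", "C"), each = length(years)),
    w = c(dens$density_F[years], dens$density_C[years]))
  wt$w <- wt$w / sum(wt$w)
  cohorts <- dplyr::bind_rows(lapply(seq_len(nrow(totals)), function(i) {
    n <- largest_remainder(wt$w * totals$total[i])
    tibble(year = wt$year, sex = totals$sex[i], age = totals$age[i],
           state = wt$state, n = n)
  }))
  cohorts <- cohorts[cohorts$n > 0, ]

  class_cells <- tibble(sex = totals$sex, age = totals$age)
  beta_phi <- solve_class_beta(~ sex * age,
                               dplyr::mutate(class_cells, prob = phi))
  psi_cf <- psi_cf %||% psi_fc
  ## movement depends on origin state only through the (optional)
  ## FC/CF asymmetry: solve the saturated sex*age*state system
  psi_cells <- tidyr::expand_grid(class_cells, state = c("F", "C"))
  cls <- match(paste(psi_cells$sex, psi_cells$age),
               paste(class_cells$sex, class_cells$age))
  psi_cells$prob <- ifelse(psi_cells$state == "F", psi_fc[cls], psi_cf[cls])
  beta_psi <- solve_class_beta(~ sex * age * state, psi_cells)
  p_cells <- tidyr::expand_grid(sex = c("female", "male"),
                                state = c("F", "C"))
  p_cells$prob <- p
  beta_p <- solve_class_beta(~ sex * state, p_cells)

  spec <- ms_spec(phi = ~ sex * age, p = ~ sex * state,
                  psi = ~ sex * age * state)
  beta <- list(phi = beta_phi, p = beta_p, psi = beta_psi)

  if (!is.null(phi_covariates)) {
    spec <- add_terms(spec, "phi", names(phi_covariates))
    beta$phi <- c(beta$phi, phi_covariates)
  }
  if (!is.null(psi_covariates)) {
    spec <- add_terms(spec, "psi", names(psi_covariates))
    beta$psi <- c(beta$psi, psi_covariates)
  }
  if (is.null(covariates) && (!is.null(phi_covariates) ||
                              !is.null(psi_covariates))) {
    covariates <- "simulated"
  }
  sc <- ms_scenario(cohorts, spec, beta, n_occasions,
                    covariates = covariates, control = control)
  sc$truths <- list(phi = phi, psi_fc = psi_fc, psi_cf = psi_cf, p = p,
                    phi_covariates = phi_covariates,
                    psi_covariates = psi_covariates)
  sc
}

## Map a per-block named coefficient list onto the compiled design's
## column order; plain numeric vectors pass through unchanged.
resolve_beta <- function(design, beta) {
  if (!is.list(beta)) {
    if (length(beta) != design$k) {
      stop("beta has length ", length(beta), " but the design has ",
           design$k, " columns", call. = FALSE)
    }
    return(as.numeric(beta))
  }
  out <- numeric(0)
  for (par in c("phi", "p", "psi")) {
    cn <- sub("^[^:]*:", "", colnames(design$blocks[[par]]$X))
    b <- beta[[par]][cn]
    if (anyNA(b)) {
      stop("scenario beta for ", par, " is missing term(s): ",
           paste(cn[is.na(b)], collapse = ", "), call. = FALSE)
    }
    out <- c(out, as.numeric(b))
  }
  out
}

## round fractional allocations to integers preserving the total
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  need <- round(sum(x)) - sum(fl)
  if (need > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Simulate encounter histories from a scenario
#'
#' Generates a complete dataset: for each released individual, per
#' interval Bernoulli survival at the origin-state probability, then
#' Bernoulli movement, then Bernoulli detection at the destination state.
#' Death/permanent emigration is absorbing. The result is deterministic
#' given `seed`.
#'
#' @param scenario An [ms_scenario()].
#' @param seed Integer seed.
#' @return An object of class `ms_dataset`: a list with `histories` (an
#'   encounter-history tibble), `covariates` (the standardized covariate
#'   tibble used, or `NULL`) and `scenario`.
#' @export
ms_simulate <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "ms_scenario"))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)

  T <- scenario$n_occasions
  covariates <- scenario$covariates
  if (identical(covariates, "simulated")) {
    covariates <- tibble(year = seq_len(T))
    for (cl in c("soi", "rain", "temp", "ndvi_west", "ndvi_east",
                 "density_F", "density_C", "fledge_F", "fledge_C")) {
      covariates[[cl]] <- rnorm(T)
    }
  }

  cohorts <- scenario$cohorts
  n <- sum(cohorts$n)
  idx <- rep(seq_len(nrow(cohorts)), cohorts$n)
  sex <- cohorts$sex[idx]
  age <- cohorts$age[idx]
  first <- cohorts$year[idx]
  st0 <- as.integer(cohorts$state[idx])  # 1 = F, 2 = C

  ## probability arrays from the generating model, via the same design
  ## machinery the likelihood uses
  pseudo <- ms_histories(tibble(
    id = as.character(seq_len(n)),
    ch = vapply(seq_len(n), function(i) {
      paste0(strrep("0", first[i] - 1), .ms_states[st0[i]],
             strrep("0", T - first[i]))
    }, ""),
    sex = as.character(sex), age = as.character(age)))
  design <- compile_design(scenario$spec, pseudo, covariates,
                           scenario$control)
  beta <- resolve_beta(design, scenario$beta)
  ra <- real_arrays(design, beta)
  nc <- nrow(design$cohorts)
  phi <- array(ra$phi, dim = c(nc, T - 1, 2))
  psi <- array(ra$psi, dim = c(nc, T - 1, 2))
  p <- array(ra$p, dim = c(nc, T, 2))
  coh <- design$cohort_of

  obs <- matrix(0L, n, T)
  obs[cbind(seq_len(n), first)] <- st0
  state <- st0
  alive <- rep(TRUE, n)
  for (t in seq_len(T - 1)) {
    act <- which(alive & first <= t)
    if (length(act) == 0) next
    i <- cbind(coh[act], t, state[act])
    surv <- runif(length(act)) < phi[i]
    alive[act[!surv]] <- FALSE
    liv <- act[surv]
    if (length(liv) == 0) next
    mv <- runif(length(liv)) < psi[cbind(coh[liv], t, state[liv])]
    state[liv[mv]] <- 3L - state[liv[mv]]
    det <- runif(length(liv)) < p[cbind(coh[liv], t + 1, state[liv])]
    liv_det <- liv[det]
    if (length(liv_det) > 0) {
      obs[cbind(liv_det, rep(t + 1L, length(liv_det)))] <- state[liv_det]
    }
  }

  histories <- ms_histories(tibble(
    id = sprintf("sim%05d", seq_len(n)),
    ch = matrix_ch(obs),
    sex = as.character(sex), age = as.character(age)))
  structure(list(histories = histories, covariates = covariates,
                 scenario = scenario, seed = seed),
            class = "ms_dataset")
}

#' @export
print.ms_dataset <- function(x, ...) {
  cat("<ms_dataset> ", nrow(x$histories), " individuals, ",
      attr(x$histories, "n_occasions"), " occasions (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}
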