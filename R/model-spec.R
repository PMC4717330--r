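#' Specify a multistate model structure
#'
#' A model is specified by three one-sided formulas giving the linear
#' predictor (logit link) for apparent survival `phi`, recapture `p`, and
#' the movement probability `psi` (probability of switching habitat,
#' conditional on survival; with two states the stay probability is its
#' complement). Available terms:
#'
#' * `sex` - factor, reference `female`;
#' * `age` - current age class, reference `ASY`. By default age is
#'   time-varying: an SY-marked bird is `SY` for its first interval (and
#'   first re-encounter occasion) and `ASY` afterwards;
#' * `state` - habitat state, reference `F` (for `phi`/`psi` the origin
#'   state, for `p` the state at the encounter occasion);
#' * any column of the annual covariate table (`soi`, `rain`, `temp`,
#'   `ndvi_west`, `ndvi_east`), indexed by the interval (survival and
#'   movement from occasion t to t+1 use the value in row t);
#' * `density` - standardized territory density of the individual's origin
#'   habitat: for `phi` the density in the year the interval starts; for
#'   `psi` the density in the destination year by default (see
#'   [ms_control()] option `psi_density_year`);
#' * `fledge` - standardized mean fledging success of the origin habitat in
#'   the year the interval starts (`psi` only, by convention);
#' * `male` - numeric 0/1 dummy for male-only slopes, e.g. `density:male`
#'   leaves female predictions untouched for any value of that coefficient.
#'
#' Quadratic terms are written `I(soi^2)`. Interactions use the usual `*`
#' and `:` operators; coding is treatment contrasts throughout.
#'
#' @param phi,p,psi One-sided formulas, e.g. `phi = ~ sex * age + soi + I(soi^2)`.
#' @return An object of class `ms_spec`.
#' @examples
#' ms_spec(phi = ~ sex * age, p = ~ sex * state, psi = ~ sex + age)
#' @export
ms_spec <- function(phi = ~1, p = ~1, psi = ~1) {
  for (f in list(phi, p, psi)) {
    if (!inherits(f, "formula") || length(f) != 2) {
      stop("phi, p and psi must be one-sided formulas", call. = FALSE)
    }
  }
  structure(list(phi = phi, p = p, psi = psi), class = "ms_spec")
}

#' @export
format.ms_spec <- function(x, ...) {
  fm <- function(f) {
    s <- paste(deparse(f[[2]]), collapse = "")
    gsub("\\s+", " ", s)
  }
  paste0("phi(", fm(x$phi), ") p(", fm(x$p), ") psi(", fm(x$psi), ")")
}

#' @export
print.ms_spec <- function(x, ...) {
  cat("<ms_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

## current age class for an interval starting at occasion `t`
## (or, for p, the arrival occasion t+1 is associated with the same
## interval): SY only during the first interval after SY marking.
age_at <- function(age_marking, first, t, age_mode = "transient") {
  age_mode <- match.arg(age_mode, c("transient", "static"))
  if (age_mode == "static") return(as.character(age_marking))
  ifelse(as.character(age_marking) == "SY" & t == first, "SY", "ASY")
}

#' Control options for model compilation and fitting
#'
#' @param age_mode `"transient"` (default): SY birds graduate to ASY after
#'   one interval; `"static"`: age class fixed at marking.
#' @param psi_density_year `"current"` (default): the `density` covariate on
#'   `psi` is the destination-year density of the origin habitat;
#'   `"previous"`: the origin-year density.
#' @param n_starts Number of random optimizer starts in addition to the
#'   null start at beta = 0.
#' @param start_sd Standard deviation of random starting values.
#' @param maxit Maximum optimizer iterations.
#' @param grad_tol Maximum absolute gradient of -2 log L accepted as
#'   converged.
#' @param seed Seed for the random starts.
#' @return A list of class `ms_control`.
#' @export
ms_control <- function(age_mode = c("transient", "static"),
                       psi_density_year = c("current", "previous"),
                       n_starts = 5, start_sd = 1, maxit = 500,
                       grad_tol = 1e-3, seed = 1) {
  structure(list(
    age_mode = match.arg(age_mode),
    psi_density_year = match.arg(psi_density_year),
    n_starts = n_starts, start_sd = start_sd, maxit = maxit,
    grad_tol = grad_tol, seed = seed
  ), class = "ms_control")
}

## Build the covariate frame for one parameter block.
## kind: "interval" (phi/psi; indexed by interval t = origin occasion)
##       or "occasion" (p; indexed by the encounter occasion t).
block_frame <- function(kind, cohorts, n_occasions, covariates, control,
                        density_year = c("origin", "destination")) {
  density_year <- match.arg(density_year)
  T <- n_occasions
  idx <- if (kind == "interval") seq_len(T - 1) else seq_len(T)
  g <- expand.grid(cohort = seq_len(nrow(cohorts)), time = idx,
                   state = .ms_states, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- as_tibble(g)
  g$sex <- cohorts$sex[g$cohort]
  first <- cohorts$first[g$cohort]
  agemark <- cohorts$age[g$cohort]
  ## for p the encounter occasion t belongs to the interval t-1 -> t
  t_int <- if (kind == "interval") g$time else g$time - 1L
  g$age <- factor(age_at(agemark, first, t_int, control$age_mode),
                  levels = .ms_ages)
  g$state <- factor(g$state, levels = .ms_states)
  g$male <- as.integer(g$sex == "male")
  if (!is.null(covariates)) {
    ann <- setdiff(names(covariates), c("year", "density_F", "density_C",
                                        "fledge_F", "fledge_C"))
    cov_row <- pmin(pmax(t_int, 1L), nrow(covariates))
    for (cl in ann) g[[cl]] <- covariates[[cl]][cov_row]
    if (all(c("density_F", "density_C") %in% names(covariates))) {
      dens_row <- if (density_year == "destination") {
        pmin(cov_row + 1L, nrow(covariates))
      } else cov_row
      g$density <- ifelse(g$state == "F",
                          covariates$density_F[dens_row],
                          covariates$density_C[dens_row])
    }
    if (all(c("fledge_F", "fledge_C") %in% names(covariates))) {
      g$fledge <- ifelse(g$state == "F",
                         covariates$fledge_F[cov_row],
                         covariates$fledge_C[cov_row])
    }
  }
  g
}

## Compile an ms_spec against data into per-block design matrices whose
## rows are ordered (cohort, time, state) with cohort varying fastest,
## matching the column-major probability arrays used by the likelihood.
compile_design <- function(spec, histories, covariates = NULL,
                           control = ms_control()) {
  stopifnot(inherits(spec, "ms_spec"))
  histories <- ms_histories(histories)
  T <- attr(histories, "n_occasions")
  cohorts <- dplyr::distinct(
    dplyr::arrange(histories[, c("sex", "age", "first")],
                   .data$sex, .data$age, .data$first))
  if (nrow(cohorts) == 0) cohorts <- tibble(sex = factor("female", .ms_sexes),
                                            age = factor("ASY", .ms_ages),
                                            first = 1L)
  key <- paste(histories$sex, histories$age, histories$first)
  cohort_of <- match(key, paste(cohorts$sex, cohorts$age, cohorts$first))

  blocks <- list()
  for (par in c("phi", "p", "psi")) {
    kind <- if (par == "p") "occasion" else "interval"
    dens <- if (par == "psi" && control$psi_density_year == "current") {
      "destination"
    } else "origin"
    frame <- block_frame(kind, cohorts, T, covariates, control,
                         density_year = dens)
    f <- spec[[par]]
    vars <- setdiff(all.vars(f), names(frame))
    if (length(vars) > 0) {
      stop("unknown term(s) in ", par, " formula: ",
           paste(vars, collapse = ", "), call. = FALSE)
    }
    tt <- terms(f)
    X <- model.matrix(tt, frame)
    colnames(X) <- paste0(par, ":", colnames(X))
    blocks[[par]] <- list(
      X = X, frame = frame, terms = tt,
      xlev = list(sex = .ms_sexes, age = .ms_ages, state = .ms_states),
      dims = c(nrow(cohorts), length(unique(frame$time)), 2L))
  }
  structure(list(
    spec = spec, blocks = blocks, cohorts = cohorts, cohort_of = cohort_of,
    n_occasions = T, control = control,
    k = sum(vapply(blocks, function(b) ncol(b$X), 0L))
  ), class = "ms_design")
}

## number of identifiable structural columns (design columns) of a spec
## when compiled against a given dataset

#' Count the structural parameters of a model
#'
#' Returns `k`, the total number of design-matrix columns across the
#' `phi`, `p` and `psi` blocks when `spec` is compiled against the data.
#'
#' @param spec An [ms_spec()].
#' @param histories Encounter-history tibble.
#' @param covariates Optional standardized annual covariate tibble.
#' @param control An [ms_control()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, histories, covariates = NULL,
                             control = ms_control()) {
  compile_design(spec, histories, covariates, control)$k
}

## split a beta vector into named per-block pieces
split_beta <- function(design, beta) {
  ks <- vapply(design$blocks, function(b) ncol(b$X), 0L)
  if (length(beta) != sum(ks)) {
    stop("beta has length ", length(beta), " but the design has ",
         sum(ks), " columns", call. = FALSE)
  }
  ends <- cumsum(ks)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- Map(function(s, e) beta[s:e], starts, ends)
  names(out) <- names(ks)
  out
}

## probability arrays on [0,1]: list(phi, psi, p) each a numeric vector
## laid out column-major over (cohort, time, state)
real_arrays <- function(design, beta) {
  bb <- split_beta(design, beta)
  lapply(setNames(nm = c("phi", "p", "psi")), function(par) {
    as.numeric(plogis(design$blocks[[par]]$X %*% bb[[par]]))
  })[c("phi", "psi", "p")]
}
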