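#' Fit a multistate mark-recapture model by maximum likelihood
#'
#' Maximizes the Arnason-Schwarz likelihood over the logit-scale
#' coefficients of the compiled design, using `nlminb` from a null start
#' (beta = 0) plus `n_starts` seeded random starts. The coefficient
#' covariance is twice the inverse Hessian of -2 log L at the optimum.
#'
#' @param data Either an encounter-history tibble or an `ms_dataset` as
#'   returned by [ms_simulate()] (whose covariates are used unless
#'   `covariates` is given).
#' @param spec An [ms_spec()].
#' @param covariates Optional standardized annual covariate tibble.
#' @param control An [ms_control()].
#' @return An object of class `ms_fit` with elements `beta`, `vcov`,
#'   `neg2lnl`, `k`, `ess` (effective sample size: releases plus live
#'   re-encounters), `converged`, `boundary` (names of design cells whose
#'   fitted probability is within 1e-6 of 0 or 1) and the compiled design.
#' @examples
#' \donttest{
#' sim <- ms_simulate(redstart_scenario(), seed = 1)
#' fit <- ms_fit(sim, ms_spec(phi = ~sex, p = ~sex + state, psi = ~1))
#' glance(fit)
#' }
#' @export
ms_fit <- function(data, spec, covariates = NULL, control = ms_control()) {
  if (inherits(data, "ms_dataset")) {
    if (is.null(covariates)) covariates <- data$covariates
    histories <- data$histories
  } else {
    histories <- data
  }
  histories <- ms_histories(histories)
  if (nrow(histories) == 0) stop("cannot fit an empty dataset", call. = FALSE)
  design <- compile_design(spec, histories, covariates, control)
  agg <- aggregate_histories(design, histories)
  k <- design$k

  fn <- function(beta) {
    v <- neg2ll_design(design, agg, beta)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- list(rep(0, k))
  if (control$n_starts > 0) {
    rs <- local({
      old <- get_rng_state()
      on.exit(set_rng_state(old))
      set.seed(control$seed)
      lapply(seq_len(control$n_starts),
             function(i) rnorm(k, 0, control$start_sd))
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      nlminb(s, fn, control = list(iter.max = control$maxit,
                                   eval.max = 20L * control$maxit)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective - 1e-9) best <- opt
  }
  if (is.null(best)) {
    stop("optimization failed from every start; check the model structure",
         call. = FALSE)
  }
  beta <- best$par
  grad <- num_grad(fn, beta)
  converged <- all(is.finite(grad)) && max(abs(grad)) < control$grad_tol

  H <- tryCatch(optimHess(beta, fn), error = function(e) NULL)
  vcov <- matrix(NA_real_, k, k)
  if (!is.null(H)) {
    Vi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vi)) {
      vcov <- 2 * (Vi + t(Vi)) / 2  # cov = 2 * inverse Hessian of -2lnL
    }
  }
  cn <- unlist(lapply(design$blocks, function(b) colnames(b$X)),
               use.names = FALSE)
  names(beta) <- cn
  dimnames(vcov) <- list(cn, cn)

  ra <- real_arrays(design, beta)
  boundary <- boundary_cells(design, ra)

  structure(list(
    spec = spec, beta = beta, vcov = vcov,
    neg2lnl = best$objective, k = k,
    ess = effective_sample_size(histories),
    converged = converged, gradient = grad,
    n_starts = length(starts), boundary = boundary,
    design = design, histories = histories, covariates = covariates,
    control = control
  ), class = "ms_fit")
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

num_grad <- function(fn, x, h = 1e-6) {
  f0 <- fn(x)
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- xm <- x
    xp[i] <- x[i] + hi
    xm[i] <- x[i] - hi
    (fn(xp) - fn(xm)) / (2 * hi)
  }, 0)
}

## Effective sample size for QAICc: number of releases, i.e. initial
## captures plus live re-encounters (all re-encountered animals are
## re-released in this design).
effective_sample_size <- function(histories) {
  m <- ch_matrix(histories)
  sum(m > 0)
}

## real-parameter cells (over design rows in use) within 1e-6 of 0/1
boundary_cells <- function(design, ra) {
  out <- character()
  for (par in names(ra)) {
    pr <- ra[[par]]
    hit <- pr < 1e-6 | pr > 1 - 1e-6
    if (any(hit)) {
      fr <- design$blocks[[par]]$frame
      lab <- unique(paste0(par, "[", fr$sex, ".", fr$age, ".", fr$state,
                           ",t=", fr$time, "]")[hit])
      out <- c(out, lab)
    }
  }
  out
}

#' @export
print.ms_fit <- function(x, ...) {
  cat("<ms_fit> ", format(x$spec), "\n", sep = "")
  cat("  -2 log L = ", format(x$neg2lnl, digits = 8), ", k = ", x$k,
      ", ess = ", x$ess, ", converged: ", x$converged, "\n", sep = "")
  if (length(x$boundary) > 0) {
    cat("  boundary estimates: ", length(x$boundary), " cell(s)\n", sep = "")
  }
  invisible(x)
}

#' Back-transformed real-parameter estimates
#'
#' Evaluates a fitted model on the probability scale for user-specified
#' cells, with delta-method standard errors and Wald intervals computed on
#' the logit scale and back-transformed (so intervals always lie inside
#' `(0, 1)`). The coefficient covariance is inflated by the overdispersion
#' factor `chat` (link-scale SEs scale with `sqrt(chat)`).
#'
#' @param fit An [ms_fit()].
#' @param param `"phi"`, `"p"` or `"psi"`.
#' @param newdata Tibble of cells: columns `sex`, `age`, `state` and any
#'   numeric covariates used by the formula (missing numeric covariates
#'   default to 0, the standardized mean; `male` is derived from `sex`).
#' @param chat Overdispersion factor (>= 1).
#' @param level Confidence level.
#' @return A tibble with the `newdata` columns plus `param`, `estimate`,
#'   `se`, `lcl`, `ucl`. If the Hessian was singular the SEs are `NA` but
#'   estimates are still returned.
#' @export
real_estimates <- function(fit, param = c("phi", "p", "psi"),
                           newdata = NULL, chat = 1, level = 0.95) {
  param <- match.arg(param)
  if (chat < 1) stop("chat must be >= 1", call. = FALSE)
  if (is.null(newdata)) {
    newdata <- tidyr::expand_grid(sex = .ms_sexes, age = .ms_ages,
                                  state = if (param == "psi") "F" else .ms_states)
  }
  newdata <- as_tibble(newdata)
  X <- design_rows(fit$design, param, newdata)
  bb <- split_beta(fit$design, fit$beta)
  eta <- as.numeric(X %*% bb[[param]])
  est <- plogis(eta)
  V <- block_vcov(fit, param) * chat
  se_link <- if (anyNA(V)) rep(NA_real_, length(eta)) else {
    sqrt(pmax(0, rowSums((X %*% V) * X)))
  }
  z <- qnorm(1 - (1 - level) / 2)
  out <- newdata
  out$param <- param
  out$estimate <- est
  out$se <- est * (1 - est) * se_link
  out$lcl <- plogis(eta - z * se_link)
  out$ucl <- plogis(eta + z * se_link)
  out
}

## model-matrix rows for prediction cells
design_rows <- function(design, param, newdata) {
  b <- design$blocks[[param]]
  nd <- as_tibble(newdata)
  vars <- all.vars(b$terms)
  if ("sex" %in% names(nd)) {
    nd$sex <- check_level(nd$sex, .ms_sexes, "sex")
    if (!"male" %in% names(nd)) nd$male <- as.integer(nd$sex == "male")
  }
  if ("age" %in% names(nd)) nd$age <- check_level(nd$age, .ms_ages, "age")
  if ("state" %in% names(nd)) nd$state <- check_level(nd$state, .ms_states, "state")
  for (v in setdiff(vars, names(nd))) {
    if (v %in% c("sex", "age", "state")) {
      stop("newdata must supply column '", v, "'", call. = FALSE)
    }
    nd[[v]] <- 0
  }
  X <- model.matrix(b$terms, nd, xlev = b$xlev[intersect(names(b$xlev), vars)])
  colnames(X) <- paste0(param, ":", colnames(X))
  X
}

block_vcov <- function(fit, param) {
  cn <- colnames(fit$design$blocks[[param]]$X)
  fit$vcov[cn, cn, drop = FALSE]
}

## ---- broom-style methods -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted multistate model
#'
#' @param x An `ms_fit`.
#' @param chat Overdispersion factor used to inflate standard errors.
#' @param ... Unused.
#' @return A tibble with one row per logit-scale coefficient: `block`,
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.ms_fit <- function(x, chat = 1, ...) {
  se <- sqrt(pmax(0, diag(x$vcov)) * chat)
  block <- sub(":.*$", "", names(x$beta))
  term <- sub("^[^:]*:", "", names(x$beta))
  tibble(block = block, term = term, estimate = unname(x$beta),
         std.error = unname(se),
         conf.low = unname(x$beta - 1.96 * se),
         conf.high = unname(x$beta + 1.96 * se))
}

#' One-row model summary
#'
#' @param x An `ms_fit`.
#' @param chat Overdispersion factor for the QAICc column.
#' @param ... Unused.
#' @return A tibble with `neg2lnl`, `k`, `ess`, `qaicc`, `converged`,
#'   `n_boundary`.
#' @export
glance.ms_fit <- function(x, chat = 1, ...) {
  tibble(neg2lnl = x$neg2lnl, k = x$k, ess = x$ess,
         qaicc = qaicc(x$neg2lnl, chat, x$k, x$ess),
         converged = x$converged, n_boundary = length(x$boundary))
}
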