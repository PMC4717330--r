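#' Quasi-likelihood AIC with small-sample correction
#'
#' `QAICc = -2lnL / chat + 2k + 2k(k+1) / (ess - k - 1)`.
#'
#' @param neg2lnl -2 log likelihood.
#' @param chat Overdispersion factor; must be >= 1 (values below 1 are
#'   conventionally truncated to 1 before calling, see [truncate_chat()]).
#' @param k Number of structural parameters.
#' @param ess Effective sample size; must exceed `k + 1`.
#' @return The QAICc value.
#' @examples
#' qaicc(100, 1, 2, 100) # 104.1237
#' @export
qaicc <- function(neg2lnl, chat, k, ess) {
  if (any(chat < 1)) stop("chat must be >= 1", call. = FALSE)
  if (any(ess <= k + 1)) {
    stop("effective sample size must exceed k + 1", call. = FALSE)
  }
  neg2lnl / chat + 2 * k + 2 * k * (k + 1) / (ess - k - 1)
}

#' @rdname qaicc
#' @param chat_raw A possibly sub-1 overdispersion estimate.
#' @export
truncate_chat <- function(chat_raw) max(1, chat_raw)

#' Akaike weights
#'
#' Normalized relative likelihoods `exp(-delta/2) / sum(exp(-delta/2))`,
#' where `delta` are the (Q)AICc differences from the best model. The
#' input may be raw criterion values or differences; weights are invariant
#' to a constant shift.
#'
#' @param qaicc_values Numeric vector of QAICc values (or deltas).
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(0, 2))
#' @export
akaike_weights <- function(qaicc_values) {
  if (length(qaicc_values) == 0) stop("need at least one value", call. = FALSE)
  d <- qaicc_values - min(qaicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank a candidate model set by QAICc
#'
#' @param fits A (possibly named) list of [ms_fit()] objects fitted to the
#'   same dataset.
#' @param chat Overdispersion factor (>= 1) applied to every model.
#' @return An object of class `ms_candidates`: the ranked table is
#'   available via [tidy()], the fitted models are kept (ranked order) in
#'   `$fits`. Ties in QAICc are broken by smaller `k`, then by the model
#'   string.
#' @export
ms_candidates <- function(fits, chat = 1) {
  if (inherits(fits, "ms_fit")) fits <- list(fits)
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, TRUE, "ms_fit")))
  model <- vapply(fits, function(f) format(f$spec), "")
  q <- vapply(fits, function(f) qaicc(f$neg2lnl, chat, f$k, f$ess), 0)
  k <- vapply(fits, function(f) as.integer(f$k), 0L)
  ord <- order(q, k, model)
  fits <- fits[ord]
  tab <- tibble(
    model = model[ord],
    qaicc = q[ord],
    delta_qaicc = q[ord] - min(q),
    weight = akaike_weights(q[ord]),
    k = k[ord],
    qdev = vapply(fits, function(f) f$neg2lnl / chat, 0),
    converged = vapply(fits, function(f) f$converged, TRUE)
  )
  structure(list(table = tab, fits = fits, chat = chat),
            class = "ms_candidates")
}

#' @export
print.ms_candidates <- function(x, ...) {
  cat("<ms_candidates> ", nrow(x$table), " models, chat = ", x$chat,
      "\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' @export
tidy.ms_candidates <- function(x, ...) x$table

#' Model-averaged real-parameter estimates
#'
#' Averages back-transformed estimates across a candidate set with Akaike
#' weights, and reports the unconditional standard error
#' `sum(w_i * sqrt(var_i + (theta_i - theta_bar)^2))`, which folds
#' between-model spread into the sampling variance. Confidence intervals
#' are computed on the logit scale from the averaged estimate and
#' unconditional SE.
#'
#' @param candidates An [ms_candidates()] object.
#' @param param `"phi"`, `"p"` or `"psi"`.
#' @param newdata Cells to evaluate (see [real_estimates()]).
#' @param level Confidence level.
#' @return A tibble like [real_estimates()] with an added `weight`-free
#'   unconditional `se`.
#' @export
model_average <- function(candidates, param = c("phi", "p", "psi"),
                          newdata = NULL, level = 0.95) {
  stopifnot(inherits(candidates, "ms_candidates"))
  param <- match.arg(param)
  w <- candidates$table$weight
  per_model <- lapply(candidates$fits, real_estimates, param = param,
                      newdata = newdata, chat = candidates$chat,
                      level = level)
  est <- vapply(per_model, function(m) m$estimate, per_model[[1]]$estimate)
  se <- vapply(per_model, function(m) m$se, per_model[[1]]$se)
  est <- matrix(est, ncol = length(w))
  se <- matrix(se, ncol = length(w))
  if (anyNA(est)) stop("a model failed to supply estimates for a cell",
                       call. = FALSE)
  avg <- as.numeric(est %*% w)
  se_unc <- vapply(seq_along(avg), function(i) {
    sum(w * sqrt(se[i, ]^2 + (est[i, ] - avg[i])^2))
  }, 0)
  out <- per_model[[1]]
  out$estimate <- avg
  out$se <- se_unc
  z <- qnorm(1 - (1 - level) / 2)
  inside <- avg > 0 & avg < 1
  se_link <- ifelse(inside, se_unc / (avg * (1 - avg)), 0)
  out$lcl <- ifelse(inside, plogis(qlogis(avg) - z * se_link), avg)
  out$ucl <- ifelse(inside, plogis(qlogis(avg) + z * se_link), avg)
  out
}

## ---- stepwise annual-covariate procedure ---------------------------------

#' Describe one annual covariate for the stepwise procedure
#'
#' @param name Label used in the provenance log.
#' @param on Parameter the covariate acts on: `"phi"` or `"psi"`.
#' @param terms Character vector of formula terms, e.g.
#'   `c("soi", "I(soi^2)")` or `"density:male"`.
#' @param interactions Optional subset of `c("age", "sex")`; each listed
#'   factor yields an additional phase-1 variant with
#'   covariate-by-factor interaction terms.
#' @return A list of class `ms_cov_term`.
#' @export
cov_term <- function(name, on = c("phi", "psi"), terms,
                     interactions = NULL) {
  on <- match.arg(on)
  stopifnot(is.character(terms), length(terms) > 0,
            all(interactions %in% c("age", "sex")))
  structure(list(name = name, on = on, terms = terms,
                 interactions = interactions), class = "ms_cov_term")
}

add_terms <- function(spec, on, terms) {
  f <- update.formula(spec[[on]],
                      stats::as.formula(paste("~ . +",
                                              paste(terms, collapse = " + "))))
  out <- spec
  out[[on]] <- f
  ms_spec(phi = out$phi, p = out$p, psi = out$psi)
}

variant_terms <- function(item) {
  v <- list(plain = item$terms)
  for (ia in item$interactions) {
    v[[paste0("x_", ia)]] <- c(item$terms, paste0(item$terms, ":", ia))
  }
  v
}

#' Stepwise evaluation of annual covariates
#'
#' Implements the three-phase covariate selection procedure used with
#' QAICc in multistate survival analyses:
#'
#' 1. each covariate on the menu (and each of its listed age/sex
#'    interaction variants) is added singly to the base model; a covariate
#'    is retained when its best variant strictly lowers QAICc;
#' 2. the retained covariates are combined in one model and all reduced
#'    versions (subsets of the retained set) are evaluated;
#' 3. every excluded covariate is added back to the current top model; if
#'    this does not lower QAICc the augmented model is removed from the
#'    candidate set (models differing by one unsupported parameter are
#'    spuriously competitive), otherwise it is kept.
#'
#' @param data Dataset (tibble of histories or `ms_dataset`).
#' @param base_spec The base [ms_spec()] without annual covariates.
#' @param menu List of [cov_term()] items.
#' @param covariates Standardized annual covariate tibble.
#' @param chat Overdispersion factor (>= 1).
#' @param control An [ms_control()].
#' @return An `ms_candidates` object over all retained evaluated models,
#'   with a provenance `log` tibble (phase, model, qaicc, decision)
#'   attached, plus `top`, the best fitted model.
#' @export
ms_stepwise <- function(data, base_spec, menu, covariates, chat = 1,
                        control = ms_control()) {
  stopifnot(all(vapply(menu, inherits, TRUE, "ms_cov_term")))
  fits <- list()
  model_items <- list()  # covariate names included in each fitted model
  log <- list()
  fit1 <- function(spec, items = character()) {
    key <- format(spec)
    if (!is.null(fits[[key]])) return(fits[[key]])
    f <- tryCatch(ms_fit(data, spec, covariates, control),
                  error = function(e) NULL)
    fits[[key]] <<- f
    model_items[[key]] <<- items
    f
  }
  q_of <- function(f) qaicc(f$neg2lnl, chat, f$k, f$ess)
  note <- function(phase, name, model, q, decision) {
    log[[length(log) + 1]] <<- tibble(phase = phase, covariate = name,
                                      model = model, qaicc = q,
                                      decision = decision)
  }

  base_fit <- fit1(base_spec)
  if (is.null(base_fit)) stop("base model failed to fit", call. = FALSE)
  q_base <- q_of(base_fit)
  note(1L, "(base)", format(base_spec), q_base, "base")

  if (length(menu) == 0) {
    cand <- ms_candidates(list(base_fit), chat = chat)
    cand$log <- dplyr::bind_rows(log)
    cand$top <- base_fit
    return(cand)
  }

  ## phase 1: single additions
  best_variant <- list()
  retained <- character()
  for (item in menu) {
    vq <- Inf
    vbest <- NULL
    for (vt in variant_terms(item)) {
      spec <- add_terms(base_spec, item$on, vt)
      f <- fit1(spec, items = item$name)
      if (is.null(f)) {
        note(1L, item$name, format(spec), NA_real_, "failed to converge")
        next
      }
      q <- q_of(f)
      note(1L, item$name, format(spec), q,
           if (q < q_base) "lowers QAICc" else "no improvement")
      if (q < vq) {
        vq <- q
        vbest <- vt
      }
    }
    best_variant[[item$name]] <- vbest
    if (is.finite(vq) && vq < q_base) retained <- c(retained, item$name)
  }

  by_name <- setNames(menu, vapply(menu, function(i) i$name, ""))
  combo_spec <- function(names_in) {
    spec <- base_spec
    for (nm in names_in) {
      spec <- add_terms(spec, by_name[[nm]]$on, best_variant[[nm]])
    }
    spec
  }

  ## phase 2: combined model and all reduced versions
  if (length(retained) > 1) {
    subsets <- unlist(lapply(seq_along(retained), function(m) {
      utils::combn(retained, m, simplify = FALSE)
    }), recursive = FALSE)
    for (ss in subsets) {
      spec <- combo_spec(ss)
      f <- fit1(spec, items = ss)
      if (is.null(f)) {
        note(2L, paste(ss, collapse = "+"), format(spec), NA_real_,
             "failed to converge")
      } else {
        note(2L, paste(ss, collapse = "+"), format(spec), q_of(f), "evaluated")
      }
    }
  }

  ok_fits <- Filter(Negate(is.null), fits)
  qs <- vapply(ok_fits, q_of, 0)
  top_key <- names(ok_fits)[order(qs, vapply(ok_fits, function(f) f$k, 0L),
                                  names(ok_fits))][1]
  q_top <- min(qs)

  ## phase 3: re-add excluded covariates to the top model
  removed <- character()
  top_items <- model_items[[top_key]] %||% character()
  top_spec_obj <- ok_fits[[top_key]]$spec
  for (nm in setdiff(names(by_name), top_items)) {
    vt <- best_variant[[nm]] %||% by_name[[nm]]$terms
    spec <- add_terms(top_spec_obj, by_name[[nm]]$on, vt)
    f <- fit1(spec, items = c(top_items, nm))
    if (is.null(f)) {
      note(3L, nm, format(spec), NA_real_, "failed to converge")
      next
    }
    q <- q_of(f)
    if (q < q_top) {
      note(3L, nm, format(spec), q, "kept (lowers QAICc)")
    } else {
      note(3L, nm, format(spec), q, "removed (no QAICc reduction)")
      removed <- c(removed, format(spec))
    }
  }

  final <- Filter(Negate(is.null), fits)
  final <- final[!vapply(final, function(f) format(f$spec), "") %in% removed]
  cand <- ms_candidates(unname(final), chat = chat)
  cand$log <- dplyr::bind_rows(log)
  cand$retained <- retained
  cand$top <- cand$fits[[1]]
  cand$top_items <- model_items[[format(cand$top$spec)]] %||% character()
  cand
}

`%||%` <- function(a, b) if (is.null(a)) b else a
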