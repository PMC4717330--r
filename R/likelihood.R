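## ---- real-parameter containers -------------------------------------------

## Normalise user-supplied real parameters for a single history / small
## enumeration: phi and p as length-2 vectors c(F, C) or time-by-state
## matrices; psi as c(FC, CF) move probabilities or a matrix.
norm_params <- function(params, T) {
  pick <- function(x, nt, what) {
    if (is.matrix(x)) {
      if (nrow(x) != nt || ncol(x) != 2) {
        stop(what, " matrix must be ", nt, " x 2", call. = FALSE)
      }
      return(x)
    }
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2) stop(what, " must have length 1 or 2", call. = FALSE)
    matrix(rep(as.numeric(x), each = nt), nt, 2)
  }
  out <- list(phi = pick(params$phi, T - 1, "phi"),
              psi = pick(params$psi, T - 1, "psi"),
              p = pick(params$p, T, "p"))
  rng <- unlist(out)
  if (any(rng < 0 | rng > 1)) stop("real parameters must lie in [0,1]",
                                   call. = FALSE)
  out
}

#' Probability of one encounter history
#'
#' Computes the probability of an observed multistate encounter history,
#' conditional on the first release, by forward recursion over the latent
#' states (alive in F, alive in C, dead/emigrated). Each interval applies
#' survival in the origin state, then movement, then detection in the
#' destination state.
#'
#' @param ch Encounter history string over `0`, `F`, `C`, e.g. `"F0C"`.
#' @param params List with entries `phi`, `psi`, `p`. `phi` and `p` are
#'   state-specific probabilities `c(F, C)` (or time-by-state matrices:
#'   `phi`/`psi` with `T-1` rows for intervals, `p` with `T` rows for
#'   occasions). `psi` holds the move probabilities `c(FC, CF)`.
#' @return The history probability.
#' @examples
#' # survive, stay, be seen: 0.5 * 0.8 * 0.7
#' history_probability("FF", list(phi = c(0.5, 0.5), psi = c(0.2, 0.1),
#'                                p = c(0.7, 0.9)))
#' @export
history_probability <- function(ch, params) {
  h <- ms_histories(tibble(id = "h", ch = ch, sex = "female", age = "ASY"))
  T <- nchar(ch)
  if (T < 1) stop("empty history", call. = FALSE)
  pp <- norm_params(params, T)
  obs <- ch_matrix(h)[1, ]
  f <- h$first[1]
  a <- c(0, 0)
  a[obs[f]] <- 1
  dead <- 0
  if (T >= 2) {
    for (t in f:(T - 1)) {
      surv <- pp$phi[t, ]
      mv <- pp$psi[t, ]
      an <- c(a[1] * surv[1] * (1 - mv[1]) + a[2] * surv[2] * mv[2],
              a[1] * surv[1] * mv[1] + a[2] * surv[2] * (1 - mv[2]))
      dn <- dead + sum(a * (1 - surv))
      o <- obs[t + 1]
      det <- pp$p[t + 1, ]
      if (o > 0) {
        a <- c(0, 0)
        a[o] <- an[o] * det[o]
        dead <- 0
      } else {
        a <- an * (1 - det)
        dead <- dn
      }
    }
  }
  sum(a) + dead
}

#' Exhaustive enumeration of observable histories (testing oracle)
#'
#' Enumerates every latent path (state sequence over \{F, C, dead\}) and
#' every detection outcome after a single release, accumulating the
#' probability of each observable encounter history. Intended as an
#' independent brute-force check of the forward recursion on small
#' problems; guarded to `T <= 5` occasions.
#'
#' @param T Number of occasions (at most 5).
#' @param release_occasion,release_state Occasion (1-based) and state
#'   (`"F"`/`"C"`) of first capture.
#' @param params Real parameters as in [history_probability()].
#' @return A tibble with columns `ch` and `prob`; `sum(prob)` is 1 for any
#'   valid parameter set.
#' @export
enumerate_histories <- function(T, release_occasion, release_state, params) {
  if (T > 5) stop("enumeration is limited to T <= 5 occasions", call. = FALSE)
  if (release_occasion < 1 || release_occasion > T) {
    stop("release occasion out of range", call. = FALSE)
  }
  s0 <- match(release_state, .ms_states)
  if (is.na(s0)) stop("release state must be F or C", call. = FALSE)
  pp <- norm_params(params, T)
  acc <- new.env(parent = emptyenv())
  add <- function(key, pr) {
    assign(key, pr + (if (exists(key, acc)) get(key, acc) else 0), acc)
  }
  codes <- c("F", "C")
  recurse <- function(t, state, obs_so_far, pr) {
    if (t == T) {
      add(paste(obs_so_far, collapse = ""), pr)
      return(invisible())
    }
    if (state == 0) { # dead/emigrated: only zeros follow
      add(paste(c(obs_so_far, rep("0", T - t)), collapse = ""), pr)
      return(invisible())
    }
    surv <- pp$phi[t, state]
    mv <- pp$psi[t, state]
    recurse(t + 1, 0L, c(obs_so_far, "0"), pr * (1 - surv))
    for (dest in 1:2) {
      trans <- if (dest == state) 1 - mv else mv
      det <- pp$p[t + 1, dest]
      base <- pr * surv * trans
      recurse(t + 1, dest, c(obs_so_far, codes[dest]), base * det)
      recurse(t + 1, dest, c(obs_so_far, "0"), base * (1 - det))
    }
  }
  prefix <- c(rep("0", release_occasion - 1), codes[s0])
  recurse(release_occasion, s0, prefix, 1)
  keys <- ls(acc)
  out <- tibble(ch = keys,
                prob = unname(vapply(keys, function(k) get(k, acc), 0)))
  dplyr::arrange(out, dplyr::desc(.data$prob), .data$ch)
}

## ---- dataset-level likelihood --------------------------------------------

## Aggregate histories into unique (cohort, ch) rows with counts for the
## compiled design.
aggregate_histories <- function(design, histories) {
  key <- paste(design$cohort_of, histories$ch)
  u <- !duplicated(key)
  idx <- which(u)
  count <- as.numeric(table(factor(key, levels = key[u])))
  hu <- histories[idx, ]
  list(obs = ch_matrix(hu), first = hu$first,
       cohort = design$cohort_of[idx], count = count)
}

neg2ll_design <- function(design, agg, beta) {
  ra <- real_arrays(design, beta)
  ms_neg2ll_cpp(agg$obs, agg$first, agg$cohort, agg$count,
                ra$phi, ra$psi, ra$p, nrow(design$cohorts))
}

#' -2 log likelihood of a dataset under a model
#'
#' Computes minus twice the Arnason-Schwarz log likelihood of a set of
#' encounter histories, conditional on first releases, for a model
#' specification and coefficient vector on the logit scale.
#'
#' @param histories Encounter-history tibble (see [ms_histories()]).
#' @param spec An [ms_spec()].
#' @param beta Coefficient vector (length `k` of the compiled design).
#' @param covariates Optional standardized annual covariate tibble.
#' @param control An [ms_control()].
#' @return -2 log L (0 for an empty dataset; `Inf` if any history has
#'   probability zero, with the offending histories reported in a warning).
#' @export
neg2_log_likelihood <- function(histories, spec, beta, covariates = NULL,
                                control = ms_control()) {
  histories <- ms_histories(histories)
  if (nrow(histories) == 0) return(0)
  design <- compile_design(spec, histories, covariates, control)
  agg <- aggregate_histories(design, histories)
  val <- neg2ll_design(design, agg, beta)
  if (!is.finite(val)) {
    ra <- real_arrays(design, beta)
    pr <- ms_history_probs_cpp(agg$obs, agg$first, agg$cohort,
                               ra$phi, ra$psi, ra$p, nrow(design$cohorts))
    bad <- matrix_ch(agg$obs[pr <= 0, , drop = FALSE])
    warning("histories with probability zero under the model: ",
            paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  val
}
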