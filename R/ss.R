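#' Generic stepping-stone marginal-likelihood estimator
#'
#' Estimates a log marginal likelihood by bridging from the posterior to the
#' prior along power posteriors `p(theta) L(theta)^beta`. The rung powers
#' follow Beta(`alpha_beta`, 1) quantile spacing, `beta_j = (j/steps)^(1 /
#' alpha_beta)`, j = steps..0, concentrating rungs near the prior where the
#' integrand changes fastest. Sampling starts at the posterior (`beta = 1`,
#' used only as burn-in) and walks down; each rung's chain is initialized
#' from the previous rung's final state, so every step serves as burn-in for
#' the next. For each pair (beta_j, beta_{j+1}) the ratio contribution
#' `log (1/n) sum_i exp((beta_{j+1} - beta_j) lnL_i)` is computed from the
#' samples at the lower power beta_j (stably, with the max subtracted); the
#' estimate is the sum of the per-step contributions.
#'
#' @param state0 initial state (any R object).
#' @param sweep function `(state, beta)` performing one MCMC update
#'   targeting `prior * likelihood^beta`; must return the new state.
#' @param loglik_fn function `(state)` returning the data log-likelihood.
#' @param steps number of stepping stones (default 50).
#' @param ngen_per_step generations per rung.
#' @param sample_every thinning interval within a rung.
#' @param alpha_beta Beta-quantile spacing parameter (default 0.3).
#' @param burnin_first extra generations at `beta = 1` before stepping.
#' @return a `marginal_likelihood` object: `log_ml`, per-step contributions
#'   and a block-bootstrap Monte-Carlo standard error.
#' @export
stepping_stone_engine <- function(state0, sweep, loglik_fn, steps = 50L,
                                  ngen_per_step = 200L, sample_every = 2L,
                                  alpha_beta = 0.3, burnin_first = NULL) {
  steps <- as.integer(steps)
  stopifnot(steps >= 1)
  betas <- (steps:0 / steps)^(1 / alpha_beta) # beta_steps = 1 ... beta_0 = 0
  if (is.null(burnin_first)) burnin_first <- ngen_per_step
  st <- state0
  for (g in seq_len(burnin_first)) st <- sweep(st, 1)
  contrib <- numeric(steps)
  se2 <- numeric(steps)
  details <- vector("list", steps)
  for (k in seq_len(steps)) {
    b_hi <- betas[k]     # upper power of this interval
    b_lo <- betas[k + 1] # rung sampled from
    lnl <- numeric(0)
    for (g in seq_len(ngen_per_step)) {
      st <- sweep(st, b_lo)
      if (g %% sample_every == 0) lnl <- c(lnl, loglik_fn(st))
    }
    if (any(!is.finite(lnl)) && b_lo > 0) {
      stop(sprintf("non-finite likelihood sampled at step %d (beta = %g)",
                   k, b_lo))
    }
    d <- b_hi - b_lo
    mx <- max(lnl)
    contrib[k] <- d * mx + log(mean(exp(d * (lnl - mx))))
    se2[k] <- block_boot_var(lnl, d)
    details[[k]] <- tibble::tibble(step = k, beta_low = b_lo, beta_high = b_hi,
                                   n = length(lnl), contribution = contrib[k],
                                   mean_lnL = mean(lnl))
  }
  structure(list(log_ml = sum(contrib),
                 se = sqrt(sum(se2)),
                 steps = steps,
                 betas = betas,
                 contributions = dplyr::bind_rows(details)),
            class = "marginal_likelihood")
}

# block-bootstrap variance of one step's log-ratio contribution
block_boot_var <- function(lnl, d, nblock = 10L, B = 200L) {
  n <- length(lnl)
  if (n < nblock * 2 || d == 0) return(0)
  blocks <- split(lnl, cut(seq_len(n), nblock, labels = FALSE))
  mx <- max(lnl)
  reps <- vapply(seq_len(B), function(b) {
    smp <- unlist(blocks[sample.int(nblock, nblock, replace = TRUE)])
    d * mx + log(mean(exp(d * (smp - mx))))
  }, numeric(1))
  stats::var(reps)
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("<marginal_likelihood> log ML = %.4f (MC-SE %.4f), %d steps\n",
              x$log_ml, x$se, x$steps))
  invisible(x)
}

#' Stepping-stone marginal likelihood of (constrained) tree hypotheses
#'
#' Runs the package's constrained tree MCMC inside
#' [stepping_stone_engine()]: the topology prior is uniform over trees
#' satisfying `constraints` (hard constraints, proposal rejection), and the
#' likelihood power is annealed from the posterior down to the prior.
#'
#' @inheritParams run_mcmc
#' @param steps number of stepping stones (default 50, following common
#'   practice for constrained-topology comparisons).
#' @param ngen_per_step generations per rung.
#' @param sample_every within-rung thinning.
#' @return a `marginal_likelihood` with a `data_fingerprint` attribute used
#'   by [bayes_factor()] to refuse cross-data comparisons.
#' @export
stepping_stone <- function(cm, scheme = NULL, constraints = NULL,
                           steps = 50L, config = mcmc_config(),
                           ngen_per_step = 400L, sample_every = 2L,
                           start_tree = NULL) {
  if (is.null(scheme)) scheme <- default_scheme(cm)
  check_scheme(cm, scheme)
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- init_state(cm, scheme, constraints, config, start_tree)
  ctx <- build_ctx(cm, scheme, st$phy$tip.label)
  st$lnL <- state_loglik(st, ctx)
  st$lnP <- state_logprior(st, config)
  req <- required_keys(constraints, cm$taxa)
  sweep <- function(state, beta) {
    mcmc_move(state, ctx, config, req, lik_power = beta, heat = 1)
  }
  ml <- stepping_stone_engine(st, sweep, function(s) s$lnL, steps = steps,
                              ngen_per_step = ngen_per_step,
                              sample_every = sample_every)
  attr(ml, "data_fingerprint") <- data_fingerprint(cm)
  attr(ml, "hypothesis") <- if (is.null(constraints)) "unconstrained"
    else constraints$name
  ml
}

data_fingerprint <- function(cm) {
  v <- paste(c(cm$taxa, as.vector(cm$x)), collapse = "")
  # cheap order-sensitive hash; stable across sessions
  sum(utf8ToInt(substr(v, 1, min(nchar(v), 100000))) *
        (seq_len(min(nchar(v), 100000)) %% 977 + 1)) %% 2147483647
}

#' Bayes factor between two marginal-likelihood estimates
#'
#' Compares two hypotheses fit to the same data: reports the log Bayes
#' factor `delta_ln = lnML_a - lnML_b`, its doubled value `2 delta_ln`
#' (the Kass-Raftery scale on which values above 10 read "very strong"),
#' and a verbal category. The reported `score` defaults to `2 delta_ln`.
#'
#' @param a,b `marginal_likelihood` objects.
#' @param scale `"2ln"` (default) or `"ln"` for the reported score.
#' @return a one-row tibble: hypotheses, `delta_ln`, `two_delta_ln`,
#'   `score`, `category`, and the combined MC standard error.
#' @export
bayes_factor <- function(a, b, scale = c("2ln", "ln")) {
  scale <- match.arg(scale)
  fa <- attr(a, "data_fingerprint"); fb <- attr(b, "data_fingerprint")
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb)) {
    stop("marginal likelihoods were estimated on different data")
  }
  d <- a$log_ml - b$log_ml
  t2 <- 2 * d
  cat_of <- function(x) {
    ax <- abs(x)
    if (ax < 2) "none" else if (ax < 6) "positive"
    else if (ax < 10) "strong" else "very strong"
  }
  tibble::tibble(
    hypothesis_a = attr(a, "hypothesis") %||% "a",
    hypothesis_b = attr(b, "hypothesis") %||% "b",
    delta_ln = d,
    two_delta_ln = t2,
    score = if (scale == "2ln") t2 else d,
    category = cat_of(t2),
    se = sqrt(a$se^2 + b$se^2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
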