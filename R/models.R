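#' Nucleotide substitution models
#'
#' Time-reversible models JC, HKY and GTR, optionally with a proportion of
#' invariant sites (`+I`) and discrete-gamma rate variation (`+G`). The rate
#' matrix is scaled so the mean substitution rate at stationarity is 1, so
#' branch lengths are expected substitutions per site. `+I+G` is treated as
#' a (k+1)-component rate mixture: one zero-rate class with weight `pinv`
#' and k gamma classes sharing the remaining weight.
#'
#' @param family `"JC"`, `"HKY"` or `"GTR"`.
#' @param freq base frequencies (A, C, G, T); must sum to 1.
#' @param kappa HKY transition/transversion rate ratio (> 0).
#' @param rates GTR exchangeabilities in the order AC, AG, AT, CG, CT, GT;
#'   the last is fixed to 1.
#' @param pinv proportion of invariant sites in `[0, 1)`.
#' @param alpha gamma shape (> 0), or `NULL` for no rate variation.
#' @param ncat number of discrete gamma categories (default 4).
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(family = c("JC", "HKY", "GTR"),
                        freq = rep(0.25, 4), kappa = 2,
                        rates = rep(1, 6), pinv = 0,
                        alpha = NULL, ncat = 4L) {
  family <- match.arg(family)
  if (family == "JC") freq <- rep(0.25, 4)
  stopifnot(length(freq) == 4, all(freq > 0), abs(sum(freq) - 1) < 1e-8,
            pinv >= 0, pinv < 1)
  if (!is.null(alpha) && alpha <= 0) stop("gamma shape must be positive")
  if (family == "GTR") {
    stopifnot(length(rates) == 6, all(rates > 0))
    rates <- rates / rates[6]
  }
  structure(list(family = family, freq = freq, kappa = kappa,
                 rates = rates, pinv = pinv, alpha = alpha,
                 ncat = if (is.null(alpha)) 0L else as.integer(ncat),
                 states = c("A", "C", "G", "T")),
            class = "subst_model")
}

#' Mk model for discrete morphological characters
#'
#' Symmetric k-state Markov model with uniform stationary frequencies,
#' optionally with gamma rate variation and "variable" coding (likelihood
#' conditioned on the character being variable, correcting the
#' ascertainment bias of matrices that exclude constant characters).
#'
#' @param k number of states (>= 2).
#' @param variable condition the likelihood on variability (Mkv).
#' @param alpha gamma shape, or `NULL`.
#' @param ncat gamma categories.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(k = 2L, variable = TRUE, alpha = NULL, ncat = 4L) {
  stopifnot(k >= 2)
  if (!is.null(alpha) && alpha <= 0) stop("gamma shape must be positive")
  structure(list(family = "Mk", k = as.integer(k), variable = variable,
                 freq = rep(1 / k, k), alpha = alpha,
                 ncat = if (is.null(alpha)) 0L else as.integer(ncat),
                 pinv = 0,
                 states = as.character(seq_len(k) - 1L)),
            class = "mk_model")
}

#' Parse a model specification string
#'
#' Accepts strings such as `"GTR+I+G"`, `"HKY+I"`, `"JC"`, `"Mk+G"`,
#' case-insensitively. Parameters take their construction defaults and are
#' meant to be optimized or sampled downstream.
#'
#' @param spec model string.
#' @param k state count for Mk models.
#' @return a [subst_model] or [mk_model].
#' @export
parse_model <- function(spec, k = 2L) {
  parts <- toupper(strsplit(gsub("\\s", "", spec), "\\+")[[1]])
  fam <- parts[1]
  plus_i <- "I" %in% parts[-1]
  plus_g <- any(c("G", "GAMMA") %in% parts[-1])
  alpha <- if (plus_g) 1 else NULL
  if (fam == "MK") {
    if (plus_i) stop("Mk+I is not supported")
    return(mk_model(k = k, alpha = alpha))
  }
  if (!fam %in% c("JC", "JC69", "HKY", "HKY85", "GTR")) {
    stop("unknown model family: ", fam)
  }
  fam <- c(JC = "JC", JC69 = "JC", HKY = "HKY", HKY85 = "HKY", GTR = "GTR")[fam]
  subst_model(fam, pinv = if (plus_i) 0.1 else 0, alpha = alpha)
}

#' Scaled instantaneous rate matrix of a model
#'
#' Rows sum to zero and the matrix is scaled so that the mean rate at
#' stationarity equals 1.
#' @param m a [subst_model] or [mk_model].
#' @return square numeric matrix.
#' @export
q_matrix <- function(m) {
  if (inherits(m, "mk_model")) {
    k <- m$k
    Q <- matrix(1, k, k); diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
  } else {
    ex <- switch(m$family,
      JC = rep(1, 6),
      HKY = { k <- m$kappa; c(1, k, 1, 1, k, 1) },
      GTR = m$rates)
    Q <- matrix(0, 4, 4)
    idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (r in seq_len(6)) {
      i <- idx[r, 1]; j <- idx[r, 2]
      Q[i, j] <- ex[r] * m$freq[j]
      Q[j, i] <- ex[r] * m$freq[i]
    }
    diag(Q) <- -rowSums(Q)
  }
  pi_ <- m$freq
  mu <- -sum(pi_ * diag(Q))
  Q / mu
}

# Eigendecomposition of a reversible scaled Q via symmetrization,
# guaranteeing a real spectrum: B = D^1/2 Q D^-1/2 is symmetric.
q_eigen <- function(m) {
  Q <- q_matrix(m)
  pi_ <- m$freq
  d <- sqrt(pi_)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  U <- diag(1 / d) %*% es$vectors
  Uinv <- t(es$vectors) %*% diag(d)
  list(U = U, Uinv = Uinv, lambda = es$values)
}

#' Discrete-gamma rate categories
#'
#' Mean rate of each of `k` equal-probability bins of a Gamma(alpha, alpha)
#' density (mean 1), renormalized so the category average is exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of k rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) stop("gamma shape must be positive")
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (k == 1) return(1)
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean within each bin: k * [F_{alpha+1}(q_{i+1}) - F_{alpha+1}(q_i)]
  cdf1 <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  r <- k * diff(cdf1)
  r / mean(r)
}

# Full mixture over rate categories, including the invariant class.
mixture_rates <- function(m) {
  if (m$ncat > 0) {
    g <- discrete_gamma_rates(m$alpha, m$ncat)
  } else g <- 1
  if (m$pinv > 0) {
    list(rates = c(0, g), weights = c(m$pinv, rep((1 - m$pinv) / length(g),
                                                  length(g))))
  } else {
    list(rates = g, weights = rep(1 / length(g), length(g)))
  }
}

#' Transition probability matrix
#'
#' `exp(Qt)` for the scaled rate matrix of the model (the gamma/invariant
#' mixture is applied by the likelihood functions, not here).
#'
#' @param m a [subst_model] or [mk_model].
#' @param t branch length (>= 0), expected substitutions per site.
#' @return row-stochastic matrix.
#' @export
transition_probabilities <- function(m, t) {
  if (t < 0) stop("branch length must be non-negative")
  eg <- q_eigen(m)
  P <- eg$U %*% diag(exp(eg$lambda * t), length(eg$lambda)) %*% eg$Uinv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(m$states, m$states)
  P
}
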