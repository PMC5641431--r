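# Independent oracles used across the suite. These deliberately avoid the
# package's own pruning/uniformization code paths: matrix exponentials are
# computed by scaling-and-squaring of a Taylor series, likelihoods by
# explicit enumeration over interior-node states, and expected change
# counts by summing the uniformization series.

# naive matrix exponential (scaling and squaring + Taylor)
expm_naive <- function(A) {
  k <- max(0, ceiling(log2(max(1e-12, max(abs(A))))) + 4)
  B <- A / 2^k
  X <- diag(nrow(A)); term <- diag(nrow(A))
  for (i in 1:20) {
    term <- term %*% B / i
    X <- X + term
  }
  for (i in seq_len(k)) X <- X %*% X
  X
}

# scaled rate matrix built from first principles
oracle_q <- function(family = "JC", freq = rep(0.25, 4), kappa = 2,
                     rates6 = rep(1, 6), k_states = NULL) {
  if (family == "MK") {
    s <- k_states
    Q <- matrix(1, s, s); diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    pi_ <- rep(1 / s, s)
  } else {
    ex <- switch(family, JC = rep(1, 6),
                 HKY = c(1, kappa, 1, 1, kappa, 1), GTR = rates6)
    Q <- matrix(0, 4, 4)
    idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (r in 1:6) {
      i <- idx[r, 1]; j <- idx[r, 2]
      Q[i, j] <- ex[r] * freq[j]; Q[j, i] <- ex[r] * freq[i]
    }
    diag(Q) <- -rowSums(Q)
    pi_ <- freq
  }
  Q / (-sum(pi_ * diag(Q)))
}

# log-likelihood by brute-force enumeration over interior states, with an
# arbitrary rate mixture (rates + weights)
enum_loglik <- function(phy, Q, freq, tip_states, rates = 1, weights = 1) {
  # tip_states: list (per taxon label) of allowed state indices
  s <- nrow(Q)
  ntip <- length(phy$tip.label)
  nn <- max(phy$edge)
  nint <- nn - ntip
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), nint)))
  total <- 0
  Ps <- lapply(seq_along(rates), function(ci) {
    lapply(seq_len(nrow(phy$edge)), function(e) {
      expm_naive(Q * phy$edge.length[e] * rates[ci])
    })
  })
  tipsets <- tip_states[phy$tip.label]
  Lsite <- 0
  for (ci in seq_along(rates)) {
    Lcat <- 0
    for (g in seq_len(nrow(grid))) {
      # sum over tip ambiguity sets too
      tip_grid <- expand.grid(tipsets)
      for (tg in seq_len(nrow(tip_grid))) {
        assign_ <- c(as.integer(tip_grid[tg, ]), grid[g, ])
        pr <- freq[assign_[ntip + 1]]
        for (e in seq_len(nrow(phy$edge))) {
          pr <- pr * Ps[[ci]][[e]][assign_[phy$edge[e, 1]],
                                   assign_[phy$edge[e, 2]]]
        }
        Lcat <- Lcat + pr
      }
    }
    Lsite <- Lsite + weights[ci] * Lcat
  }
  log(Lsite)
}

# site loglik of a whole DNA matrix by enumeration
enum_loglik_matrix <- function(phy, Q, freq, cm, rates = 1, weights = 1) {
  code <- list(A = 1L, C = 2L, G = 3L, T = 4L,
               R = c(1L, 3L), Y = c(2L, 4L), N = 1:4, "?" = 1:4, "-" = 1:4)
  sum(vapply(seq_len(ncol(cm$x)), function(j) {
    ts <- lapply(seq_along(cm$taxa), function(i) code[[cm$x[i, j]]])
    names(ts) <- cm$taxa
    enum_loglik(phy, Q, freq, ts, rates, weights)
  }, numeric(1)))
}

# minimum changes by brute force over all interior labelings
brute_fitch <- function(phy, char) {
  states <- sort(unique(char[!(char %in% c("?", "-", NA))]))
  s <- length(states)
  if (s <= 1) return(0L)
  ntip <- length(phy$tip.label)
  nint <- max(phy$edge) - ntip
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), nint)))
  tipidx <- lapply(phy$tip.label, function(tx) {
    if (char[tx] %in% c("?", "-") || is.na(char[tx])) seq_len(s)
    else match(char[tx], states)
  })
  best <- Inf
  tip_grid <- as.matrix(expand.grid(tipidx))
  for (g in seq_len(nrow(grid))) for (tg in seq_len(nrow(tip_grid))) {
    assign_ <- c(tip_grid[tg, ], grid[g, ])
    ch <- sum(assign_[phy$edge[, 1]] != assign_[phy$edge[, 2]])
    best <- min(best, ch)
  }
  as.integer(best)
}

# analytic expected number of changes of an Mk character given the tips
# (up-down algorithm + uniformization series), independent of the
# package's samplers
oracle_expected_changes <- function(phy, k, char, rate = 1) {
  s <- k
  Q <- oracle_q("MK", k_states = s) * rate
  freq <- rep(1 / s, s)
  ntip <- length(phy$tip.label)
  nn <- max(phy$edge)
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e) {
    expm_naive(Q * phy$edge.length[e])
  })
  tipvec <- function(tx) {
    v <- rep(0, s)
    if (char[tx] %in% c("?", "-") || is.na(char[tx])) v[] <- 1
    else v[as.integer(char[tx]) + 1] <- 1
    v
  }
  # lower partials by repeated passes until every node is resolved
  L <- matrix(1, nn, s)
  for (i in seq_len(ntip)) L[i, ] <- tipvec(phy$tip.label[i])
  known <- c(rep(TRUE, ntip), rep(FALSE, nn - ntip))
  while (!all(known)) {
    for (nd in which(!known)) {
      kids_e <- which(phy$edge[, 1] == nd)
      kids <- phy$edge[kids_e, 2]
      if (all(known[kids])) {
        v <- rep(1, s)
        for (ii in seq_along(kids_e)) {
          v <- v * as.numeric(Ps[[kids_e[ii]]] %*% L[kids[ii], ])
        }
        L[nd, ] <- v
        known[nd] <- TRUE
      }
    }
  }
  root <- ntip + 1
  # upper partials, edges processed parents-first (by node depth)
  U <- matrix(0, nn, s); U[root, ] <- freq
  depth <- rep(0L, nn)
  repeat {
    ch_any <- FALSE
    for (e in seq_len(nrow(phy$edge))) {
      pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      if (depth[ch] != depth[pa] + 1L) { depth[ch] <- depth[pa] + 1L; ch_any <- TRUE }
    }
    if (!ch_any) break
  }
  for (e in order(depth[phy$edge[, 2]])) {
    pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sibs <- setdiff(which(phy$edge[, 1] == pa), e)
    pr <- U[pa, ]
    for (se_ in sibs) pr <- pr * as.numeric(Ps[[se_]] %*% L[phy$edge[se_, 2], ])
    U[ch, ] <- as.numeric(t(Ps[[e]]) %*% pr)
  }
  # expected changes per edge
  R <- matrix(1 / (s - 1), s, s); diag(R) <- 0
  tot <- 0
  for (e in seq_len(nrow(phy$edge))) {
    pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    t <- phy$edge.length[e] * rate
    sibs <- setdiff(which(phy$edge[, 1] == pa), e)
    pr <- U[pa, ]
    for (se_ in sibs) pr <- pr * as.numeric(Ps[[se_]] %*% L[phy$edge[se_, 2], ])
    J <- matrix(0, s, s)
    for (a in seq_len(s)) for (b in seq_len(s)) {
      J[a, b] <- pr[a] * Ps[[e]][a, b] * L[ch, b]
    }
    J <- J / sum(J)
    En <- matrix(0, s, s); Pn <- matrix(0, s, s); Rp <- diag(s)
    for (n2 in 0:150) {
      w <- stats::dpois(n2, t)
      En <- En + n2 * w * Rp
      Pn <- Pn + w * Rp
      Rp <- Rp %*% R
    }
    Econd <- En / Pn
    Econd[Pn == 0] <- 0
    tot <- tot + sum(J * Econd)
  }
  tot
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Mantel-style correlation between two distance matrices (upper triangles)
mantel_cor <- function(D1, D2) {
  stats::cor(D1[upper.tri(D1)], D2[upper.tri(D2)])
}

# random binary character on taxa
rand_char <- function(taxa, s = 2) {
  stats::setNames(as.character(sample.int(s, length(taxa), TRUE) - 1L), taxa)
}
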