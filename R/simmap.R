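# conditional (lower) partial likelihoods per node for one character and a
# fixed relative rate; tipp dim (s, 1, ntip) aligned to phy$tip.label
node_partials <- function(phy, m, tipp, rate) {
  s <- length(m$states)
  ed <- postorder_edges(phy)
  eg <- q_eigen(m)
  nn <- ed$nnode_total
  part <- matrix(1, nn, s)
  for (i in seq_len(ed$ntip)) part[i, ] <- tipp[, 1, i]
  Ps <- vector("list", nrow(phy$edge))
  for (k in seq_along(ed$parent)) {
    t <- ed$elen[k] * rate
    P <- eg$U %*% diag(exp(eg$lambda * t), s) %*% eg$Uinv
    P[P < 0] <- 0
    e_orig <- which(phy$edge[, 1] == ed$parent[k] &
                    phy$edge[, 2] == ed$child[k])[1]
    Ps[[e_orig]] <- P
    part[ed$parent[k], ] <- part[ed$parent[k], ] *
      as.numeric(P %*% part[ed$child[k], ])
  }
  list(part = part, P = Ps, root = ed$root)
}

sample_one_history <- function(phy, m, np, rate) {
  s <- length(m$states)
  nn <- max(phy$edge)
  node_state <- integer(nn)
  w <- m$freq * np$part[np$root, ]
  node_state[np$root] <- sample.int(s, 1, prob = w)
  # preorder: parents before children
  for (e in rev(edge_postorder(phy))) {
    pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    P <- np$P[[e]]
    w <- P[node_state[pa], ] * np$part[ch, ]
    node_state[ch] <- if (sum(w) > 0) sample.int(s, 1, prob = w)
      else node_state[pa]
  }
  # endpoint-conditioned substitution history per branch by uniformization;
  # for the symmetric scaled Mk generator the uniformized jump chain has no
  # virtual (self) jumps, so every jump is a real state change
  R <- matrix(1 / (s - 1), s, s); diag(R) <- 0
  Rpow <- list(diag(s), R)
  dwell <- stats::setNames(numeric(s), m$states)
  ev <- list()
  n_changes <- 0L
  for (e in seq_len(nrow(phy$edge))) {
    a <- node_state[phy$edge[e, 1]]; b <- node_state[phy$edge[e, 2]]
    t <- phy$edge.length[e] * rate
    if (t <= 0) {
      dwell[a] <- dwell[a] + phy$edge.length[e]
      next
    }
    pab <- np$P[[e]][a, b]
    # sample the number of jumps
    u <- stats::runif(1)
    acc <- 0; n <- -1
    repeat {
      n <- n + 1
      if (n + 1 > length(Rpow)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
      pn <- exp(stats::dpois(n, t, log = TRUE)) * Rpow[[n + 1]][a, b] / pab
      acc <- acc + pn
      if (u <= acc || n > 10000) break
    }
    if (n == 0) {
      dwell[a] <- dwell[a] + phy$edge.length[e]
      next
    }
    times <- sort(stats::runif(n)) * phy$edge.length[e]
    st <- a
    prev_t <- 0
    for (k in seq_len(n)) {
      wjump <- R[st, ] * Rpow[[n - k + 1]][, b]
      nxt <- sample.int(s, 1, prob = wjump)
      dwell[st] <- dwell[st] + (times[k] - prev_t)
      ev[[length(ev) + 1L]] <- c(branch = e, time = times[k],
                                 from = st, to = nxt)
      st <- nxt; prev_t <- times[k]
      n_changes <- n_changes + 1L
    }
    dwell[st] <- dwell[st] + (phy$edge.length[e] - prev_t)
  }
  events <- if (length(ev)) {
    tibble::as_tibble(do.call(rbind, ev))
  } else {
    tibble::tibble(branch = integer(0), time = numeric(0),
                   from = integer(0), to = integer(0))
  }
  structure(list(events = events, dwell = dwell, n_changes = n_changes,
                 node_state = node_state,
                 tree_length = sum(phy$edge.length)),
            class = "character_history")
}

#' Sample stochastic character maps
#'
#' Draws explicit substitution histories of one discrete character on a
#' tree, conditional on the tip states and an Mk model: ancestral states
#' are sampled from their joint conditional distribution (pruning followed
#' by root-to-tip sampling), then each branch's history is simulated
#' conditional on its endpoint states by uniformization. Missing tips are
#' integrated out. With a gamma-rate model, each draw first picks a rate
#' category proportional to its marginal likelihood.
#'
#' @param phy tree with branch lengths.
#' @param m an [mk_model].
#' @param char named character vector of states (names = taxon labels;
#'   `?`/`-`/`NA` missing), or a [char_matrix] plus `col`.
#' @param n number of draws.
#' @param rate overall rate scaler applied to the branch lengths.
#' @param col character index when `char` is a matrix.
#' @return list of `character_history` objects (events per branch, per-state
#'   dwell times summing to the total tree length, change counts).
#' @export
sample_history <- function(phy, m, char, n = 100L, rate = 1, col = NULL) {
  if (inherits(char, "char_matrix")) {
    char <- stats::setNames(char$x[, col], char$taxa)
  }
  char <- char[phy$tip.label]
  if (all(char %in% c("?", "-", NA))) stop("character has no observed state")
  s <- m$k
  tipp <- array(0, dim = c(s, 1, length(phy$tip.label)))
  for (i in seq_along(char)) {
    if (char[i] %in% c("?", "-") || is.na(char[i])) tipp[, 1, i] <- 1
    else tipp[match(char[i], m$states), 1, i] <- 1
  }
  mx <- mixture_rates(m)
  nps <- lapply(mx$rates * rate, function(r) node_partials(phy, m, tipp, r))
  catlik <- vapply(seq_along(nps), function(c_) {
    mx$weights[c_] * sum(m$freq * nps[[c_]]$part[nps[[c_]]$root, ])
  }, numeric(1))
  if (sum(catlik) <= 0) stop("character has zero likelihood on this tree")
  lapply(seq_len(n), function(i) {
    c_ <- if (length(catlik) == 1) 1L else sample.int(length(catlik), 1,
                                                      prob = catlik)
    h <- sample_one_history(phy, m, nps[[c_]], mx$rates[c_] * rate)
    h$rate <- mx$rates[c_] * rate
    h
  })
}

#' Consistency and homoplasy index from sampled histories
#'
#' `CI = m / s` where `m` is the parsimony minimum for an unordered
#' character (observed distinct states minus one) and `s` the mean mapped
#' change count over the sampled histories; clipped at 1 when Monte-Carlo
#' noise pushes `s` below `m`. `HI = 1 - CI`. Constant characters have no
#' defined CI and return `NA`.
#'
#' @param histories list of `character_history` draws.
#' @param char the character the histories were sampled for (named vector).
#' @return named numeric vector `c(ci, hi, m, mean_changes)`.
#' @export
consistency_index <- function(histories, char) {
  obs <- char[!(char %in% c("?", "-")) & !is.na(char)]
  m <- length(unique(obs)) - 1L
  s <- mean(vapply(histories, function(h) h$n_changes, numeric(1)))
  if (m == 0) return(c(ci = NA_real_, hi = NA_real_, m = 0, mean_changes = s))
  ci <- min(1, m / s)
  c(ci = ci, hi = 1 - ci, m = m, mean_changes = s)
}

#' Mean per-state dwell-time fractions
#'
#' Proportion of total tree time spent in each state, averaged over sampled
#' histories; fractions sum to one.
#'
#' @param histories list of `character_history` draws.
#' @return named numeric vector of fractions.
#' @export
dwell_times <- function(histories) {
  stopifnot(length(histories) >= 1)
  fr <- rowMeans(vapply(histories, function(h) h$dwell / h$tree_length,
                        numeric(length(histories[[1]]$dwell))))
  fr / sum(fr)
}

#' Map all characters of a matrix and summarize homoplasy
#'
#' Runs [sample_history()] for every character of a morphological matrix on
#' a fixed tree (typically the molecular consensus with its branch
#' lengths). Each character gets an Mk model with its own observed state
#' count and a per-character rate scaler drawn from its posterior over a
#' log-spaced grid under a Gamma(`rate_shape`, `rate_shape`) prior (mean 1),
#' so fast and slow characters are mapped at appropriate rates.
#'
#' @param phy tree with branch lengths.
#' @param cm standard-alphabet [char_matrix] with region tags.
#' @param n_draws history draws per character.
#' @param gamma_alpha optional gamma shape for among-branch rate variation
#'   within a character's Mk model.
#' @param rate_shape shape of the rate-scaler prior.
#' @param rate_grid grid of candidate rate scalers.
#' @return a `homoplasy_report` tibble: per character the region tag,
#'   parsimony minimum `m`, mean mapped changes, `ci`, `hi`, and dwell-time
#'   fractions (list column), with the tree and draw count as attributes.
#' @export
map_characters <- function(phy, cm, n_draws = 100L, gamma_alpha = NULL,
                           rate_shape = 1,
                           rate_grid = exp(seq(log(0.05), log(30),
                                               length.out = 25))) {
  stopifnot(cm$alphabet == "standard")
  phy <- align_tree_matrix(phy, cm)
  rows <- vector("list", ncol(cm$x))
  for (j in seq_len(ncol(cm$x))) {
    char <- stats::setNames(cm$x[, j], cm$taxa)[phy$tip.label]
    obs <- unique(char[!(char %in% c("?", "-")) & !is.na(char)])
    k <- max(2L, length(obs))
    m <- mk_model(k = k, variable = FALSE, alpha = gamma_alpha)
    # map observed symbols onto 0..k-1 so sparse multistate codings work
    recode <- stats::setNames(m$states[seq_along(sort(obs))], sort(obs))
    charr <- ifelse(char %in% names(recode), recode[char], NA)
    names(charr) <- names(char)
    # posterior over the rate-scaler grid
    lls <- vapply(rate_grid, function(r) {
      ph2 <- phy; ph2$edge.length <- ph2$edge.length * r
      cmx <- char_matrix(matrix(ifelse(is.na(charr), "?", charr),
                                ncol = 1,
                                dimnames = list(names(charr), NULL)),
                         alphabet = "standard")
      loglik_mkv(ph2, m, cmx)
    }, numeric(1))
    lp <- lls + stats::dgamma(rate_grid, rate_shape, rate_shape, log = TRUE) +
      log(rate_grid) # log-uniform grid correction
    w <- exp(lp - max(lp)); w <- w / sum(w)
    rates <- sample(rate_grid, n_draws, replace = TRUE, prob = w)
    hist_all <- unlist(lapply(unique(rates), function(r) {
      sample_history(phy, m, charr, n = sum(rates == r), rate = r)
    }), recursive = FALSE)
    cix <- consistency_index(hist_all, charr)
    dw <- dwell_times(hist_all)
    names(dw) <- names(recode)[match(names(dw), recode)]
    rows[[j]] <- tibble::tibble(
      character = j, region = cm$region[j],
      n_states = length(obs), m = cix[["m"]],
      mean_changes = cix[["mean_changes"]],
      ci = cix[["ci"]], hi = cix[["hi"]],
      dwell = list(dw))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("homoplasy_report", class(out))
  attr(out, "n_draws") <- n_draws
  out
}

#' Share of homoplasy per gonopod region
#'
#' Aggregates a homoplasy report over anatomical regions, by default the
#' three gonopodal podomeres. Characters tagged `somatic`/`other` and
#' constant characters (undefined CI) are excluded. The default statistic
#' sums HI per region and standardizes by the total over the included
#' regions; `statistic = "ci"` sums CI instead (both aggregations are
#' reported in the literature).
#'
#' @param report a `homoplasy_report`.
#' @param regions regions to include.
#' @param statistic `"hi"` (default) or `"ci"`.
#' @return tibble of region, summed statistic, and `share` (sums to 1).
#' @export
region_homoplasy <- function(report,
                             regions = c("coxa", "prefemur", "tibiotarsus"),
                             statistic = c("hi", "ci")) {
  statistic <- match.arg(statistic)
  d <- report[report$region %in% regions & !is.na(report$ci), ]
  val <- if (statistic == "hi") d$hi else d$ci
  sums <- vapply(regions, function(r) sum(val[d$region == r]), numeric(1))
  if (any(sums == 0)) {
    warning("region(s) with no contributing characters: ",
            paste(regions[sums == 0], collapse = ", "))
  }
  tot <- sum(sums)
  tibble::tibble(region = regions, total = unname(sums),
                 share = if (tot > 0) unname(sums) / tot
                         else rep(0, length(sums)))
}

#' Fraction of characters above a homoplasy threshold
#'
#' @param report a `homoplasy_report`.
#' @param threshold HI threshold in (0, 1); default 0.5.
#' @param regions regions counted as gonopodal.
#' @return proportion of applicable (non-constant) gonopodal characters
#'   with `HI > threshold` (strict).
#' @export
homoplasy_summary <- function(report, threshold = 0.5,
                              regions = c("coxa", "prefemur", "tibiotarsus")) {
  stopifnot(threshold > 0, threshold < 1)
  d <- report[report$region %in% regions & !is.na(report$hi), ]
  if (!nrow(d)) return(NA_real_)
  mean(d$hi > threshold)
}
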