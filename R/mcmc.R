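#' Partition schemes
#'
#' Named, disjoint site-index sets covering an alignment, each with its own
#' substitution model; topology and (proportional) branch lengths are shared
#' across partitions during MCMC.
#'
#' @param sites named list of integer site-index vectors (1-based).
#' @param models a single model or list of models ([subst_model] /
#'   [mk_model] or spec strings), recycled across partitions.
#' @return an object of class `partition_scheme`.
#' @export
partition_scheme <- function(sites, models) {
  if (!is.list(sites)) sites <- list(all = sites)
  if (is.null(names(sites))) names(sites) <- paste0("part", seq_along(sites))
  all_sites <- unlist(sites)
  if (anyDuplicated(all_sites)) stop("partitions overlap")
  if (!is.list(models) || inherits(models, c("subst_model", "mk_model"))) {
    models <- list(models)
  }
  models <- lapply(models, function(m) if (is.character(m)) parse_model(m) else m)
  models <- rep(models, length.out = length(sites))
  structure(list(sites = sites, models = models), class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  for (i in seq_along(x$sites)) {
    cat(sprintf("%s: %d sites, %s\n", names(x$sites)[i], length(x$sites[[i]]),
                x$models[[i]]$family))
  }
  invisible(x)
}

# Read a simple INI/TOML-style partition file: lines "name = model : 1-600"
# (1-based inclusive ranges, comma-separated, matching the usual
# "COI (1-600)" convention).
#' Read a partition scheme from an INI/TOML-style text file
#'
#' Each non-comment line has the form `name = MODEL : ranges`, where ranges
#' are 1-based inclusive, e.g. `COI = GTR+I+G : 1-600` or
#' `noncoding = HKY+G : 601-749, 750-830`.
#' @param path file path.
#' @return a [partition_scheme].
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines)]
  sites <- list(); models <- list()
  for (ln in lines) {
    mch <- regmatches(ln, regexec("^([^=]+)=([^:]+):(.*)$", ln))[[1]]
    if (length(mch) != 4) stop("cannot parse partition line: ", ln)
    nm <- trimws(mch[2]); spec <- trimws(mch[3])
    rngs <- strsplit(trimws(mch[4]), ",")[[1]]
    idx <- unlist(lapply(rngs, function(r) {
      ab <- as.integer(strsplit(trimws(r), "-")[[1]])
      if (length(ab) == 1) ab else seq(ab[1], ab[2])
    }))
    sites[[nm]] <- idx; models[[nm]] <- spec
  }
  partition_scheme(sites, unname(models))
}

#' MCMC configuration
#'
#' @param ngen number of generations (one proposed move per chain each).
#' @param sample_every sampling interval in generations.
#' @param burnin fraction of samples discarded as burn-in.
#' @param nruns independent runs (cold chains compared by [sdsf()]).
#' @param nheated heated chains per run (Metropolis coupling).
#' @param heat_lambda heating increment; chain j runs at power
#'   `1 / (1 + heat_lambda * j)`.
#' @param bl_prior_rate rate of the iid exponential branch-length prior.
#' @param move_weights named weights for `topology`, `brlen`, `params`.
#' @param swap_every generations between chain-swap proposals.
#' @param seed master seed; per-run streams are derived deterministically.
#' @export
mcmc_config <- function(ngen = 20000L, sample_every = 100L, burnin = 0.25,
                        nruns = 2L, nheated = 1L, heat_lambda = 0.1,
                        bl_prior_rate = 10,
                        move_weights = c(topology = 3, brlen = 4, params = 2),
                        swap_every = 10L, seed = NULL) {
  stopifnot(ngen >= sample_every, burnin >= 0, burnin < 1)
  structure(list(ngen = as.integer(ngen), sample_every = as.integer(sample_every),
                 burnin = burnin, nruns = as.integer(nruns),
                 nheated = as.integer(nheated), heat_lambda = heat_lambda,
                 bl_prior_rate = bl_prior_rate, move_weights = move_weights,
                 swap_every = as.integer(swap_every), seed = seed),
            class = "mcmc_config")
}

# ---- internal engine ------------------------------------------------------

# Precomputed per-partition data: pattern-compressed tip partials + weights.
build_ctx <- function(cm, scheme, tip_order) {
  parts <- lapply(seq_along(scheme$sites), function(p) {
    cols <- scheme$sites[[p]]
    m <- scheme$models[[p]]
    states <- m$states
    sub <- cm$x[match(tip_order, cm$taxa), cols, drop = FALSE]
    pid <- apply(sub, 2, paste, collapse = "\r")
    upat <- !duplicated(pid)
    wt <- as.numeric(table(factor(pid, levels = pid[upat])))
    cmp <- cm; cmp$x <- sub[, upat, drop = FALSE]; cmp$taxa <- tip_order
    tipp <- tip_partial_array(cmp, states = states)
    const_tipp <- NULL
    if (inherits(m, "mk_model") && isTRUE(m$variable)) {
      cc <- matrix(rep(states, each = length(tip_order)),
                   nrow = length(tip_order))
      rownames(cc) <- tip_order
      ccm <- cm; ccm$x <- cc; ccm$taxa <- tip_order
      const_tipp <- tip_partial_array(ccm, states = states)
    }
    list(tipp = tipp, wt = wt, nchar = length(cols),
         const_tipp = const_tipp)
  })
  names(parts) <- names(scheme$sites)
  parts
}

partition_loglik <- function(phy, m, part, prate = 1) {
  if (prate != 1) phy$edge.length <- phy$edge.length * prate
  lnl <- pattern_loglik(phy, m, part$tipp)
  tot <- sum(part$wt * lnl)
  if (!is.null(part$const_tipp)) {
    lnc <- pattern_loglik(phy, m, part$const_tipp)
    pconst <- sum(exp(lnc))
    if (pconst >= 1) pconst <- 1 - 1e-12
    tot <- tot - sum(part$wt) * log1p(-pconst)
  }
  tot
}

state_loglik <- function(st, ctx) {
  tot <- 0
  for (p in seq_along(ctx)) {
    tot <- tot + partition_loglik(st$phy, st$models[[p]], ctx[[p]],
                                  st$prates[p])
  }
  tot
}

state_logprior <- function(st, cfg) {
  lp <- sum(stats::dexp(st$phy$edge.length, rate = cfg$bl_prior_rate,
                        log = TRUE))
  for (m in st$models) {
    if (!is.null(m$alpha)) lp <- lp + stats::dexp(m$alpha, 1, log = TRUE)
    if (inherits(m, "subst_model") && m$family == "HKY") {
      lp <- lp + stats::dlnorm(m$kappa, 1, 1.25, log = TRUE)
    }
    # Dirichlet(1,..) priors on frequencies / GTR rates / partition-rate
    # multipliers and the U(0,1) prior on pinv are flat: constant terms.
  }
  lp
}

# split keys for constraint checking, memoized per topology change
required_keys <- function(cs, taxa) {
  if (is.null(cs) || !length(cs$sets)) return(character(0))
  vapply(cs$sets, split_key, character(1), taxa = taxa)
}

topology_ok <- function(phy, req) {
  if (!length(req)) return(TRUE)
  all(req %in% bipartitions(phy, trivial = TRUE))
}

# one random NNI; returns NULL when the tree has no internal edge
propose_nni <- function(phy) {
  ntip <- length(phy$tip.label)
  int_e <- which(phy$edge[, 2] > ntip)
  if (!length(int_e)) return(NULL)
  e <- if (length(int_e) == 1) int_e else sample(int_e, 1)
  u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
  ech_v <- which(phy$edge[, 1] == v)
  ec <- if (length(ech_v) == 1) ech_v else sample(ech_v, 1)
  ech_u <- setdiff(which(phy$edge[, 1] == u), e)
  if (!length(ech_u)) return(NULL)
  ew <- if (length(ech_u) == 1) ech_u else sample(ech_u, 1)
  w <- phy$edge[ew, 2]; c_ <- phy$edge[ec, 2]
  phy$edge[ew, 2] <- c_
  phy$edge[ec, 2] <- w
  phy
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}
ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Dirichlet-centred simplex proposal; returns new simplex + log Hastings.
simplex_move <- function(x, conc = 300) {
  a_fwd <- pmax(conc * x, 1e-3)
  y <- rdirichlet1(a_fwd)
  y <- pmax(y, 1e-6); y <- y / sum(y)
  a_rev <- pmax(conc * y, 1e-3)
  list(x = y, lh = ddirichlet_log(x, a_rev) - ddirichlet_log(y, a_fwd))
}

scale_move <- function(x, lam = 1) {
  m <- exp(lam * (stats::runif(1) - 0.5))
  list(x = x * m, lh = log(m))
}

# One Metropolis sweep (a single proposed move) targeting
# prior * likelihood^lik_power, with overall chain heat `heat`.
mcmc_move <- function(st, ctx, cfg, req, lik_power = 1, heat = 1) {
  w <- cfg$move_weights
  kinds <- c("topology", "brlen", "params")
  kind <- sample(kinds, 1, prob = w[kinds])
  new <- st; lh <- 0
  if (kind == "topology") {
    ph <- propose_nni(st$phy)
    if (is.null(ph)) return(st)
    if (!topology_ok(ph, req)) {
      st$topo_rejected <- st$topo_rejected + 1L
      return(st) # hard constraint: zero prior mass
    }
    new$phy <- ph
  } else if (kind == "brlen") {
    e <- sample.int(nrow(st$phy$edge), 1)
    mv <- scale_move(st$phy$edge.length[e], lam = 2 * log(2))
    new$phy$edge.length[e] <- mv$x; lh <- mv$lh
  } else {
    # pick a partition, then a tunable parameter of its model
    p <- sample.int(length(st$models), 1)
    m <- st$models[[p]]
    opts <- c(if (inherits(m, "subst_model") && m$family != "JC") "freq",
              if (inherits(m, "subst_model") && m$family == "HKY") "kappa",
              if (inherits(m, "subst_model") && m$family == "GTR") "rates",
              if (!is.null(m$alpha)) "alpha",
              if (inherits(m, "subst_model") && m$pinv > 0) "pinv",
              if (length(st$models) > 1) "prate")
    if (!length(opts)) return(st)
    prm <- if (length(opts) == 1) opts else sample(opts, 1)
    if (prm == "freq") {
      mv <- simplex_move(m$freq); m$freq <- mv$x; lh <- mv$lh
    } else if (prm == "kappa") {
      mv <- scale_move(m$kappa, 0.5); m$kappa <- mv$x; lh <- mv$lh
    } else if (prm == "rates") {
      r <- m$rates / sum(m$rates)
      mv <- simplex_move(r); m$rates <- mv$x / mv$x[6]; lh <- mv$lh
    } else if (prm == "alpha") {
      mv <- scale_move(m$alpha, 0.7); m$alpha <- mv$x; lh <- mv$lh
    } else if (prm == "pinv") {
      x <- m$pinv + stats::runif(1, -0.1, 0.1)
      if (x < 0) x <- -x
      if (x >= 1) x <- 2 - x - 1e-9
      m$pinv <- x
    } else if (prm == "prate") {
      wts <- st$part_w
      z <- st$prates * wts
      mv <- simplex_move(z)
      new$prates <- mv$x / wts; lh <- mv$lh
    }
    new$models[[p]] <- m
  }
  new$lnL <- state_loglik(new, ctx)
  new$lnP <- state_logprior(new, cfg)
  logr <- heat * (lik_power * (new$lnL - st$lnL) + (new$lnP - st$lnP)) + lh
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    new$topo_rejected <- st$topo_rejected
    new
  } else st
}

init_state <- function(cm, scheme, constraints, cfg, start_tree = NULL) {
  taxa <- cm$taxa
  phy <- if (!is.null(start_tree)) start_tree
    else constrained_start_tree(taxa, constraints, bl_rate = cfg$bl_prior_rate)
  if (length(taxa) >= 4 && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  phy <- ape::reorder.phylo(phy, "postorder")
  part_n <- lengths(scheme$sites)
  st <- list(phy = phy, models = scheme$models,
             prates = rep(1, length(scheme$sites)),
             part_w = part_n / sum(part_n),
             topo_rejected = 0L)
  st
}

flatten_params <- function(st) {
  out <- list()
  for (p in seq_along(st$models)) {
    m <- st$models[[p]]
    if (inherits(m, "subst_model") && m$family == "HKY") {
      out[[paste0("kappa.", p)]] <- m$kappa
    }
    if (!is.null(m$alpha)) out[[paste0("alpha.", p)]] <- m$alpha
    if (inherits(m, "subst_model") && m$pinv > 0) {
      out[[paste0("pinv.", p)]] <- m$pinv
    }
    if (length(st$models) > 1) out[[paste0("rate.", p)]] <- st$prates[p]
  }
  out[["tree_length"]] <- sum(st$phy$edge.length)
  out
}

normalize_tree <- function(phy) {
  ape::read.tree(text = ape::write.tree(phy))
}

#' Constrained Bayesian MCMC over trees and model parameters
#'
#' Metropolis-coupled MCMC sampling topologies (NNI moves), branch lengths
#' (multiplier moves) and substitution-model parameters under the priors:
#' branch lengths iid Exponential(`bl_prior_rate`), uniform topology over
#' constraint-satisfying trees, Dirichlet(1,...) frequencies and GTR rates,
#' log-normal(1, 1.25) kappa, Exponential(1) gamma shape, Uniform(0,1)
#' invariant proportion. Monophyly constraints are hard: any proposal whose
#' topology violates them is rejected outright.
#'
#' @param cm a [char_matrix] (nucleotide or standard).
#' @param scheme a [partition_scheme]; defaults to one partition under
#'   `HKY+G` (nucleotide) or `Mkv` (standard).
#' @param constraints optional [constraint_set].
#' @param config an [mcmc_config].
#' @param start_tree optional starting tree (must satisfy the constraints).
#' @return a `posterior_sample`: post-burn-in trees and traces from the
#'   cold chains of all runs.
#' @export
run_mcmc <- function(cm, scheme = NULL, constraints = NULL,
                     config = mcmc_config(), start_tree = NULL) {
  if (is.null(scheme)) scheme <- default_scheme(cm)
  check_scheme(cm, scheme)
  if (!is.null(config$seed)) set.seed(config$seed)
  taxa <- cm$taxa
  req <- required_keys(constraints, taxa)
  if (!is.null(start_tree) && length(req) &&
      !topology_ok(ape::reorder.phylo(start_tree, "postorder"), req)) {
    stop("start tree violates the constraint set")
  }
  runs <- vector("list", config$nruns)
  nchain <- 1L + config$nheated
  for (r in seq_len(config$nruns)) {
    # all chains of a run start from the same feasible state (they share
    # one tip ordering so the cached tip partials apply to every chain)
    st0 <- init_state(cm, scheme, constraints, config, start_tree)
    ctx <- build_ctx(cm, scheme, st0$phy$tip.label)
    st0$lnL <- state_loglik(st0, ctx)
    st0$lnP <- state_logprior(st0, config)
    chains <- rep(list(st0), nchain)
    heats <- 1 / (1 + config$heat_lambda * (seq_len(nchain) - 1))
    trees <- list(); rows <- list(); swap_acc <- 0L; swap_try <- 0L
    for (g in seq_len(config$ngen)) {
      for (j in seq_len(nchain)) {
        chains[[j]] <- mcmc_move(chains[[j]], ctx, config, req,
                                 lik_power = 1, heat = heats[j])
      }
      if (nchain > 1 && g %% config$swap_every == 0) {
        j <- sample.int(nchain - 1, 1)
        a <- chains[[j]]; b <- chains[[j + 1]]
        logr <- (heats[j] - heats[j + 1]) * ((b$lnL + b$lnP) - (a$lnL + a$lnP))
        swap_try <- swap_try + 1L
        if (log(stats::runif(1)) < logr) {
          chains[[j]] <- b; chains[[j + 1]] <- a
          swap_acc <- swap_acc + 1L
        }
      }
      if (g %% config$sample_every == 0) {
        cold <- chains[[1]]
        trees[[length(trees) + 1L]] <- normalize_tree(cold$phy)
        rows[[length(rows) + 1L]] <- c(list(generation = g, lnL = cold$lnL,
                                            lnPrior = cold$lnP),
                                       flatten_params(cold))
      }
    }
    nsamp <- length(trees)
    keep <- seq_len(nsamp) > floor(config$burnin * nsamp)
    tr <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    runs[[r]] <- list(trees = trees[keep], trace = tr[keep, ],
                      swap_accept = swap_acc, swap_try = swap_try,
                      topo_rejected = chains[[1]]$topo_rejected)
  }
  structure(list(runs = runs, taxa = taxa, constraints = constraints,
                 scheme = scheme, config = config),
            class = "posterior_sample")
}

default_scheme <- function(cm) {
  if (cm$alphabet == "dna") {
    partition_scheme(list(all = seq_len(ncol(cm$x))), subst_model("HKY", alpha = 1))
  } else {
    k <- max(2L, length(state_labels(cm)))
    partition_scheme(list(all = seq_len(ncol(cm$x))), mk_model(k = k))
  }
}

check_scheme <- function(cm, scheme) {
  all_sites <- as.integer(sort(unname(unlist(scheme$sites))))
  if (!identical(all_sites, seq_len(ncol(cm$x)))) {
    stop("partition scheme must cover all sites exactly once")
  }
  invisible(TRUE)
}

#' @export
print.posterior_sample <- function(x, ...) {
  n <- sum(vapply(x$runs, function(r) length(r$trees), integer(1)))
  cat(sprintf("<posterior_sample> %d runs, %d post-burn-in samples, %d taxa\n",
              length(x$runs), n, length(x$taxa)))
  invisible(x)
}

#' Post-burn-in sampled trees of a posterior sample
#' @param ps a `posterior_sample`.
#' @param runs which runs to pool (default all).
#' @return a `multiPhylo` list.
#' @export
posterior_trees <- function(ps, runs = seq_along(ps$runs)) {
  out <- do.call(c, lapply(ps$runs[runs], function(r) r$trees))
  class(out) <- "multiPhylo"
  out
}
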