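test_that("a fully constrained run degenerates to one topology and samples lengths", {
  set.seed(41)
  tt <- simulate_yule_tree(6, height = 0.6)
  sq <- simulate_sequences(tt, c(a = 200), list(subst_model("JC")))
  cs <- constraints_from_tree(tt, "fixed")
  ps <- run_mcmc(sq, partition_scheme(list(a = 1:200), subst_model("JC")),
                 cs, mcmc_config(ngen = 1500, sample_every = 25, nruns = 1,
                                 seed = 4))
  trees <- posterior_trees(ps)
  key <- sort(bipartitions(ape::unroot(tt)))
  for (tr in trees) expect_equal(sort(bipartitions(tr)), key)
  # branch lengths still move
  expect_gt(sd(tidy(ps)$tree_length), 0)
})

test_that("every sampled tree of a constrained run satisfies the constraints", {
  set.seed(43)
  tt <- simulate_yule_tree(7, height = 0.8)
  sq <- simulate_sequences(tt, c(a = 150), list(subst_model("JC")))
  cs <- constraint_set(list(c("t1", "t2"), c("t4", "t5", "t6")), "partial",
                       taxa = tt$tip.label)
  ps <- run_mcmc(sq, constraints = cs,
                 config = mcmc_config(ngen = 2000, sample_every = 25,
                                      nruns = 2, seed = 9))
  ok <- vapply(posterior_trees(ps), satisfies, logical(1), cs = cs)
  expect_true(all(ok))
})

test_that("MCMC recovers the generating topology on simulated data", {
  set.seed(45)
  hits <- 0L
  nseed <- 5L
  for (i in seq_len(nseed)) {
    tt <- simulate_yule_tree(6, height = 0.5)
    sq <- simulate_sequences(tt, c(a = 500), list(subst_model("JC")))
    ps <- run_mcmc(sq, partition_scheme(list(a = 1:500), subst_model("JC")),
                   config = mcmc_config(ngen = 12000, sample_every = 60,
                                        nruns = 1, seed = i))
    cons <- consensus_tree(ps)
    hits <- hits + setequal(bipartitions(cons), bipartitions(ape::unroot(tt)))
  }
  expect_gte(hits, nseed - 1L)
})

test_that("two-taxon branch-length posterior matches numeric quadrature", {
  # one free branch: data = k matching sites out of n under JC at total
  # length t, prior Gamma(2, 10) on the two-edge sum
  set.seed(47)
  t_true <- 0.2
  tr <- read_tree(text = sprintf("(A:%g,B:%g);", t_true / 2, t_true / 2))
  n <- 300
  m <- subst_model("JC")
  sq <- simulate_sequences(tr, c(a = n), list(m))
  ps <- run_mcmc(sq, partition_scheme(list(a = 1:n), m),
                 config = mcmc_config(ngen = 20000, sample_every = 20,
                                      nruns = 1, nheated = 0, seed = 2,
                                      move_weights = c(topology = 0,
                                                       brlen = 1, params = 0)))
  tl <- tidy(ps)$tree_length
  k <- sum(sq$x[1, ] == sq$x[2, ])
  lik <- function(t) {
    ps_ <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    pd <- (1 - ps_) / 3
    (ps_ / 4)^k * (3 * pd / 4)^(n - k)
  }
  post <- function(t) lik(t) * dgamma(t, shape = 2, rate = 10)
  z <- integrate(post, 0, 10)$value
  pm <- integrate(function(t) t * post(t), 0, 10)$value / z
  pv <- integrate(function(t) t^2 * post(t), 0, 10)$value / z - pm^2
  mc_se <- sd(tl) / sqrt(max(20, length(tl) / 10)) # generous ESS guess
  expect_lt(abs(mean(tl) - pm), 3 * sqrt(pv / 20) + 3 * mc_se)
})

test_that("SDSF matches hand calculations", {
  t1 <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- suppressWarnings(read_tree(text = "((A,C),(B,D));"))
  t2$edge.length <- rep(1, nrow(t2$edge))
  expect_equal(as.numeric(sdsf(list(list(t1, t1), list(t1, t1)))), 0)
  # split AB|CD at frequency 1 in run 1, 0 in run 2: population SD = 0.5
  s <- sdsf(list(list(t1, t1), list(t2, t2)))
  expect_equal(as.numeric(s), 0.5)
  # hand-built 3-run example: frequencies 1, 0.5, 0 for CD|AB-type split
  r3 <- sdsf(list(list(t1, t1), list(t1, t2), list(t2, t2)))
  per <- attr(r3, "per_split")
  f_cd <- c(1, 0.5, 0)
  sd_cd <- sqrt(mean((f_cd - mean(f_cd))^2))
  expect_true(any(abs(per$sd - sd_cd) < 1e-12))
  expect_error(sdsf(list(list(t1))), "two runs")
})

test_that("all-compatible consensus follows greedy split frequency", {
  t_ab <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t_ac <- suppressWarnings(read_tree(text = "((A,C),(B,D));"))
  t_ac$edge.length <- rep(1, nrow(t_ac$edge))
  # identical trees: consensus is that tree with pp = 1
  cons <- consensus_tree(list(t_ab, t_ab, t_ab))
  expect_setequal(bipartitions(cons), bipartitions(t_ab))
  pp <- suppressWarnings(as.numeric(cons$node.label))
  expect_true(all(pp[!is.na(pp)] == 1))
  # 60/40 conflict keeps the majority split only
  cons2 <- consensus_tree(list(t_ab, t_ab, t_ab, t_ac, t_ac))
  expect_equal(bipartitions(cons2), "C,D")
  lab <- suppressWarnings(as.numeric(cons2$node.label))
  expect_true(any(abs(lab[!is.na(lab)] - 0.6) < 1e-9))

  # agreement with an independent greedy implementation on random samples
  set.seed(51)
  for (rep in 1:10) {
    sample_trees <- lapply(1:12, function(i) {
      ape::unroot(simulate_yule_tree(6, height = 1))
    })
    cons <- consensus_tree(sample_trees)
    # oracle: greedy over ape::prop.part frequencies
    pp <- ape::prop.part(sample_trees)
    labs <- attr(pp, "labels")
    freq <- attr(pp, "number") / length(sample_trees)
    keys <- vapply(pp, function(s) {
      phylotopo:::split_key(labs[s], labs)
    }, character(1))
    nontrivial <- vapply(strsplit(keys, ","), function(s) {
      length(s) >= 2 && length(s) <= 4
    }, logical(1))
    keep <- nchar(keys) > 0 & nontrivial
    # complementary clades normalize to the same split: merge their counts
    agg <- tapply(freq[keep], keys[keep], sum)
    ord <- order(-agg, names(agg))
    cand <- names(agg)[ord]
    sides <- strsplit(cand, ",")
    chosen <- list()
    for (i in seq_along(sides)) {
      ok <- all(vapply(chosen, function(c_) {
        a <- sides[[i]]; b <- c_
        ia <- length(intersect(a, b))
        ia == 0 || ia == length(a) || ia == length(b) ||
          length(union(a, b)) == 6
      }, logical(1)))
      if (ok) chosen[[length(chosen) + 1]] <- sides[[i]]
    }
    oracle_keys <- sort(vapply(chosen, paste, character(1), collapse = ","))
    expect_setequal(bipartitions(cons), oracle_keys)
  }
})
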