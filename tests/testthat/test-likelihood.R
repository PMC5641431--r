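test_that("pruning log-likelihood matches closed forms", {
  m <- subst_model("JC")
  # one taxon, one site
  one <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                        edge.length = 0.3, tip.label = "A", Nnode = 1L),
                   class = "phylo")
  cm1 <- char_matrix(matrix("A", 1, 1, dimnames = list("A", NULL)))
  expect_equal(loglik(one, m, cm1), log(1 / 4), tolerance = 1e-12)
  # two identical bases at distance t
  t <- 0.37
  tr <- read_tree(text = sprintf("(A:%g,B:%g);", t / 2, t / 2))
  cm <- char_matrix(matrix("A", 2, 1, dimnames = list(c("A", "B"), NULL)))
  expect_equal(loglik(tr, m, cm),
               log(1 / 4 * (1 / 4 + 3 / 4 * exp(-4 * t / 3))),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on small trees (JC, GTR+G, +I)", {
  set.seed(101)
  for (n in c(4, 5, 6)) {
    tr <- simulate_yule_tree(n, height = 0.8)
    g <- subst_model("GTR", freq = c(0.3, 0.2, 0.25, 0.25),
                     rates = c(1.5, 4, 0.8, 1.2, 5, 1), alpha = 0.6, ncat = 3)
    sq <- simulate_sequences(tr, c(a = 12), list(g))
    mx <- phylotopo:::mixture_rates(g)
    Qo <- oracle_q("GTR", freq = g$freq, rates6 = g$rates)
    expect_equal(loglik(tr, g, sq),
                 enum_loglik_matrix(tr, Qo, g$freq, sq, mx$rates, mx$weights),
                 tolerance = 1e-8)
  }
  # invariant-sites mixture and ambiguity codes
  tr <- read_tree(text = "((A:0.2,B:0.3):0.1,(C:0.4,D:0.1):0.2);")
  hi <- subst_model("HKY", freq = c(0.35, 0.15, 0.2, 0.3), kappa = 3,
                    pinv = 0.3, alpha = 0.9, ncat = 2)
  x <- matrix(c("A", "R", "-", "T",
                "C", "C", "T", "?"), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  cm <- char_matrix(x)
  mx <- phylotopo:::mixture_rates(hi)
  Qo <- oracle_q("HKY", freq = hi$freq, kappa = hi$kappa)
  expect_equal(loglik(tr, hi, cm),
               enum_loglik_matrix(tr, Qo, hi$freq, cm, mx$rates, mx$weights),
               tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting for reversible models", {
  set.seed(55)
  tr <- simulate_yule_tree(6, height = 0.7)
  g <- subst_model("GTR", freq = c(0.3, 0.2, 0.25, 0.25),
                   rates = c(1.5, 4, 0.8, 1.2, 5, 1), alpha = 0.6)
  sq <- simulate_sequences(tr, c(a = 50), list(g))
  base <- loglik(ape::unroot(tr), g, sq)
  for (og in c("t1", "t3", "t5")) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = FALSE)
    expect_equal(loglik(rr, g, sq), base, tolerance = 1e-9)
  }
})

test_that("Mkv conditioning behaves like a probability correction", {
  set.seed(9)
  tr <- simulate_yule_tree(5, height = 0.6)
  x <- matrix(as.character(rbinom(5 * 8, 1, 0.5)), 5, 8,
              dimnames = list(tr$tip.label, NULL))
  # force variability
  x[1, ] <- "0"; x[2, ] <- "1"
  cm <- char_matrix(x, "standard")
  mkv <- mk_model(2, variable = TRUE)
  mk <- mk_model(2, variable = FALSE)
  l_v <- loglik_mkv(tr, mkv, cm)
  l_p <- loglik_mkv(tr, mk, cm)
  # conditioning on the variability event raises the log-likelihood
  expect_gt(as.numeric(l_v), as.numeric(l_p))
  # correction denominator within (0,1): per-character lift is the same
  lift <- attr(l_v, "per_character") - attr(l_p, "per_character")
  expect_true(all(lift > 0))
  expect_true(sd(lift) < 1e-10)
  pconst <- 1 - exp(-lift[1])
  expect_gt(pconst, 0); expect_lt(pconst, 1)

  # brute-force conditional probability for a 2-taxon binary character
  t2 <- read_tree(text = "(A:0.25,B:0.25);")
  cm2 <- char_matrix(matrix(c("0", "1"), 2, 1,
                            dimnames = list(c("A", "B"), NULL)), "standard")
  Qm <- oracle_q("MK", k_states = 2)
  P <- expm_naive(Qm * 0.5)
  p01 <- 0.5 * P[1, 2]; p10 <- 0.5 * P[2, 1]
  pconst2 <- 0.5 * P[1, 1] + 0.5 * P[2, 2]
  expect_equal(as.numeric(loglik_mkv(t2, mkv, cm2)),
               log(p01 / (1 - pconst2)), tolerance = 1e-9)

  # as branch lengths -> 0 with variable data, the likelihood vanishes
  tr0 <- tr; tr0$edge.length <- rep(1e-8, nrow(tr0$edge))
  expect_lt(as.numeric(loglik_mkv(tr0, mk, cm)), -100)

  # observed state count above the model's r errors
  cm3 <- char_matrix(matrix(c("0", "1", "2", "0", "1"), 5, 1,
                            dimnames = list(tr$tip.label, NULL)), "standard")
  expect_error(loglik_mkv(tr, mkv, cm3), "states beyond")
})

test_that("Fitch length equals brute force, handles polytomies and missing data", {
  tr <- read_tree(text = "((A:0,B:0):1,(C:0,D:0):1);")
  expect_equal(fitch_length(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_equal(fitch_length(tr, c(A = "0", B = "0", C = "0", D = "0")), 0L)
  poly <- suppressWarnings(read_tree(text = "((A,B,C),(D,E));"))
  expect_equal(fitch_length(poly, c(A = "0", B = "1", C = "2", D = "0",
                                    E = "0")), 2L)
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    tr <- simulate_yule_tree(n, height = 1)
    if (runif(1) < 0.3) tr <- ape::di2multi(tr, tol = 0.2)
    ch <- rand_char(tr$tip.label, s = sample(2:3, 1))
    if (runif(1) < 0.3) ch[sample(seq_along(ch), 1)] <- "?"
    expect_equal(fitch_length(tr, ch), brute_fitch(tr, ch))
  }
})
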