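test_that("sampled histories respect parity and degenerate limits", {
  m <- mk_model(2, variable = FALSE)
  tr2 <- read_tree(text = "(A:0.5,B:0.5);")
  set.seed(71)
  hs <- sample_history(tr2, m, c(A = "0", B = "1"), n = 200)
  expect_true(all(vapply(hs, function(h) h$n_changes %% 2 == 1, logical(1))))
  # constant character at a tiny rate: no events
  hs0 <- sample_history(tr2, m, c(A = "0", B = "0"), n = 100, rate = 1e-8)
  expect_true(all(vapply(hs0, function(h) h$n_changes, numeric(1)) == 0))
  # dwell times sum to the tree length (fractions to 1)
  expect_equal(sum(dwell_times(hs)), 1, tolerance = 1e-9)
  for (h in hs) expect_equal(sum(h$dwell), h$tree_length, tolerance = 1e-9)
  expect_error(sample_history(tr2, m, c(A = "?", B = "?")), "no observed")
})

test_that("mean mapped changes match the analytic expectation on 4-taxon fixtures", {
  set.seed(73)
  fixtures <- list(
    list(tree = "((A:0.4,B:0.4):0.3,(C:0.3,D:0.5):0.2);",
         char = c(A = "0", B = "1", C = "0", D = "1"), k = 2),
    list(tree = "((A:0.2,B:0.6):0.1,(C:0.3,D:0.3):0.4);",
         char = c(A = "0", B = "0", C = "1", D = "1"), k = 2),
    list(tree = "((A:0.3,B:0.3):0.2,(C:0.2,D:0.4):0.3);",
         char = c(A = "0", B = "1", C = "2", D = "?"), k = 3))
  for (fx in fixtures) {
    tr <- read_tree(text = fx$tree)
    m <- mk_model(fx$k, variable = FALSE)
    hs <- sample_history(tr, m, fx$char, n = 4000)
    counts <- vapply(hs, function(h) h$n_changes, numeric(1))
    se <- sd(counts) / sqrt(length(counts))
    truth <- oracle_expected_changes(tr, fx$k, fx$char)
    expect_lt(abs(mean(counts) - truth), 3 * se + 1e-3)
  }
})

test_that("node-state sampling matches pruning marginals (chi-squared)", {
  set.seed(75)
  tr <- read_tree(text = "((A:0.4,B:0.4):0.3,(C:0.3,D:0.5):0.2);")
  m <- mk_model(2, variable = FALSE)
  char <- c(A = "0", B = "1", C = "0", D = "1")
  hs <- sample_history(tr, m, char, n = 10000)
  root <- 5L
  draws <- vapply(hs, function(h) h$node_state[root], integer(1))
  # marginal root posterior from the oracle's pruning partials
  Q <- oracle_q("MK", k_states = 2)
  P <- lapply(seq_len(nrow(tr$edge)), function(e) {
    expm_naive(Q * tr$edge.length[e])
  })
  tipv <- function(tx) if (char[tx] == "0") c(1, 0) else c(0, 1)
  L6 <- (P[[which(tr$edge[, 2] == 1)]] %*% tipv("A")) *
        (P[[which(tr$edge[, 2] == 2)]] %*% tipv("B"))
  L7 <- (P[[which(tr$edge[, 2] == 3)]] %*% tipv("C")) *
        (P[[which(tr$edge[, 2] == 4)]] %*% tipv("D"))
  e6 <- which(tr$edge[, 2] == 6); e7 <- which(tr$edge[, 2] == 7)
  Lroot <- (P[[e6]] %*% L6) * (P[[e7]] %*% L7)
  prob <- (0.5 * Lroot) / sum(0.5 * Lroot)
  obs <- tabulate(draws, 2)
  chi <- sum((obs - 10000 * prob)^2 / (10000 * prob))
  expect_lt(chi, qchisq(0.999, df = 1))
})

test_that("mean mapped changes are at least the Fitch minimum", {
  set.seed(77)
  for (i in 1:6) {
    tr <- simulate_yule_tree(6, height = 1)
    m <- mk_model(2, variable = FALSE)
    ch <- rand_char(tr$tip.label)
    if (length(unique(ch)) < 2) next
    hs <- sample_history(tr, m, ch, n = 400)
    counts <- vapply(hs, function(h) h$n_changes, numeric(1))
    se <- sd(counts) / sqrt(length(counts))
    expect_gte(mean(counts), fitch_length(tr, ch) - 3 * se)
  }
})

test_that("dwell fractions approach stationarity on long trees", {
  set.seed(79)
  tr <- read_tree(text = "(A:60,B:60);")
  m <- mk_model(2, variable = FALSE)
  hs <- sample_history(tr, m, c(A = "0", B = "1"), n = 400)
  dw <- dwell_times(hs)
  per <- vapply(hs, function(h) h$dwell[1] / h$tree_length, numeric(1))
  se <- sd(per) / sqrt(length(per))
  expect_lt(abs(dw[[1]] - 0.5), 3 * se)
})

test_that("consistency index and the homoplasy threshold summary count correctly", {
  m <- mk_model(2, variable = FALSE)
  tr <- read_tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  set.seed(81)
  # one clean synapomorphy at a low rate: CI ~ 1
  hs <- sample_history(tr, m, c(A = "1", B = "1", C = "0", D = "0"),
                       n = 400, rate = 0.05)
  ci <- consistency_index(hs, c(A = "1", B = "1", C = "0", D = "0"))
  expect_equal(ci[["ci"]], 1, tolerance = 0.05)
  expect_equal(ci[["hi"]], 0, tolerance = 0.05)
  # convergent binary character on two separated tips: ~2 changes, CI ~ 0.5
  hs2 <- sample_history(tr, m, c(A = "1", B = "0", C = "1", D = "0"),
                        n = 600, rate = 0.05)
  ci2 <- consistency_index(hs2, c(A = "1", B = "0", C = "1", D = "0"))
  expect_equal(ci2[["ci"]], 0.5, tolerance = 0.06)
  # constant character: not applicable
  hs3 <- sample_history(tr, m, c(A = "0", B = "0", C = "0", D = "0"), n = 10)
  ci3 <- consistency_index(hs3, c(A = "0", B = "0", C = "0", D = "0"))
  expect_true(is.na(ci3[["ci"]]))

  rep_ <- tibble::tibble(
    character = 1:5,
    region = c("coxa", "tibiotarsus", "tibiotarsus", "prefemur", "somatic"),
    hi = c(0.4, 0.6, 0.7, 0.9, 0.99), ci = 1 - c(0.4, 0.6, 0.7, 0.9, 0.99))
  class(rep_) <- c("homoplasy_report", class(rep_))
  expect_equal(homoplasy_summary(rep_, 0.5), 0.75) # somatic excluded
  expect_equal(homoplasy_summary(dplyr::mutate(rep_, hi = 0), 0.5), 0)
})

test_that("region aggregation standardizes shares over gonopod regions", {
  rep_ <- tibble::tibble(
    character = 1:6,
    region = c("coxa", "coxa", "prefemur", "tibiotarsus", "somatic",
               "tibiotarsus"),
    hi = c(0.2, 0.3, 0.5, 0.8, 1, 0.7), ci = 0.5)
  class(rep_) <- c("homoplasy_report", class(rep_))
  sh <- region_homoplasy(rep_)
  expect_equal(sum(sh$share), 1)
  expect_equal(sh$share[sh$region == "tibiotarsus"], 1.5 / 2.5)
  # all characters in one region
  one <- dplyr::mutate(rep_, region = "coxa")
  class(one) <- class(rep_)
  expect_warning(sh1 <- region_homoplasy(one), "no contributing")
  expect_equal(sh1$share[sh1$region == "coxa"], 1)
  # equal sums give equal thirds
  eq <- tibble::tibble(character = 1:3,
                       region = c("coxa", "prefemur", "tibiotarsus"),
                       hi = 0.5, ci = 0.5)
  class(eq) <- c("homoplasy_report", class(eq))
  expect_equal(region_homoplasy(eq)$share, rep(1 / 3, 3))
})

test_that("matrix-level mapping produces a coherent homoplasy report", {
  set.seed(83)
  tt <- simulate_yule_tree(8, height = 1)
  mm <- simulate_morphology(tt, n_char = 10, rho = 0.3)
  rep_ <- map_characters(tt, mm, n_draws = 30)
  expect_s3_class(rep_, "homoplasy_report")
  expect_equal(nrow(rep_), 10)
  ok <- !is.na(rep_$ci)
  expect_true(all(rep_$ci[ok] > 0 & rep_$ci[ok] <= 1))
  expect_equal(rep_$hi[ok], 1 - rep_$ci[ok])
  for (dw in rep_$dwell) expect_equal(sum(dw), 1, tolerance = 1e-9)
  expect_true(all(rep_$mean_changes[ok] >= rep_$m[ok] - 1e-9 |
                    rep_$ci[ok] == 1))
})
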