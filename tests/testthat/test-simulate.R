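test_that("Yule trees are ultrametric with the requested size and height", {
  set.seed(101)
  for (n in c(3, 5, 12)) {
    tr <- simulate_yule_tree(n, height = 1)
    expect_length(tr$tip.label, n)
    depths <- ape::node.depth.edgelength(tr)[1:n]
    expect_equal(depths, rep(1, n), tolerance = 1e-9)
  }
  tr3 <- simulate_yule_tree(3, height = 1)
  expect_equal(tr3$Nnode, 2) # root join plus exactly one further split
})

test_that("lineage counts through time match the pure-birth expectation", {
  set.seed(103)
  lam <- 1.2; t0 <- 0.5
  nrep <- 1000
  counts <- vapply(seq_len(nrep), function(i) {
    tr <- simulate_yule_tree(12, birth_rate = lam, height = NULL)
    bt <- sort(max(ape::node.depth.edgelength(tr)) -
                 ape::branching.times(tr)) # times of splits from the root
    2 + sum(bt[-1] <= t0 & bt[-1] > 0) # lineages at t0 (starts with 2)
  }, numeric(1))
  counts <- pmin(counts, 12)
  expectation <- 2 * exp(lam * t0)
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expectation), 3 * se + 0.05)
})

test_that("sequence simulation honours the model: limits, frequencies, distances", {
  set.seed(105)
  tr <- simulate_yule_tree(5, height = 1)
  tr0 <- tr; tr0$edge.length <- rep(0, nrow(tr0$edge))
  sq0 <- simulate_sequences(tr0, c(a = 100), list(subst_model("JC")))
  for (i in 2:5) expect_identical(sq0$x[i, ], sq0$x[1, ])

  g <- subst_model("GTR", freq = c(0.4, 0.3, 0.2, 0.1),
                   rates = c(1, 2, 1, 1, 2, 1))
  sq <- simulate_sequences(tr, c(a = 10000), list(g))
  emp <- prop.table(table(factor(sq$x, levels = c("A", "C", "G", "T"))))
  for (i in 1:4) {
    se <- sqrt(g$freq[i] * (1 - g$freq[i]) / (5 * 10000))
    expect_lt(abs(emp[i] - g$freq[i]), 4 * se + 0.01)
  }

  t_ <- 0.3
  tr2 <- read_tree(text = sprintf("(A:%g,B:%g);", t_ / 2, t_ / 2))
  sq2 <- simulate_sequences(tr2, c(a = 10000), list(subst_model("JC")))
  p <- as.numeric(p_distance(paste(sq2$x[1, ], collapse = ""),
                             paste(sq2$x[2, ], collapse = "")))
  expct <- 3 / 4 * (1 - exp(-4 * t_ / 3))
  expect_lt(abs(p - expct), 3 * sqrt(expct * (1 - expct) / 10000))
})

test_that("morphology generator: variable coding, region tags, convergence flags", {
  set.seed(107)
  tt <- simulate_yule_tree(10, height = 1)
  mm <- simulate_morphology(tt, n_char = 30, rho = 0.4)
  expect_equal(dim(mm), c(10L, 30L))
  # no constant characters (variable coding contract)
  nstates <- apply(mm$x, 2, function(col) length(unique(col)))
  expect_true(all(nstates >= 2))
  expect_true(all(mm$region %in% c("coxa", "prefemur", "tibiotarsus")))
  expect_equal(sum(attr(mm, "convergent")), 12)
})

test_that("convergent characters raise mapped homoplasy relative to clean ones", {
  set.seed(109)
  m <- mk_model(2, variable = FALSE)
  mean_hi <- function(rho, nrep = 6) {
    mean(vapply(seq_len(nrep), function(i) {
      tt <- simulate_yule_tree(10, height = 1)
      mm <- simulate_morphology(tt, n_char = 12, rho = rho, rate = 0.3)
      his <- vapply(seq_len(12), function(j) {
        ch <- setNames(mm$x[, j], mm$taxa)
        consistency_index(sample_history(tt, m, ch, n = 25, rate = 0.3),
                          ch)[["hi"]]
      }, numeric(1))
      mean(his, na.rm = TRUE)
    }, numeric(1)))
  }
  h0 <- mean_hi(0); h1 <- mean_hi(1)
  expect_gt(h1, h0)
  # near-zero homoplasy for clean characters at a low rate
  set.seed(110)
  tt <- simulate_yule_tree(10, height = 1)
  mm <- simulate_morphology(tt, n_char = 15, rho = 0, rate = 0.02)
  his <- vapply(seq_len(15), function(j) {
    ch <- setNames(mm$x[, j], mm$taxa)
    consistency_index(sample_history(tt, m, ch, n = 30, rate = 0.02),
                      ch)[["hi"]]
  }, numeric(1))
  expect_lt(mean(his, na.rm = TRUE), 0.1)
})

test_that("locality simulation: degenerate limits and phylogenetic signal", {
  set.seed(111)
  tt <- simulate_yule_tree(10, height = 1)
  loc0 <- simulate_localities(tt, sigma = 1e-6, noise = 0, jitter_km = 1e-9)
  expect_true(all(abs(loc0$latitude - 37) < 1e-4))
  expect_true(all(abs(loc0$longitude + 81) < 1e-4))

  # with zero noise, geographic distance correlates with patristic distance
  pos <- 0
  nrep <- 15
  for (i in seq_len(nrep)) {
    tt <- simulate_yule_tree(10, height = 1)
    loc <- simulate_localities(tt, sigma = 150, noise = 0)
    cen <- species_centroids(loc)
    cen <- cen[match(tt$tip.label, cen$species), ]
    G <- distance_matrix_km(cen, "species")
    Pt <- ape::cophenetic.phylo(tt)[cen$species, cen$species]
    pos <- pos + (mantel_cor(G, Pt) > 0)
  }
  expect_gte(pos / nrep, 0.9)

  # full noise destroys the signal on average
  set.seed(112)
  cors <- vapply(seq_len(20), function(i) {
    tt <- simulate_yule_tree(10, height = 1)
    loc <- simulate_localities(tt, sigma = 150, noise = 1)
    cen <- species_centroids(loc)
    cen <- cen[match(tt$tip.label, cen$species), ]
    mantel_cor(distance_matrix_km(cen, "species"),
               ape::cophenetic.phylo(tt)[cen$species, cen$species])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(20) + 0.05)
})

test_that("the full synthetic study is reproducible from its master seed", {
  cfg <- sim_config(n_taxa = 8, seq_lengths = c(a = 50), seq_models = list("JC"),
                    n_morph = 6, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$sequences$x, d2$sequences$x)
  expect_identical(d1$morphology$x, d2$morphology$x)
  expect_identical(d1$localities, d2$localities)
  d3 <- simulate_dataset(sim_config(n_taxa = 8, seq_lengths = c(a = 50),
                                    seq_models = list("JC"), n_morph = 6,
                                    seed = 78))
  expect_false(identical(d1$sequences$x, d3$sequences$x))
})
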