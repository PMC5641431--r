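test_that("spherical centroids handle symmetry and the antimeridian", {
  expect_equal(unname(sphere_centroid(10, 20)), c(10, 20), tolerance = 1e-12)
  expect_equal(unname(sphere_centroid(c(10, -10), c(20, 20))), c(0, 20),
               tolerance = 1e-9)
  ct <- sphere_centroid(c(0.5, -0.5), c(179.9, -179.9))
  expect_lt(abs(ct[["latitude"]]), 1e-9)
  expect_gt(abs(ct[["longitude"]]), 179.9) # near +-180, not 0
  # unit-vector oracle
  la <- c(40, 42, 41) * pi / 180; lo <- c(179.5, -179.7, 179.9) * pi / 180
  v <- c(mean(cos(la) * cos(lo)), mean(cos(la) * sin(lo)), mean(sin(la)))
  v <- v / sqrt(sum(v^2))
  ct2 <- sphere_centroid(c(40, 42, 41), c(179.5, -179.7, 179.9))
  expect_equal(ct2[["latitude"]], asin(v[3]) * 180 / pi, tolerance = 1e-9)
  expect_equal(ct2[["longitude"]], atan2(v[2], v[1]) * 180 / pi,
               tolerance = 1e-9)
  expect_error(sphere_centroid(c(0, 0), c(0, 180)), "degenerate")
})

test_that("great-circle distances: identity, antipodes, law-of-cosines oracle", {
  expect_equal(great_circle_km(37, -81, 37, -81), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-6)
  set.seed(91)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -179, 179))
    b <- c(runif(1, -80, 80), runif(1, -179, 179))
    slc <- acos(pmin(1, pmax(-1,
      sin(a[1] * pi / 180) * sin(b[1] * pi / 180) +
        cos(a[1] * pi / 180) * cos(b[1] * pi / 180) *
        cos((a[2] - b[2]) * pi / 180)))) * 6371.0088
    expect_equal(great_circle_km(a[1], a[2], b[1], b[2]), slc,
                 tolerance = 1e-6)
  }
  cen <- tibble::tibble(species = c("x", "y", "z"),
                        latitude = c(35, 36, 37), longitude = c(-83, -81, -80))
  D <- distance_matrix_km(cen, "species")
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
})

test_that("region assignment is deterministic with a lexicographic boundary tie-break", {
  rm_ <- region_map(list(
    B = data.frame(longitude = c(0, 1, 1, 0), latitude = c(0, 0, 1, 1)),
    A = data.frame(longitude = c(1, 2, 2, 1), latitude = c(0, 0, 1, 1))))
  expect_equal(as.character(assign_region(0.5, 0.5, rm_)), "B")
  # the shared edge lon = 1 belongs to the lexicographically first region
  for (i in 1:5) {
    expect_equal(as.character(assign_region(0.5, 1, rm_)), "A")
  }
  out <- assign_region(10, 10, rm_, quiet = TRUE)
  expect_true(isTRUE(attr(out, "fallback")))
  expect_equal(as.character(out), "A") # nearest boundary vertex
  expect_error(assign_region(0, 0, region_map(list())), "unique names|empty")
})

test_that("neighbor joining: closed form, additive recovery, permutation invariance", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- nj_tree(D3)
  el <- setNames(nj3$edge.length[order(nj3$edge[, 2])][1:3], nj3$tip.label)
  expect_equal(sort(unname(el[c("A", "B", "C")])), c(0, 2, 4))
  tr <- read_tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr)
  nj4 <- nj_tree(D)
  expect_equal(bipartitions(nj4), "C,D")
  # exact path lengths on an additive matrix
  expect_equal(ape::cophenetic.phylo(nj4)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # label order never changes the topology
  set.seed(93)
  tt <- simulate_yule_tree(8, height = 1)
  tt$edge.length <- tt$edge.length + runif(nrow(tt$edge), 0, 0.5)
  Dt <- ape::cophenetic.phylo(tt)
  ref <- sort(bipartitions(nj_tree(Dt)))
  for (i in 1:5) {
    p <- sample(rownames(Dt))
    expect_equal(sort(bipartitions(nj_tree(Dt[p, p]))), ref)
  }
  expect_error(nj_tree(Dt[1:2, 1:2]), "at least 3")
  Da <- Dt; Da[1, 2] <- Da[1, 2] + 1
  expect_error(nj_tree(Da), "not symmetric")
})

test_that("ecoregion pipeline groups well-separated clusters into constraints", {
  set.seed(95)
  rm_ <- region_map(list(
    west = data.frame(longitude = c(-10, -8, -8, -10), latitude = c(0, 0, 2, 2)),
    mid = data.frame(longitude = c(-1, 1, 1, -1), latitude = c(0, 0, 2, 2)),
    east = data.frame(longitude = c(8, 10, 10, 8), latitude = c(0, 0, 2, 2))))
  recs <- dplyr::bind_rows(
    tibble::tibble(species = c("w1", "w1", "w2"), latitude = 1,
                   longitude = c(-9.2, -9.1, -8.8)),
    tibble::tibble(species = c("m1", "m2"), latitude = 1,
                   longitude = c(-0.2, 0.3)),
    tibble::tibble(species = c("e1", "e2"), latitude = 1,
                   longitude = c(8.8, 9.4)))
  edt <- ecoregion_distance_tree(recs, rm_)
  expect_setequal(edt$tree$tip.label, c("west", "mid", "east"))
  expect_equal(edt$tree$Nnode, 1) # 3-region star
  expect_length(edt$constraints, 3)
  expect_true(all(!edt$assignments$fallback))
  # disjoint groups are always a compatible constraint set
  expect_silent(constraint_set(edt$constraints$sets))
})

test_that("range areas and endemism classes follow the definitions", {
  expect_equal(range_area_km2(37, -81), 0)
  expect_equal(range_area_km2(c(37, 37.5, 38), c(-81, -81, -81)), 0)
  # 1x1 degree square at the equator vs the spherical-excess oracle
  a <- range_area_km2(c(0, 0, 1, 1), c(0, 1, 1, 0))
  oracle <- 6371.0088^2 * (pi / 180) * (sin(pi / 180) - 0)
  expect_lt(abs(a - oracle) / oracle, 0.01)
  expect_equal(endemism_class(c(0.95, 999.9, 1000, 9999, 10000, 2e5)),
               c("MRE", "MRE", "SRE", "SRE", "widespread", "widespread"))
  recs <- tibble::tibble(
    species = rep(c("tiny", "big"), each = 4),
    latitude = c(37, 37.01, 37.01, 37, 35, 35, 38, 38),
    longitude = c(-81, -81, -80.99, -80.99, -84, -80, -80, -84))
  et <- endemism_table(recs)
  expect_equal(et$class[et$species == "tiny"], "MRE")
  expect_equal(et$class[et$species == "big"], "widespread")
  expect_true(et$sre_qualifying[et$species == "tiny"])
  expect_false(et$sre_qualifying[et$species == "big"])
})
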