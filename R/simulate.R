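#' Simulation configuration
#'
#' Bundles the generator settings for a full synthetic study: a Yule tree,
#' partitioned sequence data, morphology with a controlled fraction of
#' convergent characters, and localities whose spatial proximity tracks the
#' phylogeny. Defaults mirror a multi-gene arthropod study of ~90 taxa
#' scored for 68 morphological characters; tests and examples scale the
#' counts down.
#'
#' @param n_taxa number of tips.
#' @param birth_rate Yule speciation rate (per lineage per unit time).
#' @param tree_height target tree height in expected substitutions/site.
#' @param seq_lengths named integer vector of partition lengths.
#' @param seq_models list of [subst_model]s (or spec strings), one per
#'   partition (recycled).
#' @param n_morph number of morphological characters.
#' @param morph_states number of states per morphological character.
#' @param morph_rate rate scaler for morphological evolution.
#' @param convergence_fraction fraction rho of characters evolved on an
#'   independent decoy tree (inducing convergence relative to the true
#'   tree).
#' @param region_weights sampling weights of the gonopod-region tags.
#' @param sigma dispersal scale in km (Brownian step SD per unit branch
#'   length is `sigma * sqrt(branch length)`).
#' @param geo_noise probability that a tip's position is redrawn uniformly,
#'   destroying its phylogenetic signal.
#' @param n_localities_max tips receive 1..this many jittered localities.
#' @param origin latitude/longitude about which simulated geography is
#'   centred (default southern Appalachians).
#' @param seed master seed; all generators derive their streams from it.
#' @export
sim_config <- function(n_taxa = 90L, birth_rate = 1, tree_height = 1,
                       seq_lengths = c(COI_cp1 = 200L, COI2_EF1a12 = 514L,
                                       COI_cp3 = 200L, rRNA = 1666L,
                                       r28S = 1085L, EF1a_cp3 = 157L,
                                       EF1a_intron = 153L),
                       seq_models = list("GTR+I+G", "HKY+I+G", "GTR+I+G",
                                         "GTR+I+G", "GTR+I+G", "HKY+I",
                                         "HKY+G"),
                       n_morph = 68L, morph_states = 2L, morph_rate = 0.3,
                       convergence_fraction = 0.5,
                       region_weights = c(coxa = 0.2, prefemur = 0.2,
                                          tibiotarsus = 0.6),
                       sigma = 150, geo_noise = 0.1, n_localities_max = 6L,
                       origin = c(latitude = 37, longitude = -81),
                       seed = 1L) {
  stopifnot(n_taxa >= 3, convergence_fraction >= 0, convergence_fraction <= 1,
            geo_noise >= 0, geo_noise <= 1, sigma > 0,
            all(seq_lengths > 0), n_morph > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth process started from two lineages; the waiting time with k
#' lineages is Exponential(k * birth_rate). The tree is rescaled to
#' `height` (expected substitutions per site from root to any tip) unless
#' `height` is `NULL`.
#'
#' @param n number of tips (>= 3).
#' @param birth_rate speciation rate.
#' @param height target height, or `NULL` to keep the simulated time scale.
#' @return an ultrametric [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, height = 1) {
  stopifnot(n >= 3)
  # lineage birth times: each active lineage splits at rate birth_rate
  # splits: vector of times with k lineages, k = 2..n-1
  waits <- stats::rexp(n - 1, rate = birth_rate * (1:(n - 1)))
  # waits[k] is the waiting time with k lineages (k = 1 handled as the
  # root edge of length 0: we start at the first split)
  split_times <- cumsum(waits[-1]) # times of splits 2->3, ..., n-1->n
  total <- if (n > 2) sum(waits[-1]) + stats::rexp(1, n * birth_rate)
    else stats::rexp(1, 2 * birth_rate)
  # build by splitting a random active tip at each event
  # representation: newick assembled via node records
  parent <- integer(2 * n - 1); btime <- numeric(2 * n - 1)
  # node 1 = root (time 0); lineages are "open" nodes
  nxt <- 1L
  open <- c()
  root <- nxt; btime[root] <- 0
  ch <- c(nxt + 1L, nxt + 2L)
  parent[ch] <- root; btime[ch] <- 0
  nxt <- nxt + 2L
  open <- ch
  ts <- c(split_times, total)
  for (k in seq_len(n - 2)) {
    sp <- open[sample.int(length(open), 1)]
    ch <- c(nxt + 1L, nxt + 2L)
    parent[ch] <- sp; btime[ch] <- ts[k]
    nxt <- nxt + 2L
    open <- c(setdiff(open, sp), ch)
  }
  # open now has n lineages; they end at time `total`
  nn <- nxt
  is_tip <- !(seq_len(nn) %in% parent[seq_len(nn)])
  tip_ids <- which(is_tip)
  node_ids <- setdiff(seq_len(nn), tip_ids)
  newid <- integer(nn)
  newid[tip_ids] <- seq_along(tip_ids)
  newid[node_ids] <- length(tip_ids) + seq_along(node_ids)
  end_time <- numeric(nn)
  end_time[tip_ids] <- total
  for (i in node_ids) {
    kids <- which(parent == i)
    end_time[i] <- btime[kids[1]]
  }
  edges <- which(parent > 0)
  edge <- cbind(newid[parent[edges]], newid[edges])
  elen <- end_time[edges] - btime[edges]
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_along(tip_ids)),
                        Nnode = length(node_ids)), class = "phylo")
  phy <- ape::read.tree(text = ape::write.tree(phy)) # canonicalize
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * height / h
  }
  phy
}

# evolve one partition of sites down the tree under a substitution model
evolve_states <- function(phy, m, nsites, rates) {
  s <- length(m$states)
  eg <- q_eigen(m)
  ntip <- length(phy$tip.label)
  nn <- max(phy$edge)
  states <- matrix(0L, nn, nsites)
  root <- tree_root(phy)
  states[root, ] <- sample.int(s, nsites, replace = TRUE, prob = m$freq)
  site_rate <- rates$rates[sample.int(length(rates$rates), nsites,
                                      replace = TRUE, prob = rates$weights)]
  for (e in rev(edge_postorder(phy))) { # preorder
    pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]; t <- phy$edge.length[e]
    for (r in unique(site_rate)) {
      idx <- which(site_rate == r)
      P <- eg$U %*% diag(exp(eg$lambda * t * r), s) %*% eg$Uinv
      P[P < 0] <- 0; P <- P / rowSums(P)
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(idx))
      from <- states[pa, idx]
      states[ch, idx] <- 1L + as.integer(rowSums(u > cum[from, , drop = FALSE]))
    }
  }
  states[seq_len(ntip), , drop = FALSE]
}

#' Simulate partitioned sequence data on a tree
#'
#' Root states drawn from the stationary frequencies, then evolved down
#' each branch with the model's transition probabilities, independently per
#' partition, with per-site rates drawn from the model's invariant/gamma
#' mixture.
#'
#' @param phy tree with branch lengths (expected substitutions/site).
#' @param lengths named vector of partition lengths.
#' @param models list of [subst_model]s or spec strings (recycled).
#' @return a DNA [char_matrix] with the partition ids set; attribute
#'   `scheme` holds the matching [partition_scheme].
#' @export
simulate_sequences <- function(phy, lengths, models) {
  if (!is.list(models)) models <- list(models)
  models <- lapply(models, function(m) if (is.character(m)) parse_model(m) else m)
  models <- rep(models, length.out = length(lengths))
  mats <- list()
  for (p in seq_along(lengths)) {
    m <- models[[p]]
    st <- evolve_states(phy, m, lengths[p], mixture_rates(m))
    mats[[p]] <- matrix(m$states[st], nrow = nrow(st))
  }
  x <- do.call(cbind, mats)
  rownames(x) <- phy$tip.label
  part <- rep(seq_along(lengths), lengths)
  cm <- char_matrix(x, alphabet = "dna", partition = part)
  sites <- split(seq_len(ncol(x)), part)
  names(sites) <- if (!is.null(names(lengths))) names(lengths)
    else paste0("part", seq_along(lengths))
  attr(cm, "scheme") <- partition_scheme(sites, models)
  cm
}

#' Simulate morphological characters with controlled convergence
#'
#' A fraction `1 - rho` of characters evolves under the Mk model on the
#' true tree; a fraction `rho` evolves on an independently drawn decoy Yule
#' tree over the same taxa, which induces convergence (shared derived
#' states in taxa that are unrelated on the true tree). Constant characters
#' are redrawn, emulating "variable" coding. Characters are tagged with
#' gonopod regions at the configured weights.
#'
#' @param phy true tree.
#' @param n_char number of characters.
#' @param k states per character.
#' @param rho convergence fraction in `[0, 1]`.
#' @param rate rate scaler for character evolution.
#' @param region_weights named weights for coxa/prefemur/tibiotarsus.
#' @param decoy_tree optional decoy tree (default: fresh Yule tree of the
#'   same height).
#' @param max_redraws redraw budget per character before accepting a
#'   constant character anyway.
#' @return a standard [char_matrix]; attribute `convergent` flags the
#'   decoy-evolved characters, attribute `decoy_tree` stores the tree.
#' @export
simulate_morphology <- function(phy, n_char = 68L, k = 2L, rho = 0.5,
                                rate = 0.3,
                                region_weights = c(coxa = 0.2, prefemur = 0.2,
                                                   tibiotarsus = 0.6),
                                decoy_tree = NULL, max_redraws = 200L) {
  stopifnot(rho >= 0, rho <= 1)
  ntip <- length(phy$tip.label)
  h <- max(ape::node.depth.edgelength(phy))
  if (is.null(decoy_tree)) {
    decoy_tree <- simulate_yule_tree(ntip, height = h)
    decoy_tree$tip.label <- sample(phy$tip.label)
  }
  m <- mk_model(k = k, variable = FALSE)
  n_conv <- round(rho * n_char)
  convergent <- c(rep(TRUE, n_conv), rep(FALSE, n_char - n_conv))
  cols <- matrix("", ntip, n_char, dimnames = list(phy$tip.label, NULL))
  rates <- mixture_rates(m)
  for (j in seq_len(n_char)) {
    tr <- if (convergent[j]) decoy_tree else phy
    tr$edge.length <- tr$edge.length * rate
    for (trial in seq_len(max_redraws)) {
      st <- evolve_states(tr, m, 1L, rates)
      if (length(unique(st[, 1])) > 1) break
    }
    v <- m$states[st[, 1]]
    names(v) <- tr$tip.label
    cols[, j] <- v[phy$tip.label]
  }
  region <- sample(names(region_weights), n_char, replace = TRUE,
                   prob = region_weights)
  cm <- char_matrix(cols, alphabet = "standard", region = region)
  attr(cm, "convergent") <- convergent
  attr(cm, "decoy_tree") <- decoy_tree
  cm
}

#' Simulate locality records tracking the phylogeny
#'
#' Positions diffuse along the tree as 2-D Brownian motion in km with step
#' standard deviation `sigma * sqrt(branch length)` per axis; each tip gets
#' 1..`n_localities_max` localities jittered around its position. With
#' probability `noise` a tip's position is redrawn uniformly over the
#' simulation window, destroying its signal. Kilometre offsets are mapped
#' to latitude/longitude about `origin`.
#'
#' @param phy tree with branch lengths.
#' @param sigma dispersal scale (km).
#' @param noise per-tip signal-destruction probability in `[0, 1]`.
#' @param origin `c(latitude, longitude)` of the diffusion origin.
#' @param n_localities_max maximum localities per species.
#' @param jitter_km local scatter of a species' localities.
#' @return a [locality_records] tibble; attribute `tip_xy` stores the true
#'   tip positions in km.
#' @export
simulate_localities <- function(phy, sigma = 150, noise = 0,
                                origin = c(latitude = 37, longitude = -81),
                                n_localities_max = 6L, jitter_km = 25) {
  stopifnot(sigma > 0, noise >= 0, noise <= 1)
  nn <- max(phy$edge)
  ntip <- length(phy$tip.label)
  xy <- matrix(0, nn, 2)
  for (e in rev(edge_postorder(phy))) { # preorder
    pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sd_ <- sigma * sqrt(phy$edge.length[e])
    xy[ch, ] <- xy[pa, ] + stats::rnorm(2, 0, sd_)
  }
  h <- max(ape::node.depth.edgelength(phy))
  half <- 3 * sigma * sqrt(max(h, 1e-12))
  redraw <- which(stats::runif(ntip) < noise)
  if (length(redraw)) {
    xy[redraw, ] <- matrix(stats::runif(2 * length(redraw), -half, half),
                           ncol = 2)
  }
  rows <- list()
  for (i in seq_len(ntip)) {
    nl <- sample.int(n_localities_max, 1)
    for (l in seq_len(nl)) {
      dx <- xy[i, 1] + stats::rnorm(1, 0, jitter_km)
      dy <- xy[i, 2] + stats::rnorm(1, 0, jitter_km)
      lat <- origin[["latitude"]] + dy / 111.32
      lon <- origin[["longitude"]] +
        dx / (111.32 * cos(lat * pi / 180))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species = phy$tip.label[i], latitude = lat, longitude = lon)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "tip_xy") <- xy[seq_len(ntip), , drop = FALSE]
  out
}

#' Default rectangular region map for simulations
#'
#' A grid of rectangles around the configured origin, a simple stand-in
#' for an ecoregion map.
#' @param origin `c(latitude, longitude)` grid centre.
#' @param n grid side (n x n regions).
#' @param cell_deg cell side in degrees.
#' @return a [region_map] with names `R11..Rnn`.
#' @export
grid_region_map <- function(origin = c(latitude = 37, longitude = -81),
                            n = 3, cell_deg = 2) {
  half <- n * cell_deg / 2
  polys <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    lon0 <- origin[["longitude"]] - half + (j - 1) * cell_deg
    lat0 <- origin[["latitude"]] - half + (i - 1) * cell_deg
    polys[[paste0("R", i, j)]] <- data.frame(
      longitude = c(lon0, lon0 + cell_deg, lon0 + cell_deg, lon0),
      latitude = c(lat0, lat0, lat0 + cell_deg, lat0 + cell_deg))
  }
  region_map(polys)
}

#' Simulate a full synthetic study
#'
#' Draws the true tree, sequence supermatrix, morphology and localities in
#' one call, reproducibly from the master seed.
#'
#' @param cfg a [sim_config].
#' @return list with `tree`, `sequences` (with its `scheme` attribute),
#'   `morphology`, `localities`, `regions`, and `truth` (a list recording
#'   the generating parameters and per-character generating tree).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  tree <- simulate_yule_tree(cfg$n_taxa, cfg$birth_rate, cfg$tree_height)
  seqs <- simulate_sequences(tree, cfg$seq_lengths, cfg$seq_models)
  morph <- simulate_morphology(tree, cfg$n_morph, cfg$morph_states,
                               cfg$convergence_fraction, cfg$morph_rate,
                               cfg$region_weights)
  loc <- simulate_localities(tree, cfg$sigma, cfg$geo_noise, cfg$origin,
                             cfg$n_localities_max)
  regions <- grid_region_map(cfg$origin)
  list(tree = tree, sequences = seqs, morphology = morph, localities = loc,
       regions = regions,
       truth = list(seed = cfg$seed,
                    convergence_fraction = cfg$convergence_fraction,
                    convergent = attr(morph, "convergent"),
                    sigma = cfg$sigma, geo_noise = cfg$geo_noise))
}
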