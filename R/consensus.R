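# Split frequencies of a tree sample, as a named numeric vector over
# normalized split keys.
split_frequencies <- function(trees) {
  n <- length(trees)
  tab <- table(unlist(lapply(trees, bipartitions)))
  stats::setNames(as.numeric(tab) / n, names(tab))
}

#' Average standard deviation of split frequencies (SDSF)
#'
#' Topological convergence diagnostic between independent MCMC runs: for
#' every non-trivial split reaching frequency `min_freq` in at least one
#' run, the (population) standard deviation of its frequency across runs is
#' computed; the mean over such splits is returned.
#'
#' @param x a `posterior_sample` with two or more runs, or a list of tree
#'   lists.
#' @param min_freq inclusion threshold (default 0.10).
#' @return mean SD; attribute `per_split` holds the per-split table.
#' @export
sdsf <- function(x, min_freq = 0.10) {
  runs <- if (inherits(x, "posterior_sample")) {
    lapply(x$runs, function(r) r$trees)
  } else x
  if (length(runs) < 2) stop("sdsf needs at least two runs")
  if (any(vapply(runs, length, integer(1)) == 0)) stop("empty tree sample")
  freqs <- lapply(runs, split_frequencies)
  keys <- unique(unlist(lapply(freqs, names)))
  fmat <- vapply(freqs, function(f) ifelse(keys %in% names(f), f[keys], 0),
                 numeric(length(keys)))
  fmat <- matrix(fmat, nrow = length(keys))
  keep <- apply(fmat, 1, max) >= min_freq
  if (!any(keep)) return(structure(0, per_split = tibble::tibble()))
  fm <- fmat[keep, , drop = FALSE]
  sds <- apply(fm, 1, function(v) sqrt(mean((v - mean(v))^2)))
  structure(mean(sds),
            per_split = tibble::tibble(split = keys[keep], sd = sds))
}

#' All-compatible (greedy extended majority-rule) consensus
#'
#' Splits are added in decreasing sample frequency whenever compatible with
#' the splits already accepted; node labels carry the split frequencies
#' (posterior probabilities). Branch lengths are the mean lengths of the
#' matching edges across the samples in which each split occurs (pendant
#' edges averaged over all samples).
#'
#' @param x a `posterior_sample` or list of trees.
#' @param min_freq drop splits below this frequency (default 0: keep all
#'   compatible groupings).
#' @return an [ape::phylo] tree with `node.label` posterior probabilities.
#' @export
consensus_tree <- function(x, min_freq = 0) {
  trees <- if (inherits(x, "posterior_sample")) posterior_trees(x) else x
  if (!length(trees)) stop("empty tree sample")
  taxa <- sort(trees[[1]]$tip.label)
  freqs <- split_frequencies(trees)
  ord <- order(-freqs, names(freqs)) # frequency desc, key asc for ties
  freqs <- freqs[ord]
  freqs <- freqs[freqs >= max(min_freq, 1e-12)]
  compat <- function(a, b) {
    ia <- intersect(a, b)
    length(ia) == 0 || length(ia) == length(a) || length(ia) == length(b) ||
      length(union(a, b)) == length(taxa)
  }
  chosen <- list(); chosen_f <- numeric(0)
  for (i in seq_along(freqs)) {
    side <- strsplit(names(freqs)[i], ",")[[1]]
    ok <- all(vapply(chosen, function(c_) {
      compat(side, c_) || compat(setdiff(taxa, side), c_)
    }, logical(1)))
    if (ok) {
      # store as the clade side usable in a rooted build: the side not
      # containing the reference taxon
      chosen[[length(chosen) + 1L]] <- side
      chosen_f <- c(chosen_f, freqs[i])
    }
  }
  # laminar family (relative to taxa minus reference): build newick
  build <- function(members, idx) {
    within <- idx[vapply(idx, function(i) all(chosen[[i]] %in% members) &&
                           length(chosen[[i]]) < length(members), logical(1))]
    tops <- within[vapply(within, function(i) {
      !any(vapply(within, function(j) j != i &&
                    all(chosen[[i]] %in% chosen[[j]]) &&
                    length(chosen[[j]]) > length(chosen[[i]]), logical(1)))
    }, logical(1))]
    used <- unlist(chosen[tops])
    parts <- c(lapply(tops, function(i) {
      paste0(build(chosen[[i]], within), sprintf("%.4f", chosen_f[i]))
    }), as.list(setdiff(members, used)))
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, seq_along(chosen)), ";")
  cons <- ape::read.tree(text = nwk)
  cons$edge.length <- consensus_branch_lengths(cons, trees)
  cons
}

# mean branch length over samples for each consensus edge (matched by the
# split the edge induces; splits absent from a sample are skipped).
consensus_branch_lengths <- function(cons, trees) {
  taxa <- cons$tip.label
  sets <- node_tip_sets(cons)
  keys <- vapply(seq_along(sets), function(i) split_key(sets[[i]], taxa),
                 character(1))
  sums <- stats::setNames(numeric(length(keys)), NULL)
  cnts <- numeric(length(keys))
  for (tr in trees) {
    tsets <- node_tip_sets(tr)
    tkeys <- vapply(seq_along(tsets), function(i) split_key(tsets[[i]], taxa),
                    character(1))
    tlen <- numeric(length(tkeys))
    for (e in seq_len(nrow(tr$edge))) tlen[tr$edge[e, 2]] <- tr$edge.length[e]
    agg <- tapply(tlen, tkeys, sum)
    m <- match(keys, names(agg))
    hit <- !is.na(m)
    sums[hit] <- sums[hit] + agg[m[hit]]
    cnts[hit] <- cnts[hit] + 1
  }
  el <- numeric(nrow(cons$edge))
  for (e in seq_len(nrow(cons$edge))) {
    nd <- cons$edge[e, 2]
    el[e] <- if (cnts[nd] > 0) sums[nd] / cnts[nd] else 0
  }
  el
}
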