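# Edge indices in postorder (children before parents), independent of the
# storage order of the edge matrix.
edge_postorder <- function(phy) {
  nn <- max(phy$edge)
  kids <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge))) {
    pa <- phy$edge[e, 1]
    kids[[pa]] <- c(kids[[pa]], e)
  }
  out <- integer(nrow(phy$edge))
  k <- 0L
  rec <- function(node) {
    for (e in kids[[node]]) {
      rec(phy$edge[e, 2])
      k <<- k + 1L
      out[k] <<- e
    }
  }
  rec(tree_root(phy))
  out
}

# root node id: the node that never appears as a child
tree_root <- function(phy) {
  r <- unique(phy$edge[, 1][!(phy$edge[, 1] %in% phy$edge[, 2])])
  if (length(r) != 1) stop("tree has no unique root")
  r
}

# postorder edge arrays (used by the R-side samplers)
postorder_edges <- function(phy) {
  po <- edge_postorder(phy)
  list(parent = phy$edge[po, 1], child = phy$edge[po, 2],
       elen = phy$edge.length[po],
       nnode_total = max(phy$edge),
       root = tree_root(phy),
       ntip = length(phy$tip.label))
}

# Per-pattern log-likelihood (rate categories combined) via the compiled
# pruning core. `tipp` has dim (nstates, npat, ntip) ordered like
# phy$tip.label.
pattern_loglik <- function(phy, m, tipp) {
  eg <- q_eigen(m)
  mx <- mixture_rates(m)
  ntip <- length(phy$tip.label)
  pruning_loglik_cpp(phy$edge, phy$edge.length, ntip, max(phy$edge),
                     tree_root(phy), tipp, eg$U, eg$Uinv, eg$lambda,
                     m$freq, mx$rates, log(mx$weights))
}

# Align matrix taxa to tree tips; matrix taxa absent from the tree error,
# tree tips absent from the matrix are pruned.
align_tree_matrix <- function(phy, cm) {
  miss <- setdiff(cm$taxa, phy$tip.label)
  if (length(miss)) stop("taxa absent from tree: ", paste(miss, collapse = ", "))
  extra <- setdiff(phy$tip.label, cm$taxa)
  if (length(extra)) phy <- ape::drop.tip(phy, extra)
  phy
}

#' Phylogenetic log-likelihood (pruning algorithm)
#'
#' Felsenstein pruning under a reversible substitution model with optional
#' invariant-site and discrete-gamma rate mixture. Missing, gap and
#' ambiguous cells contribute a partial likelihood of 1 over their allowed
#' states. Sites are pattern-compressed internally.
#'
#' @param phy tree with branch lengths; its tips must include all matrix
#'   taxa.
#' @param m a [subst_model].
#' @param cm a [char_matrix] with `alphabet = "dna"`.
#' @param cols optional column (site) subset.
#' @return total log-likelihood; per-site values via [site_loglik()].
#' @export
loglik <- function(phy, m, cm, cols = NULL) {
  sum(site_loglik(phy, m, cm, cols))
}

#' @rdname loglik
#' @export
site_loglik <- function(phy, m, cm, cols = NULL) {
  stopifnot(inherits(cm, "char_matrix"))
  if (is.null(cols)) cols <- seq_len(ncol(cm$x))
  phy <- align_tree_matrix(phy, cm)
  states <- m$states
  sub <- cm$x[match(phy$tip.label, cm$taxa), cols, drop = FALSE]
  pat_id <- apply(sub, 2, paste, collapse = "\r")
  upat <- !duplicated(pat_id)
  cmp <- cm
  cmp$x <- sub[, upat, drop = FALSE]
  cmp$taxa <- phy$tip.label
  tipp <- tip_partial_array(cmp, states = states)
  per_pat <- pattern_loglik(phy, m, tipp)
  per_pat[match(pat_id, pat_id[upat])]
}

#' Mk / Mkv log-likelihood for morphological characters
#'
#' Likelihood of a multistate matrix under the Mk model, optionally
#' conditioned on characters being variable ("variable" coding): each
#' character's likelihood is divided by one minus the summed likelihood of
#' all constant patterns, with the gamma mixture applied inside both the
#' numerator and the correction.
#'
#' @param phy tree with branch lengths.
#' @param m an [mk_model].
#' @param cm a standard-alphabet [char_matrix].
#' @param cols optional character subset.
#' @return total log-likelihood; attribute `per_character` holds the
#'   per-character values.
#' @export
loglik_mkv <- function(phy, m, cm, cols = NULL) {
  stopifnot(inherits(m, "mk_model"), cm$alphabet == "standard")
  if (is.null(cols)) cols <- seq_len(ncol(cm$x))
  phy <- align_tree_matrix(phy, cm)
  states <- m$states
  sub <- cm$x[match(phy$tip.label, cm$taxa), cols, drop = FALSE]
  for (j in seq_along(cols)) {
    obs <- unique(sub[, j]); obs <- obs[!(obs %in% c("?", "-"))]
    if (length(setdiff(obs, states))) {
      stop(sprintf("character %d has states beyond the %d-state model",
                   cols[j], m$k))
    }
  }
  cmp <- cm; cmp$x <- sub; cmp$taxa <- phy$tip.label
  tipp <- tip_partial_array(cmp, states = states)
  lnl <- pattern_loglik(phy, m, tipp)
  if (isTRUE(m$variable)) {
    ntax <- nrow(sub)
    cc <- matrix(rep(states, each = ntax), nrow = ntax)
    rownames(cc) <- phy$tip.label
    ccm <- cm; ccm$x <- cc; ccm$taxa <- phy$tip.label
    ccm$partition <- rep(1L, ncol(cc)); ccm$region <- rep("other", ncol(cc))
    tippc <- tip_partial_array(ccm, states = states)
    lnc <- pattern_loglik(phy, m, tippc)
    pconst <- sum(exp(lnc))
    if (pconst >= 1) pconst <- 1 - 1e-12
    lnl <- lnl - log1p(-pconst)
  }
  structure(sum(lnl), per_character = lnl)
}

#' Minimum state changes of a character on a tree (Fitch length)
#'
#' Parsimony length of an unordered multistate character, computed with
#' Hartigan's generalization of the Fitch downpass, which is exact on
#' polytomous trees. Missing or ambiguous cells contribute their full
#' allowed state set.
#'
#' @param phy tree (branch lengths ignored).
#' @param char named character vector of states (names are taxon labels),
#'   with `?`/`-`/`NA` for missing; or a [char_matrix] together with `col`.
#' @param col character index when `char` is a matrix.
#' @return integer minimum number of changes.
#' @export
fitch_length <- function(phy, char, col = NULL) {
  if (inherits(char, "char_matrix")) {
    cm <- char
    sets <- tip_partial_array(cm, cols = col, states = state_labels(cm))
    tip_sets <- t(sets[, 1, ]) > 0 # ntaxa x nstates
    rownames(tip_sets) <- cm$taxa
  } else {
    char <- stats::setNames(as.character(char), names(char))
    states <- sort(unique(char[!(char %in% c("?", "-", NA))]))
    if (!length(states)) return(0L)
    tip_sets <- matrix(FALSE, length(char), length(states),
                       dimnames = list(names(char), states))
    for (i in seq_along(char)) {
      tip_sets[i, ] <- if (char[i] %in% c("?", "-", NA)) TRUE
        else states == char[i]
    }
  }
  miss <- setdiff(phy$tip.label, rownames(tip_sets))
  if (length(miss)) phy <- ape::drop.tip(phy, miss)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  s <- ncol(tip_sets)
  setmat <- matrix(FALSE, nn, s)
  setmat[seq_len(ntip), ] <- tip_sets[match(phy$tip.label, rownames(tip_sets)), ]
  cost <- 0L
  # internal nodes ordered children-before-parents: by last occurrence as a
  # parent in the postorder edge list
  p <- phy$edge[edge_postorder(phy), 1]
  ord <- rev(unique(rev(p)))
  for (pa in ord) {
    chn <- phy$edge[phy$edge[, 1] == pa, 2]
    cnt <- colSums(matrix(setmat[chn, ], ncol = s))
    m <- max(cnt)
    cost <- cost + length(chn) - m
    setmat[pa, ] <- cnt == m
  }
  as.integer(cost)
}
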