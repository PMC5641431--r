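#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] with validation: duplicate leaf
#' labels are an error, and absent branch lengths are set to 0 with a
#' warning. Polytomies are preserved; unrooted trees keep their arbitrary
#' basal trifurcation.
#'
#' @param path file path, or a Newick string via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  phy <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree found")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (any(phy$edge.length < 0)) stop("negative branch length in input tree")
  phy
}

#' Write a tree as Newick
#' @param phy an [ape::phylo] tree.
#' @param path output file.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

# Tip-label sets descending from every node (index = node id).
node_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- max(phy$edge)
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  # accumulate in postorder: children before parents
  for (e in edge_postorder(phy)) {
    pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }
  sets
}

# Normalize a taxon subset to a split key relative to the full leaf set:
# the side not containing the lexicographically first taxon.
split_key <- function(set, taxa) {
  ref <- min(taxa)
  side <- if (ref %in% set) setdiff(taxa, set) else set
  paste(sort(side), collapse = ",")
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the leaves in two; splits
#' are orientation-normalized (the side not containing the lexicographically
#' first taxon) and returned as sorted comma-joined strings. Trivial splits
#' (one side with fewer than two taxa) are dropped.
#'
#' @param phy an [ape::phylo] tree (rooted trees are treated as unrooted).
#' @param trivial include trivial splits too (used internally by
#'   constraint checking).
#' @return character vector of split keys.
#' @export
bipartitions <- function(phy, trivial = FALSE) {
  taxa <- phy$tip.label
  n <- length(taxa)
  sets <- node_tip_sets(phy)
  root <- tree_root(phy)
  keys <- character(0)
  for (nd in seq_along(sets)) {
    if (nd == root) next
    k <- length(sets[[nd]])
    if (!trivial && (k < 2 || k > n - 2)) next
    if (k < 1 || k > n - 1) next
    keys <- c(keys, split_key(sets[[nd]], taxa))
  }
  unique(keys[keys != ""])
}

#' Monophyly constraint sets
#'
#' A named collection of taxon subsets each required to be monophyletic
#' (a hard constraint: zero prior mass on violating topologies). Subsets
#' must be pairwise compatible (nested or disjoint); incompatible sets are
#' rejected at construction.
#'
#' @param sets list of character vectors of taxon labels.
#' @param name constraint-set name.
#' @param taxa optional full taxon set; when supplied, each subset must be a
#'   proper subset of it.
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(sets, name = "constraints", taxa = NULL) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  for (s in sets) {
    if (length(s) < 2) stop("each constraint needs at least 2 taxa")
  }
  if (!is.null(taxa)) {
    for (s in sets) {
      miss <- setdiff(s, taxa)
      if (length(miss)) stop("constraint taxa not in taxon set: ",
                             paste(miss, collapse = ", "))
      if (length(s) >= length(taxa)) {
        stop("a constraint must be a proper subset of all taxa")
      }
    }
  }
  if (length(sets) > 1) {
    for (i in seq_along(sets)[-length(sets)]) for (j in (i + 1):length(sets)) {
      a <- sets[[i]]; b <- sets[[j]]
      inter <- intersect(a, b)
      if (length(inter) && !(length(inter) == length(a) ||
                             length(inter) == length(b))) {
        stop(sprintf("incompatible constraints %d and %d: overlap without nesting", i, j))
      }
    }
  }
  structure(list(name = name, sets = sets, taxa = taxa),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> '%s': %d constraint(s)\n", x$name,
              length(x$sets)))
  invisible(x)
}

#' @export
length.constraint_set <- function(x) length(x$sets)

#' Read / write constraint sets as JSON
#'
#' The JSON layout is an object mapping the set name to a list of taxon
#' lists, e.g. `{"SW86": [["t1","t2"],["t3","t4","t5"]]}`.
#' @param path JSON file.
#' @return a [constraint_set] (the first named entry).
#' @export
read_constraints <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(obj)) stop("empty constraint file")
  nm <- names(obj)[1]
  constraint_set(lapply(obj[[nm]], unlist), name = nm)
}

#' @rdname read_constraints
#' @param cs a [constraint_set].
#' @export
write_constraints <- function(cs, path) {
  obj <- stats::setNames(list(cs$sets), cs$name)
  jsonlite::write_json(obj, path)
  invisible(path)
}

#' Does a tree satisfy a constraint set?
#'
#' TRUE iff every constrained subset is a clade of the unrooted tree, i.e.
#' induced by some edge.
#'
#' @param phy an [ape::phylo] tree.
#' @param cs a [constraint_set].
#' @return logical flag.
#' @export
satisfies <- function(phy, cs) {
  taxa <- phy$tip.label
  for (s in cs$sets) {
    miss <- setdiff(s, taxa)
    if (length(miss)) stop("constraint taxa missing from tree: ",
                           paste(miss, collapse = ", "))
  }
  splits <- bipartitions(phy, trivial = TRUE)
  all(vapply(cs$sets, function(s) split_key(s, taxa) %in% splits ||
               length(s) >= length(taxa) - 1, logical(1)))
}

#' Constraint set from the clades of a reference tree
#'
#' One monophyly constraint per internal node (excluding the root's full
#' leaf set); for a fully resolved rooted tree of n taxa this yields the
#' n-1 nested constraints that pin the complete branching pattern.
#'
#' @param phy reference tree.
#' @param name constraint-set name.
#' @export
constraints_from_tree <- function(phy, name = "tree") {
  ntip <- length(phy$tip.label)
  sets <- node_tip_sets(phy)
  idx <- (ntip + 1L):(ntip + phy$Nnode)
  keep <- Filter(function(s) length(s) >= 2 && length(s) < ntip,
                 lapply(idx, function(i) sets[[i]]))
  keep <- unique(lapply(keep, sort))
  constraint_set(keep, name = name, taxa = phy$tip.label)
}

# Random topology satisfying a (compatible, nested) constraint set:
# build the constraint nest as a multifurcating tree, then resolve
# polytomies randomly. Branch lengths drawn iid Exponential(rate).
constrained_start_tree <- function(taxa, cs = NULL, bl_rate = 10) {
  taxa <- sort(taxa)
  build <- function(members, sets) {
    # maximal constraint sets within `members`
    sets <- Filter(function(s) all(s %in% members) && length(s) < length(members), sets)
    if (length(sets)) {
      ismax <- vapply(seq_along(sets), function(i) {
        !any(vapply(seq_along(sets), function(j) {
          i != j && all(sets[[i]] %in% sets[[j]])
        }, logical(1)))
      }, logical(1))
      tops <- sets[ismax]
    } else tops <- list()
    used <- unlist(tops)
    parts <- c(lapply(tops, function(s) build(s, sets)),
               as.list(setdiff(members, used)))
    if (length(parts) == 1) return(parts[[1]])
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, if (is.null(cs)) list() else cs$sets), ";")
  phy <- ape::read.tree(text = nwk)
  phy <- ape::multi2di(phy, random = TRUE)
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = bl_rate)
  phy
}
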