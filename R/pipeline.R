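#' Compare alternative topological hypotheses against molecular data
#'
#' The end-to-end test of whether geography or morphology predicts the
#' molecular phylogeny. Four hypotheses are scored by constrained
#' stepping-stone marginal likelihoods on the molecular matrix:
#'
#' * `MOT` - the molecular tree itself: an unconstrained MCMC is run, its
#'   all-compatible consensus taken, and the analysis re-run constrained to
#'   that fully resolved branching pattern (the baseline);
#' * `MRT` - the morphology tree: consensus of an Mkv MCMC on the
#'   morphological matrix, used as a full constraint set;
#' * `EDT` - the ecoregion distance tree from [ecoregion_distance_tree()]:
#'   one monophyly constraint per occupied region;
#' * a prior classification (e.g. an `SW86`-style hypothesis) supplied as a
#'   [constraint_set].
#'
#' Bayes factors are reported as `2 delta ln` against the MOT baseline.
#'
#' @param molecular nucleotide [char_matrix].
#' @param morphology optional standard [char_matrix].
#' @param localities optional [locality_records].
#' @param regions optional [region_map] (required with `localities`).
#' @param prior_constraints optional [constraint_set] for the prior
#'   classification hypothesis.
#' @param scheme optional [partition_scheme] for the molecular data.
#' @param config [mcmc_config] used for the topology-inference MCMCs.
#' @param ss_steps,ss_ngen_per_step stepping-stone settings.
#' @param seed master seed.
#' @return list of class `hypothesis_comparison`: `table` (tibble ranked by
#'   marginal likelihood: hypothesis, n constraints, log ML, MC-SE, 2
#'   delta ln vs MOT, category), `marginals`, `consensus` trees, and the
#'   per-hypothesis constraint sets.
#' @export
run_comparison <- function(molecular, morphology = NULL, localities = NULL,
                           regions = NULL, prior_constraints = NULL,
                           scheme = NULL, config = mcmc_config(),
                           ss_steps = 50L, ss_ngen_per_step = 300L,
                           seed = 1L) {
  set.seed(seed)
  if (is.null(scheme)) scheme <- attr(molecular, "scheme") %||%
      default_scheme(molecular)
  hyps <- list()
  consensus <- list()

  # MOT: unconstrained molecular run -> consensus -> full constraint set
  cfg_mot <- config; cfg_mot$seed <- NULL
  ps_mol <- run_mcmc(molecular, scheme, constraints = NULL, config = cfg_mot)
  cons_mol <- consensus_tree(ps_mol)
  consensus$MOT <- cons_mol
  hyps$MOT <- constraints_from_tree(cons_mol, name = "MOT")

  # MRT: morphology MCMC -> consensus -> full constraint set
  if (!is.null(morphology)) {
    ps_mor <- run_mcmc(morphology, config = cfg_mot)
    cons_mor <- consensus_tree(ps_mor)
    consensus$MRT <- cons_mor
    hyps$MRT <- constraints_from_tree(cons_mor, name = "MRT")
  }

  # EDT: ecoregion distance tree constraints
  if (!is.null(localities)) {
    if (is.null(regions)) stop("localities supplied without a region map")
    edt <- ecoregion_distance_tree(localities, regions)
    consensus$EDT <- edt$tree
    hyps$EDT <- edt$constraints
  }

  if (!is.null(prior_constraints)) {
    hyps[[prior_constraints$name]] <- prior_constraints
  }

  marginals <- list()
  rows <- list()
  for (nm in names(hyps)) {
    ml <- stepping_stone(molecular, scheme, hyps[[nm]], steps = ss_steps,
                         config = config, ngen_per_step = ss_ngen_per_step)
    marginals[[nm]] <- ml
    rows[[nm]] <- tibble::tibble(hypothesis = nm,
                                 n_constraints = length(hyps[[nm]]),
                                 log_ml = ml$log_ml, se = ml$se)
  }
  tab <- dplyr::bind_rows(rows)
  base <- tab$log_ml[tab$hypothesis == "MOT"]
  tab$two_delta_ln_vs_MOT <- 2 * (base - tab$log_ml)
  tab$category <- vapply(tab$two_delta_ln_vs_MOT, function(x) {
    ax <- abs(x)
    if (ax < 2) "none" else if (ax < 6) "positive"
    else if (ax < 10) "strong" else "very strong"
  }, character(1))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$log_ml))
  structure(list(table = tab, marginals = marginals, consensus = consensus,
                 constraints = hyps, molecular_posterior = ps_mol),
            class = "hypothesis_comparison")
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  cat("<hypothesis_comparison>\n")
  print(x$table)
  invisible(x)
}

#' Mk versus Mk+Gamma for a morphological matrix
#'
#' Runs the stepping-stone estimator under both models ("variable" coding
#' in both) and reports the Bayes factor; under the 2 delta ln > 10 "very
#' strong" rule the gamma model is preferred only on strong evidence.
#'
#' @param morphology standard [char_matrix].
#' @param config [mcmc_config].
#' @param steps,ngen_per_step stepping-stone settings.
#' @param seed seed.
#' @return list: `winner` (`"Mk"` or `"Mk+G"`), `bf` (the [bayes_factor()]
#'   row for Mk+G vs Mk) and both `marginals`.
#' @export
morphology_model_choice <- function(morphology, config = mcmc_config(),
                                    steps = 50L, ngen_per_step = 300L,
                                    seed = 1L) {
  k <- max(2L, length(state_labels(morphology)))
  set.seed(seed)
  sch_mk <- partition_scheme(list(all = seq_len(ncol(morphology$x))),
                             mk_model(k = k))
  sch_mkg <- partition_scheme(list(all = seq_len(ncol(morphology$x))),
                              mk_model(k = k, alpha = 1))
  ml_mk <- stepping_stone(morphology, sch_mk, steps = steps, config = config,
                          ngen_per_step = ngen_per_step)
  attr(ml_mk, "hypothesis") <- "Mk"
  ml_mkg <- stepping_stone(morphology, sch_mkg, steps = steps, config = config,
                           ngen_per_step = ngen_per_step)
  attr(ml_mkg, "hypothesis") <- "Mk+G"
  bf <- bayes_factor(ml_mkg, ml_mk)
  winner <- if (bf$two_delta_ln > 10) "Mk+G" else "Mk"
  list(winner = winner, bf = bf,
       marginals = list(Mk = ml_mk, `Mk+G` = ml_mkg))
}
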