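# Free-parameter counts: JC 0; HKY 4 (kappa + 3 free frequencies); GTR 8
# (5 free exchangeabilities + 3 free frequencies); +I and +G add 1 each.
model_k <- function(spec) {
  parts <- toupper(strsplit(gsub("\\s", "", spec), "\\+")[[1]])
  k <- switch(parts[1], JC = 0, JC69 = 0, HKY = 4, HKY85 = 4, GTR = 8,
              stop("unknown family: ", parts[1]))
  k + ("I" %in% parts[-1]) + any(c("G", "GAMMA") %in% parts[-1])
}

# Build a subst_model from a spec string and a free-parameter vector.
spec_to_model <- function(spec, par = NULL) {
  m <- parse_model(spec)
  if (is.null(par)) return(m)
  i <- 0
  grab <- function(n) { v <- par[(i + 1):(i + n)]; i <<- i + n; v }
  if (m$family %in% c("HKY", "GTR")) {
    f <- exp(c(grab(3), 0)); m$freq <- f / sum(f)
  }
  if (m$family == "HKY") m$kappa <- exp(grab(1))
  if (m$family == "GTR") m$rates <- c(exp(grab(5)), 1)
  if (m$pinv > 0) m$pinv <- stats::plogis(grab(1))
  if (!is.null(m$alpha)) m$alpha <- exp(grab(1))
  m
}

spec_start <- function(spec, emp_freq) {
  m <- parse_model(spec)
  par <- numeric(0)
  if (m$family %in% c("HKY", "GTR")) {
    f <- pmax(emp_freq, 1e-4)
    par <- c(par, log(f[1:3] / f[4]))
  }
  if (m$family == "HKY") par <- c(par, log(2))
  if (m$family == "GTR") par <- c(par, rep(0, 5))
  if (m$pinv > 0) par <- c(par, stats::qlogis(0.2))
  if (!is.null(m$alpha)) par <- c(par, log(1))
  par
}

#' Per-partition substitution-model selection by BIC
#'
#' Maximizes the log-likelihood of each candidate model on a fixed reference
#' tree (by default a neighbor-joining tree on JC-corrected distances) and
#' scores it as `BIC = -2 maxlnL + K log(n_sites)`.
#'
#' @param cm a nucleotide [char_matrix].
#' @param cols site subset defining the partition (default all).
#' @param candidates character vector of model specs.
#' @param tree optional reference tree with branch lengths.
#' @return list with `best` (spec string), `model` (fitted [subst_model])
#'   and `table`, a tibble of spec, K, maxlnL, BIC and convergence flags,
#'   sorted by BIC.
#' @export
bic_select <- function(cm, cols = NULL,
                       candidates = c("JC", "HKY", "HKY+I", "HKY+G",
                                      "HKY+I+G", "GTR", "GTR+I", "GTR+G",
                                      "GTR+I+G"),
                       tree = NULL) {
  stopifnot(length(candidates) >= 1, cm$alphabet == "dna")
  if (is.null(cols)) cols <- seq_len(ncol(cm$x))
  if (is.null(tree)) tree <- reference_tree(cm, cols)
  n <- length(cols)
  sym <- cm$x[, cols, drop = FALSE]
  emp <- prop.table(table(factor(sym[sym %in% c("A", "C", "G", "T")],
                                 levels = c("A", "C", "G", "T"))))
  emp <- as.numeric(emp); emp[emp == 0] <- 1e-4; emp <- emp / sum(emp)
  rows <- lapply(candidates, function(spec) {
    par0 <- spec_start(spec, emp)
    obj <- function(p) {
      m <- spec_to_model(spec, p)
      -loglik(tree, m, cm, cols)
    }
    if (length(par0)) {
      fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      # polish
      fit2 <- tryCatch(stats::optim(fit$par, obj, method = "BFGS",
                                    control = list(maxit = 200)),
                       error = function(e) fit)
      if (fit2$value <= fit$value) fit <- fit2
      ll <- -fit$value; conv <- fit$convergence == 0; par <- fit$par
    } else {
      ll <- -obj(numeric(0)); conv <- TRUE; par <- numeric(0)
    }
    K <- model_k(spec)
    tibble::tibble(model = spec, K = K, maxlnL = ll,
                   BIC = -2 * ll + K * log(n), converged = conv,
                   par = list(par))
  })
  tab <- dplyr::arrange(dplyr::bind_rows(rows), .data$BIC)
  if (any(!tab$converged)) {
    warning("optimizer did not converge for: ",
            paste(tab$model[!tab$converged], collapse = ", "))
  }
  best <- tab$model[1]
  list(best = best,
       model = spec_to_model(best, tab$par[[1]]),
       table = dplyr::select(tab, -"par"))
}

# NJ reference tree on JC-corrected distances (p-distances fall back when
# saturation makes the correction undefined); nonpositive branch lengths
# clamped to a small epsilon.
reference_tree <- function(cm, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(cm$x))
  nt <- nrow(cm$x)
  D <- matrix(0, nt, nt, dimnames = list(cm$taxa, cm$taxa))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    p <- as.numeric(p_distance(cm$x[i, cols], cm$x[j, cols]))
    d <- if (p < 0.74) -3 / 4 * log(1 - 4 * p / 3) else p
    D[i, j] <- D[j, i] <- d
  }
  phy <- ape::nj(stats::as.dist(D))
  phy$edge.length[phy$edge.length <= 0] <- 1e-6
  phy
}
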