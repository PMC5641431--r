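#' Discrete character matrices
#'
#' A `char_matrix` holds a rectangular taxa-by-characters matrix of discrete
#' states, either nucleotide data (IUPAC symbols, `-` for gaps, `?`/`N` for
#' missing) or standard multistate data (`0`-`9` plus `?`). Each character
#' carries a partition id and, for morphological data, an anatomical-region
#' tag used by the homoplasy aggregation (one of `coxa`, `prefemur`,
#' `tibiotarsus`, `somatic`, `other`).
#'
#' @param x character matrix (taxa in rows, characters in columns); row names
#'   are taxon labels.
#' @param alphabet `"dna"` or `"standard"`.
#' @param partition integer vector, one entry per character (default all 1).
#' @param region character vector of region tags, one per character; defaults
#'   to `"other"`.
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(x, alphabet = c("dna", "standard"),
                        partition = NULL, region = NULL) {
  alphabet <- match.arg(alphabet)
  x <- as.matrix(x)
  storage.mode(x) <- "character"
  if (is.null(rownames(x))) stop("taxa must be named (row names)")
  taxa <- rownames(x)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  x[] <- toupper(x)
  ok <- if (alphabet == "dna") names(iupac_sets()) else c(as.character(0:9), "?", "-")
  bad <- which(!(x %in% ok))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop(sprintf("unknown symbol '%s' at taxon '%s', character %d",
                 x[bad[1]], taxa[i[1]], i[2]))
  }
  if (is.null(partition)) partition <- rep(1L, ncol(x))
  if (is.null(region)) region <- rep("other", ncol(x))
  rk <- c("coxa", "prefemur", "tibiotarsus", "somatic", "other")
  if (!all(region %in% rk)) {
    stop("region tags must be one of: ", paste(rk, collapse = ", "))
  }
  stopifnot(length(partition) == ncol(x), length(region) == ncol(x))
  structure(list(x = x, taxa = taxa, alphabet = alphabet,
                 partition = as.integer(partition), region = region),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d characters (%s)\n",
              nrow(x$x), ncol(x$x), x$alphabet))
  cat("partitions:", paste(unique(x$partition), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$x)

# IUPAC nucleotide ambiguity sets over the state order A, C, G, T.
iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T", U = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"),
       N = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T"),
       "-" = c("A", "C", "G", "T"))
}

#' State labels of a character matrix
#'
#' For DNA this is `A C G T`; for standard data, the sorted set of digit
#' states observed in the matrix (or `0:(k-1)` when `nstates` is given).
#' @param cm a [char_matrix].
#' @param nstates optional state count for standard data.
#' @keywords internal
state_labels <- function(cm, nstates = NULL) {
  if (cm$alphabet == "dna") return(c("A", "C", "G", "T"))
  if (!is.null(nstates)) return(as.character(seq_len(nstates) - 1L))
  obs <- sort(unique(cm$x[!(cm$x %in% c("?", "-"))]))
  if (!length(obs)) stop("matrix contains no observed states")
  obs
}

# Tip partial-likelihood array, dim (nstates, ncol, ntaxa): cell value 1 for
# every state compatible with the observed symbol (gap/missing = all 1).
tip_partial_array <- function(cm, cols = seq_len(ncol(cm$x)), states = NULL) {
  if (is.null(states)) states <- state_labels(cm)
  s <- length(states)
  ntax <- nrow(cm$x)
  sub <- cm$x[, cols, drop = FALSE]
  arr <- array(0, dim = c(s, length(cols), ntax))
  if (cm$alphabet == "dna") {
    sets <- iupac_sets()
    for (i in seq_len(ntax)) for (j in seq_along(cols)) {
      arr[match(sets[[sub[i, j]]], states), j, i] <- 1
    }
  } else {
    for (i in seq_len(ntax)) for (j in seq_along(cols)) {
      sym <- sub[i, j]
      if (sym %in% c("?", "-")) arr[, j, i] <- 1
      else {
        k <- match(sym, states)
        if (is.na(k)) {
          stop(sprintf("state '%s' (taxon '%s') outside the declared alphabet",
                       sym, cm$taxa[i]))
        }
        arr[k, j, i] <- 1
      }
    }
  }
  arr
}

#' Read an aligned character matrix
#'
#' Reads FASTA (nucleotide) or NEXUS (`dna` or `standard` datatype) into a
#' [char_matrix]. IUPAC ambiguity codes are kept and later expanded to state
#' sets; `-` is recorded as a gap and `?` as missing.
#'
#' @param path file path.
#' @param format `"fasta"` or `"nexus"`; guessed from the extension when
#'   missing.
#' @return a [char_matrix].
#' @export
read_matrix <- function(path, format = c("fasta", "nexus")) {
  if (length(format) > 1) {
    format <- if (grepl("\\.(nex|nexus)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("not a FASTA file: ", path)
    taxa <- sub("^>\\s*", "", lines[hdr])
    taxa <- sub("\\s.*$", "", taxa)
    if (anyDuplicated(taxa)) {
      stop("duplicate taxon label(s): ",
           paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
    }
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
    }, character(1))
    seqs <- gsub("\\s", "", seqs)
    len <- nchar(seqs)
    if (length(unique(len)) > 1) {
      bad <- taxa[which(len != stats::median(len))[1]]
      stop(sprintf("ragged alignment: taxon '%s' has a different length", bad))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- taxa
    char_matrix(m, alphabet = "dna")
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    dt <- regmatches(txt, regexpr("(?i)datatype\\s*=\\s*[A-Za-z]+", txt))
    alphabet <- if (length(dt) && grepl("(?i)standard", dt[1], perl = TRUE))
      "standard" else "dna"
    dat <- ape::read.nexus.data(path)
    taxa <- names(dat)
    if (anyDuplicated(taxa)) {
      stop("duplicate taxon label(s): ",
           paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
    }
    len <- lengths(dat)
    if (length(unique(len)) > 1) {
      stop(sprintf("ragged matrix: taxon '%s' has a different length",
                   taxa[which(len != stats::median(len))[1]]))
    }
    m <- do.call(rbind, dat)
    rownames(m) <- taxa
    char_matrix(m, alphabet = alphabet)
  }
}

#' Write a character matrix
#'
#' @param cm a [char_matrix].
#' @param path output file.
#' @param format `"fasta"` (nucleotide only) or `"nexus"`.
#' @export
write_matrix <- function(cm, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") {
    if (cm$alphabet != "dna") stop("FASTA output requires nucleotide data")
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(cm$x))) {
      writeLines(c(paste0(">", cm$taxa[i]),
                   paste(cm$x[i, ], collapse = "")), con)
    }
  } else {
    dat <- lapply(seq_len(nrow(cm$x)), function(i) cm$x[i, ])
    names(dat) <- cm$taxa
    ape::write.nexus.data(dat, file = path,
                          format = if (cm$alphabet == "dna") "dna" else "standard",
                          interleaved = FALSE)
  }
  invisible(path)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise mismatch proportion; sites with a gap, `?`, `N`, or other
#' ambiguity symbol in either sequence are excluded.
#'
#' @param a,b equal-length character vectors of states (or strings).
#' @return proportion of mismatching compared sites, with attribute
#'   `percent` (same value times 100) and `n` (sites compared).
#' @export
p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(b, "")[[1]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b)) stop("sequences differ in length")
  plain <- c("A", "C", "G", "T", as.character(0:9))
  keep <- a %in% plain & b %in% plain
  n <- sum(keep)
  if (n == 0) stop("no comparable sites")
  p <- sum(a[keep] != b[keep]) / n
  structure(p, percent = 100 * p, n = n)
}

#' Classify characters by parsimony informativeness
#'
#' A character is parsimony-informative when at least two states each occur
#' in at least two taxa; constant when at most one state is observed
#' (missing, gap and ambiguous cells are excluded from the counts).
#'
#' @param cm a [char_matrix].
#' @return a tibble with columns `character`, `class` (factor levels
#'   `constant`, `variable-uninformative`, `parsimony-informative`) and the
#'   observed state count.
#' @export
classify_characters <- function(cm) {
  plain <- c("A", "C", "G", "T", as.character(0:9))
  cls <- character(ncol(cm$x)); nst <- integer(ncol(cm$x))
  for (j in seq_len(ncol(cm$x))) {
    obs <- cm$x[, j]
    obs <- obs[obs %in% plain]
    tab <- table(obs)
    nst[j] <- length(tab)
    cls[j] <- if (length(tab) <= 1) "constant"
      else if (sum(tab >= 2) >= 2) "parsimony-informative"
      else "variable-uninformative"
  }
  tibble::tibble(
    character = seq_len(ncol(cm$x)),
    class = factor(cls, levels = c("constant", "variable-uninformative",
                                   "parsimony-informative")),
    n_states = nst)
}
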