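# Conjoint-triad (CT) encoding of amino-acid sequences. The 20 standard
# residues are clustered into 7 physicochemical classes (dipole and side-chain
# volume), and every contiguous window of three residues is counted by its
# class triple, giving a fixed 7^3 = 343-dimensional count vector per protein.

#' The standard 7-class conjoint-triad residue table
#'
#' Class 1 = \{A, G, V\}, 2 = \{I, L, F, P\}, 3 = \{Y, M, T, S\},
#' 4 = \{H, N, Q, W\}, 5 = \{R, K\}, 6 = \{D, E\}, 7 = \{C\}.
#'
#' @return named integer vector mapping one-letter residue codes to a class
#'   index in 1..7.
#' @export
ct_class_table <- function() {
  c(A = 1L, G = 1L, V = 1L,
    I = 2L, L = 2L, F = 2L, P = 2L,
    Y = 3L, M = 3L, T = 3L, S = 3L,
    H = 4L, N = 4L, Q = 4L, W = 4L,
    R = 5L, K = 5L,
    D = 6L, E = 6L,
    C = 7L)
}

#' Residue class lookup
#'
#' @param residues character vector of one-letter amino-acid codes.
#' @param classes class table (override for non-default groupings).
#' @return integer vector of class indices in 1..7; `NA` for non-standard
#'   codes (B, Z, X, U, O, `*`, ...), which downstream encoding skips.
#' @export
amino_class <- function(residues, classes = ct_class_table()) {
  unname(classes[toupper(residues)])
}

# Flat triad names t<c1><c2><c3> in index order (c3 varies fastest).
ct_triad_names <- function() {
  g <- expand.grid(c3 = 1:7, c2 = 1:7, c1 = 1:7)
  paste0("t", g$c1, g$c2, g$c3)
}

# Core counter: class vector -> list(counts, usable length).
ct_count_core <- function(cls) {
  cls <- cls[!is.na(cls)]
  L <- length(cls)
  v <- if (L < 3) numeric(343) else {
    idx <- (cls[1:(L - 2)] - 1L) * 49L + (cls[2:(L - 1)] - 1L) * 7L + cls[3:L]
    as.numeric(tabulate(idx, nbins = 343))
  }
  names(v) <- ct_triad_names()
  list(counts = v, usable = L)
}

#' Conjoint-triad encoding of one sequence
#'
#' Counts every contiguous residue-class triple `(c1, c2, c3)` at flat index
#' `(c1-1)*49 + (c2-1)*7 + c3`. Non-standard residues are dropped from the
#' sequence before windowing (with a warning giving the skipped count);
#' sequences with fewer than three usable residues yield a zero vector with
#' a warning.
#'
#' @param sequence amino-acid string.
#' @param normalize divide counts by the window count `L - 2` (off by
#'   default; the canonical encoding is raw occurrence counts).
#' @param classes residue class table.
#' @return numeric vector of length 343 (named `t<c1><c2><c3>`); the sum of
#'   the unnormalized vector is `max(0, L - 2)` for `L` usable residues.
#' @export
ct_encode <- function(sequence, normalize = FALSE, classes = ct_class_table()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  cls <- classes[chars]
  skipped <- sum(is.na(cls))
  if (skipped > 0) {
    warning(sprintf("ct_encode: %d non-standard residue(s) skipped", skipped))
  }
  r <- ct_count_core(cls)
  v <- r$counts
  if (r$usable < 3) {
    warning("ct_encode: fewer than 3 usable residues; returning a zero vector")
  } else if (normalize) {
    v <- v / (r$usable - 2)
  }
  attr(v, "skipped") <- skipped
  v
}

#' Conjoint-triad feature matrix for a set of proteins
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param normalize per-row count normalization as in [ct_encode()].
#' @param classes residue class table.
#' @return `length(sequences) x 343` numeric matrix, rows in the order of
#'   `sequences`. A single message reports the total number of skipped
#'   non-standard residues and of too-short sequences.
#' @export
ct_encode_matrix <- function(sequences, normalize = FALSE,
                             classes = ct_class_table()) {
  if (is.null(names(sequences))) stop("sequences must be named by protein id")
  n_skipped <- 0L
  n_short <- 0L
  rows <- lapply(sequences, function(s) {
    cls <- classes[strsplit(toupper(s), "")[[1]]]
    n_skipped <<- n_skipped + sum(is.na(cls))
    r <- ct_count_core(cls)
    if (r$usable < 3) {
      n_short <<- n_short + 1L
      r$counts
    } else if (normalize) {
      r$counts / (r$usable - 2)
    } else {
      r$counts
    }
  })
  if (n_skipped || n_short) {
    message(sprintf(
      "ct_encode_matrix: skipped %d non-standard residue(s); %d sequence(s) shorter than 3 usable residues",
      n_skipped, n_short))
  }
  X <- do.call(rbind, rows)
  rownames(X) <- names(sequences)
  X
}
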