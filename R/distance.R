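#' @export
print.distance_result <- function(x, ...) {
  val <- if (is.na(x$value)) "UNDEFINED (saturated)" else sprintf("%.6f", x$value)
  cat(sprintf("%s distance: %s", x$method, val))
  if (!is.null(x$w_hat)) cat(sprintf("  (w_hat = %.4f)", x$w_hat))
  cat(sprintf("  [n = %d]\n", x$counts$n))
  invisible(x)
}

new_distance_result <- function(value, method, counts, w_hat = NULL) {
  structure(list(value = value, method = method, counts = counts,
                 w_hat = w_hat, saturated = is.na(value) && counts$n > 0L),
            class = "distance_result")
}

#' Classic two-parameter distance from site-pair counts
#'
#' The Kimura two-parameter estimate of substitutions per site,
#' \deqn{K = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q),}
#' with transition proportion `P = n2 / n` and transversion proportion
#' `Q = n3 / n`. Counts should come from gap-free comparisons (complete or
#' pairwise deletion). When a logarithm argument is non-positive the
#' sequences are saturated and the value is `NA` with `saturated = TRUE` —
#' an explicit "undefined" result, not an error.
#'
#' @param counts a `"pair_counts"` object (see [count_pair()]).
#' @return A `"distance_result"` with fields `value` (`NA` if undefined),
#'   `method`, `counts`, `saturated`.
#' @export
k2p_distance <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$n == 0L)
    return(new_distance_result(NA_real_, "k2p", counts))
  P <- counts$n2 / counts$n
  Q <- counts$n3 / counts$n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  value <- if (a1 <= 0 || a2 <= 0) NA_real_ else -log(a1) / 2 - log(a2) / 4
  new_distance_result(value, "k2p", counts)
}

#' Gap-aware two-parameter distance from site-pair counts
#'
#' Estimates the total number of nucleotide changes per site — substitutions
#' plus insertions and deletions — separating two aligned sequences:
#' \deqn{K = \tfrac34 \hat w \log \hat w
#'   - \tfrac{\hat w}{2} \log\big[(S - P)\sqrt{S + P - Q}\big],}
#' where `S`, `P`, `Q` are the identical, transition and transversion
#' proportions over all `n` compared sites (gap columns included) and
#' `w_hat` is the nucleotide-existence probability, estimated as the
#' observed fraction of nucleotide characters among the `2n` characters of
#' the pair: `w_hat = S + P + Q + G/2`. Under this estimator the formula is
#' the exact composition of the model's inversion formulas with the expected
#' total change count. For a gap-free pair `w_hat = 1` and the value reduces
#' exactly to the classic two-parameter distance.
#'
#' Saturated proportions (`S - P <= 0` or `S + P - Q <= 0`) give `NA` with
#' `saturated = TRUE` rather than an error.
#'
#' @param counts a `"pair_counts"` object from `"keep_gaps"` counting.
#' @return A `"distance_result"` with fields `value`, `method`, `counts`,
#'   `w_hat`, `saturated`.
#' @examples
#' k2p_gap_distance(count_pair("ACGTAC-T", "ACGTGCT-"))
#' @export
k2p_gap_distance <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$n == 0L)
    return(new_distance_result(NA_real_, "k2p_gap", counts))
  n <- counts$n
  S <- counts$n1 / n
  P <- counts$n2 / n
  Q <- counts$n3 / n
  G <- counts$n_g / n
  w_hat <- S + P + Q + G / 2
  d1 <- S - P
  d2 <- S + P - Q
  value <- if (w_hat <= 0 || d1 <= 0 || d2 <= 0) NA_real_ else
    3 / 4 * w_hat * log(w_hat) - w_hat / 2 * log(d1 * sqrt(d2))
  new_distance_result(value, "k2p_gap", counts, w_hat = w_hat)
}

# Coerce an alignment (named character vector of equal-length strings, a
# character matrix with rows = sequences, an ape DNAbin matrix, or a
# "labeled_alignment" from the simulator) to an integer state-code matrix,
# sites x sequences, with sequence labels as column names.
alignment_codes <- function(alignment, gap_chars = "-") {
  if (inherits(alignment, "labeled_alignment")) {
    codes <- alignment$codes
  } else if (inherits(alignment, "DNAbin")) {
    ch <- toupper(as.character(alignment))
    if (is.list(ch)) ch <- do.call(rbind, ch)
    codes <- apply(ch, 1L, encode_states, gap_chars = gap_chars)
    colnames(codes) <- rownames(ch)
  } else if (is.matrix(alignment) && is.character(alignment)) {
    codes <- apply(alignment, 1L, encode_states, gap_chars = gap_chars)
    colnames(codes) <- rownames(alignment)
  } else if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("sequences differ in length; the input must be aligned", call. = FALSE)
    codes <- vapply(alignment, encode_states, integer(lens[1L]),
                    gap_chars = gap_chars)
    colnames(codes) <- names(alignment)
  } else {
    stop("unsupported alignment representation", call. = FALSE)
  }
  if (!is.matrix(codes)) codes <- matrix(codes, ncol = length(alignment))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("seq", seq_len(ncol(codes)))
  codes
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all pairwise distances under one of three gap treatments:
#' \describe{
#'   \item{`k2p_gap`}{gap columns kept; the gap-aware estimator
#'     [k2p_gap_distance()].}
#'   \item{`k2p_complete`}{every column containing a gap in \emph{any}
#'     sequence is removed first (complete deletion), then the classic
#'     [k2p_distance()] per pair.}
#'   \item{`k2p_pairwise`}{gap columns removed independently per pair
#'     (pairwise deletion), then [k2p_distance()].}
#' }
#' Saturated or empty comparisons yield `NA` cells; they are preserved in
#' the matrix and only replaced by [replace_undefined()] when a finite
#' matrix is required (e.g. for tree building).
#'
#' @param alignment aligned sequences: named character vector of equal-length
#'   strings, character matrix (rows = sequences), `DNAbin` matrix, or a
#'   simulator `"labeled_alignment"`.
#' @param method one of `"k2p_gap"`, `"k2p_complete"`, `"k2p_pairwise"`.
#' @param gap_chars characters treated as gaps.
#' @return A symmetric numeric matrix with zero diagonal, `NA` for
#'   undefined cells, sequence labels as dimnames and the method recorded in
#'   `attr(, "method")`.
#' @export
distance_matrix <- function(alignment,
                            method = c("k2p_gap", "k2p_complete", "k2p_pairwise"),
                            gap_chars = "-") {
  method <- match.arg(method)
  codes <- alignment_codes(alignment, gap_chars)
  m <- ncol(codes)
  if (m < 2L) stop("need at least 2 sequences", call. = FALSE)
  labels <- colnames(codes)
  if (anyDuplicated(labels)) stop("duplicate sequence labels", call. = FALSE)

  if (method == "k2p_complete") {
    keep <- rowSums(codes == 5L) == 0L
    codes <- codes[keep, , drop = FALSE]
  }
  drop_gaps <- method == "k2p_pairwise"
  gapfree <- method != "k2p_gap"

  D <- matrix(0, m, m, dimnames = list(labels, labels))
  if (nrow(codes) == 0L) {
    D[] <- NA_real_
    diag(D) <- 0
    attr(D, "method") <- method
    return(D)
  }
  clean <- !any(codes == 0L)
  for (i in seq_len(m - 1L)) {
    ci <- codes[, i]
    for (j in (i + 1L):m) {
      cj <- codes[, j]
      if (clean) {
        cat <- .category_table[ci + (cj - 1L) * 5L]
        if (drop_gaps) cat <- cat[cat < 4L]
        tab <- tabulate(cat, nbins = 5L)
        n <- length(cat)
        if (n == 0L) { D[i, j] <- D[j, i] <- NA_real_; next }
        if (gapfree) {
          P <- tab[2L] / n; Q <- tab[3L] / n
          a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
          v <- if (a1 <= 0 || a2 <= 0) NA_real_ else -log(a1) / 2 - log(a2) / 4
        } else {
          S <- tab[1L] / n; P <- tab[2L] / n; Q <- tab[3L] / n; G <- tab[4L] / n
          w <- S + P + Q + G / 2
          d1 <- S - P; d2 <- S + P - Q
          v <- if (w <= 0 || d1 <= 0 || d2 <= 0) NA_real_ else
            3 / 4 * w * log(w) - w / 2 * log(d1 * sqrt(d2))
        }
      } else {
        cnt <- count_pair_codes(ci, cj, drop_gaps = drop_gaps)
        v <- if (gapfree) k2p_distance(cnt)$value else k2p_gap_distance(cnt)$value
      }
      D[i, j] <- D[j, i] <- v
    }
  }
  attr(D, "method") <- method
  D
}

#' Replace undefined cells of a distance matrix
#'
#' Saturated comparisons leave `NA` cells that distance-based tree building
#' cannot consume. This substitutes a large finite surrogate: by default
#' `factor` (2) times the largest finite off-diagonal entry, i.e. "farther
#' than anything measured". If no off-diagonal entry is finite, all cells are
#' set to `constant_if_empty` (1.0), which yields a star-like tied matrix.
#'
#' @param D distance matrix as returned by [distance_matrix()].
#' @param factor multiplier on the largest finite off-diagonal entry.
#' @param constant if non-`NULL`, use this fixed value for every `NA` cell
#'   instead of the factor rule.
#' @param constant_if_empty value used when the whole matrix is undefined.
#' @return The matrix with every cell finite; `attr(, "n_replaced")` records
#'   how many cells (upper triangle) were substituted.
#' @export
replace_undefined <- function(D, factor = 2, constant = NULL,
                              constant_if_empty = 1.0) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  off <- D[upper.tri(D)]
  n_na <- sum(is.na(off))
  if (n_na > 0L) {
    fill <- if (!is.null(constant)) {
      constant
    } else if (any(is.finite(off))) {
      factor * max(off[is.finite(off)])
    } else {
      constant_if_empty
    }
    D[is.na(D)] <- fill
    diag(D) <- 0
  }
  attr(D, "n_replaced") <- n_na
  D
}
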