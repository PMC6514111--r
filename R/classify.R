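# Internal state coding: A=1, C=2, G=3, T=4, gap=5; 0 = excluded (anything
# outside the model's five-state alphabet, e.g. IUPAC ambiguity codes or N).
STATE_LETTERS <- c("A", "C", "G", "T", "-")

CATEGORY_LEVELS <- c("identical", "transition", "transversion",
                     "nuc_gap", "gap_gap", "excluded")

# 5x5 category lookup over the coded states, values indexing CATEGORY_LEVELS.
.category_table <- local({
  m <- matrix(0L, 5, 5)
  for (i in 1:4) for (j in 1:4) {
    m[i, j] <- if (i == j) 1L else 3L  # default transversion
  }
  m[1, 3] <- m[3, 1] <- 2L  # A<->G transition
  m[2, 4] <- m[4, 2] <- 2L  # C<->T transition
  m[5, 1:4] <- 4L; m[1:4, 5] <- 4L
  m[5, 5] <- 5L
  m
})

#' Encode aligned sequence characters as model states
#'
#' Normalizes to uppercase, maps U to T, and codes A, C, G, T, gap as
#' integers 1..5. Any other character (IUPAC ambiguity codes, N, ?) codes as
#' 0 and the site is excluded from pair comparisons: the model has no
#' ambiguity states.
#'
#' @param x character vector of single aligned characters, or a single
#'   string which is split into characters.
#' @param gap_chars characters treated as the gap state; `"-"` by default,
#'   add `"."` for dialects that use it.
#' @return Integer vector of state codes (0 = excluded).
#' @keywords internal
encode_states <- function(x, gap_chars = "-") {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  x <- toupper(x)
  code <- integer(length(x))
  code[x == "A"] <- 1L
  code[x == "C"] <- 2L
  code[x == "G"] <- 3L
  code[x == "T" | x == "U"] <- 4L
  code[x %in% gap_chars] <- 5L
  code
}

#' Classify one pair of homologous aligned sites
#'
#' Each of the 25 combinations of the five states \{A, C, G, T/U, gap\} maps
#' to exactly one category: equal nucleotides are `identical`; purine
#' interchanges (A/G) and pyrimidine interchanges (C/T) are `transition`;
#' purine--pyrimidine pairs are `transversion`; one gap gives `nuc_gap`; two
#' gaps give `gap_gap`. A character outside the alphabet on either side
#' makes the site `excluded`.
#'
#' @param a,b single aligned characters (case-insensitive; U equals T).
#' @param gap_chars characters treated as gaps (see [encode_states()]).
#' @return One of `"identical"`, `"transition"`, `"transversion"`,
#'   `"nuc_gap"`, `"gap_gap"`, `"excluded"`. Vectorized over `a`, `b`.
#' @examples
#' classify_site_pair("A", "G")  # transition
#' classify_site_pair("U", "G")  # transversion
#' classify_site_pair("C", "-")  # nuc_gap
#' @export
classify_site_pair <- function(a, b, gap_chars = "-") {
  ca <- encode_states(a, gap_chars)
  cb <- encode_states(b, gap_chars)
  if (length(ca) != length(cb))
    stop("'a' and 'b' must have equal length", call. = FALSE)
  out <- rep(6L, length(ca))
  ok <- ca > 0L & cb > 0L
  out[ok] <- .category_table[cbind(ca[ok], cb[ok])]
  CATEGORY_LEVELS[out]
}

new_pair_counts <- function(tab, n_excluded, alignment_length) {
  tab <- as.integer(tab)
  structure(list(n = sum(tab),
                 n1 = tab[[1L]], n2 = tab[[2L]], n3 = tab[[3L]],
                 n_g = tab[[4L]], n_n = tab[[5L]],
                 n_excluded = n_excluded,
                 alignment_length = alignment_length),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf(
    "Site-pair counts over %d compared sites (alignment length %d, %d excluded):\n",
    x$n, x$alignment_length, x$n_excluded))
  cat(sprintf("  identical %d, transition %d, transversion %d, nuc-gap %d, gap-gap %d\n",
              x$n1, x$n2, x$n3, x$n_g, x$n_n))
  invisible(x)
}

# Core counting on coded state vectors; used by both the public API and the
# distance-matrix fast path.
count_pair_codes <- function(ca, cb, drop_gaps = FALSE) {
  align_len <- length(ca)
  ok <- ca > 0L & cb > 0L
  cat <- .category_table[cbind(ca[ok], cb[ok])]
  n_excluded <- align_len - length(cat)
  if (drop_gaps) {
    gap_sites <- cat >= 4L
    n_excluded <- n_excluded + sum(gap_sites)
    cat <- cat[!gap_sites]
  }
  tab <- tabulate(cat, nbins = 5L)
  new_pair_counts(tab, n_excluded, align_len)
}

#' Count site-pair categories for one aligned sequence pair
#'
#' Classifies every alignment column of the pair with [classify_site_pair()]
#' and accumulates the counts underlying all distance estimators: `n1`
#' identical, `n2` transition-type, `n3` transversion-type, `n_g`
#' nucleotide--gap and `n_n` gap--gap sites, out of `n` compared sites.
#' In `"drop_gap_sites"` mode the gap-containing columns are moved to
#' `n_excluded` (the classic pairwise-deletion treatment); in `"keep_gaps"`
#' mode they stay in `n` (the gap-aware treatment). Columns with characters
#' outside the alphabet never enter `n`.
#'
#' @param seq_a,seq_b aligned sequences of equal length: single strings or
#'   character vectors.
#' @param mode `"keep_gaps"` (default) or `"drop_gap_sites"`.
#' @param gap_chars characters treated as gaps.
#' @return A `"pair_counts"` object with fields `n`, `n1`, `n2`, `n3`,
#'   `n_g`, `n_n`, `n_excluded`, `alignment_length`.
#' @examples
#' count_pair("AC-T", "GC--")                      # keeps the gap columns
#' count_pair("AC-T", "GC--", "drop_gap_sites")    # n = 2, 2 excluded
#' @export
count_pair <- function(seq_a, seq_b, mode = c("keep_gaps", "drop_gap_sites"),
                       gap_chars = "-") {
  mode <- match.arg(mode)
  ca <- encode_states(seq_a, gap_chars)
  cb <- encode_states(seq_b, gap_chars)
  if (length(ca) != length(cb))
    stop("aligned sequences differ in length (", length(ca), " vs ",
         length(cb), ")", call. = FALSE)
  if (length(ca) == 0L) stop("empty alignment", call. = FALSE)
  count_pair_codes(ca, cb, drop_gaps = (mode == "drop_gap_sites"))
}
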