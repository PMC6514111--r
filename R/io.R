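# Atomic text write: write to a temp file in the target directory, then
# rename over the destination.
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Reads aligned nucleotide sequences (gap characters allowed), normalizes
#' them (uppercase, U to T) and codes them over the five-state alphabet.
#' Characters outside \{A, C, G, T, U, gap\} are kept as excluded states and
#' dropped per pair at comparison time. All records must have equal length.
#'
#' @param path FASTA file path.
#' @param gap_chars characters treated as gaps (default `"-"`).
#' @return A `"labeled_alignment"`.
#' @export
read_aligned_fasta <- function(path, gap_chars = "-") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf(
      "sequences are not aligned: record %d ('%s') has length %d, expected %d",
      bad, ids[bad], lens[bad], lens[1L]), call. = FALSE)
  }
  codes <- vapply(recs, function(r) encode_states(as.character(r), gap_chars),
                  integer(lens[1L]))
  if (!is.matrix(codes)) codes <- matrix(codes, ncol = length(recs))
  new_labeled_alignment(codes, unname(ids))
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment a `"labeled_alignment"` (or anything
#'   [distance_matrix()] accepts).
#' @param path output path; written atomically.
#' @return The path, invisibly.
#' @export
write_aligned_fasta <- function(alignment, path) {
  codes <- alignment_codes(alignment)
  letters5 <- c(STATE_LETTERS, "N")
  lines <- character(2L * ncol(codes))
  for (i in seq_len(ncol(codes))) {
    cl <- codes[, i]
    cl[cl == 0L] <- 6L
    lines[2L * i - 1L] <- paste0(">", colnames(codes)[i])
    lines[2L * i] <- paste(letters5[cl], collapse = "")
  }
  write_atomic(lines, path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' Header line with the taxon count, then one row per taxon: the label,
#' followed by the distances at 6 decimal places; undefined cells are
#' written as `NA` in both symmetric positions.
#'
#' @param D matrix from [distance_matrix()].
#' @param path output path; written atomically.
#' @return The path, invisibly.
#' @export
write_phylip_matrix <- function(D, path) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  fmt_cell <- function(v) if (is.na(v)) "NA" else sprintf("%.6f", v)
  rows <- vapply(seq_len(nrow(D)), function(i) {
    paste(c(rownames(D)[i], vapply(D[i, ], fmt_cell, character(1))),
          collapse = "\t")
  }, character(1))
  write_atomic(c(sprintf("%5d", nrow(D)), rows), path)
}

#' Read a square PHYLIP distance matrix
#'
#' Counterpart of [write_phylip_matrix()]; `NA` cells are read back as
#' undefined distances.
#'
#' @param path file path.
#' @return Symmetric numeric matrix with labels as dimnames.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP matrix: ", path, call. = FALSE)
  labels <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    labels[i] <- parts[1L]
    D[i, ] <- suppressWarnings(as.numeric(parts[-1L]))
  }
  dimnames(D) <- list(labels, labels)
  D
}

#' Write a tree in Newick format
#'
#' @param tree a `"phylo"` tree.
#' @param path output path; written atomically.
#' @param clamp_negative if `TRUE`, negative branch lengths (which
#'   neighbor joining can produce; topology is unaffected) are clamped to 0
#'   in the output.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path, clamp_negative = FALSE) {
  if (clamp_negative && !is.null(tree$edge.length))
    tree$edge.length <- pmax(tree$edge.length, 0)
  write_atomic(ape::write.tree(tree), path)
}

#' Read a Newick tree
#'
#' @param path file path.
#' @return A `"phylo"` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot parse Newick file: ", path, call. = FALSE)
  tree
}

#' Read a sequence-id to species table
#'
#' Tab-separated file with a header and two columns, `sequence_id` and
#' `species`.
#'
#' @param path file path.
#' @return Data frame with columns `sequence_id`, `species`.
#' @export
read_species_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_species_labeling(tab)
}

#' Long-format pairwise distance table
#'
#' One row per unordered sequence pair (id_a before id_b in label order)
#' with the site-category counts, the estimated nucleotide-existence
#' probability (gap-aware method only) and the distance (`NA` when
#' saturated).
#'
#' @param alignment input alignment (see [distance_matrix()]).
#' @param method distance method, as in [distance_matrix()].
#' @param gap_chars characters treated as gaps.
#' @return Data frame with columns `id_a`, `id_b`, `method`, `n`, `n1`,
#'   `n2`, `n3`, `n_g`, `n_n`, `w_hat`, `distance`.
#' @export
pair_table <- function(alignment,
                       method = c("k2p_gap", "k2p_complete", "k2p_pairwise"),
                       gap_chars = "-") {
  method <- match.arg(method)
  codes <- alignment_codes(alignment, gap_chars)
  if (method == "k2p_complete")
    codes <- codes[rowSums(codes == 5L) == 0L, , drop = FALSE]
  labels <- colnames(codes)
  m <- length(labels)
  idx <- utils::combn(m, 2L)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1L, k]; j <- idx[2L, k]
    cnt <- count_pair_codes(codes[, i], codes[, j],
                            drop_gaps = (method == "k2p_pairwise"))
    res <- if (method == "k2p_gap") k2p_gap_distance(cnt) else k2p_distance(cnt)
    a <- labels[i]; b <- labels[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    rows[[k]] <- data.frame(
      id_a = a, id_b = b, method = method,
      n = cnt$n, n1 = cnt$n1, n2 = cnt$n2, n3 = cnt$n3,
      n_g = cnt$n_g, n_n = cnt$n_n,
      w_hat = if (is.null(res$w_hat)) NA_real_ else res$w_hat,
      distance = res$value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a data frame as a TSV file
#'
#' Header included, no quoting or row names; written atomically.
#'
#' @param df data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path))
    stop("cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}
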