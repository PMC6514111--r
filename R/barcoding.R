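# Normalize a species labeling (data.frame with sequence_id/species columns,
# or a named character vector id -> species) to a two-column data.frame.
as_species_labeling <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("sequence_id", "species") %in% names(labels)))
      stop("labeling data frame needs columns 'sequence_id' and 'species'",
           call. = FALSE)
    out <- data.frame(sequence_id = as.character(labels$sequence_id),
                      species = as.character(labels$species),
                      stringsAsFactors = FALSE)
  } else if (is.character(labels) && !is.null(names(labels))) {
    out <- data.frame(sequence_id = names(labels),
                      species = unname(labels), stringsAsFactors = FALSE)
  } else {
    stop("'labels' must be a data frame or a named character vector",
         call. = FALSE)
  }
  if (anyDuplicated(out$sequence_id))
    stop("duplicate sequence ids in labeling", call. = FALSE)
  if (any(!nzchar(out$species)) || any(is.na(out$species)))
    stop("species names must be non-empty", call. = FALSE)
  out
}

#' Partition sequence pairs into intra- and interspecific sets
#'
#' Every unordered pair of sequences is assigned to exactly one set:
#' intraspecific if both sequences carry the same species label,
#' interspecific otherwise. Intraspecific pairs exist only for species
#' represented by at least two sequences.
#'
#' @param labels species labeling: a data frame with columns `sequence_id`
#'   and `species`, or a named character vector mapping id to species.
#' @return A list with two character matrices (`intra`, `inter`), each with
#'   columns `id_a`, `id_b` (id_a < id_b in input order); the counts always
#'   satisfy `nrow(intra) + nrow(inter) == choose(n, 2)`.
#' @export
partition_pairs <- function(labels) {
  lab <- as_species_labeling(labels)
  n <- nrow(lab)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  idx <- utils::combn(n, 2L)
  same <- lab$species[idx[1L, ]] == lab$species[idx[2L, ]]
  mk <- function(sel) {
    m <- cbind(id_a = lab$sequence_id[idx[1L, sel]],
               id_b = lab$sequence_id[idx[2L, sel]])
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  list(intra = mk(same), inter = mk(!same))
}

# Pull pairwise distances for an id-pair matrix out of a distance matrix.
pair_distances <- function(D, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  D[cbind(match(pairs[, 1L], rownames(D)), match(pairs[, 2L], colnames(D)))]
}

#' Overlap between intra- and interspecific distances
#'
#' The degree of overlap between the two distance distributions: the
#' percentage of interspecific sequence pairs whose distance is strictly
#' less than the maximum intraspecific distance. A pair exactly equal to the
#' maximum is not in the overlap zone. Undefined (`NA`) distances are
#' excluded before the computation.
#'
#' @param intra,inter numeric vectors of intra- and interspecific distances.
#' @return Percentage in \[0, 100\], or `NA` if either set is empty after
#'   removing undefined values.
#' @examples
#' overlap_percentage(c(0, 0.01, 0.02), c(0.015, 0.05, 0.10, 0.30)) # 25
#' @export
overlap_percentage <- function(intra, inter) {
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (length(intra) == 0L || length(inter) == 0L) return(NA_real_)
  100 * sum(inter < max(intra)) / length(inter)
}

#' Overlap after trimming the distribution tails
#'
#' Removes the `ceiling(trim * N)` largest intraspecific distances and the
#' `ceiling(trim * N)` smallest interspecific distances (exact-count removal
#' after a stable sort; ties are not grouped), then recomputes
#' [overlap_percentage()]. With `trim = 0` this equals the untrimmed
#' overlap.
#'
#' @inheritParams overlap_percentage
#' @param trim fraction of each tail to discard, in \[0, 1); default 0.05.
#' @return Percentage in \[0, 100\], or `NA` if trimming empties a set.
#' @export
trimmed_overlap_percentage <- function(intra, inter, trim = 0.05) {
  if (!is.numeric(trim) || trim < 0 || trim >= 1)
    stop("'trim' must lie in [0, 1)", call. = FALSE)
  intra <- sort(intra[!is.na(intra)])
  inter <- sort(inter[!is.na(inter)])
  k_intra <- ceiling(trim * length(intra))
  k_inter <- ceiling(trim * length(inter))
  intra_kept <- if (k_intra > 0) utils::head(intra, -k_intra) else intra
  inter_kept <- if (k_inter > 0) utils::tail(inter, -k_inter) else inter
  overlap_percentage(intra_kept, inter_kept)
}

#' Summary of intra- vs interspecific distance structure
#'
#' Computes the standard barcoding-gap diagnostics from a distance matrix
#' and a species labeling: pair counts, means and standard deviations of the
#' intra- and interspecific distances, the maximum intraspecific distance,
#' the overlap and trimmed overlap percentages, and the number of
#' interspecific sequence pairs (and of distinct species pairs) at exactly
#' zero distance. Undefined distances are excluded from every statistic and
#' reported as separate counts.
#'
#' @param D distance matrix from [distance_matrix()] (labels must cover all
#'   sequence ids in `labels`).
#' @param labels species labeling (see [partition_pairs()]).
#' @param trim tail fraction for the trimmed overlap.
#' @param sd_type `"population"` (divide by N, default) or `"sample"`
#'   (divide by N - 1).
#' @return An `"overlap_summary"` list.
#' @export
summarize_overlap <- function(D, labels, trim = 0.05,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  lab <- as_species_labeling(labels)
  missing_ids <- setdiff(lab$sequence_id, rownames(D))
  if (length(missing_ids) > 0L)
    stop("ids absent from distance matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  parts <- partition_pairs(lab)
  d_intra <- pair_distances(D, parts$intra)
  d_inter <- pair_distances(D, parts$inter)
  n_undef_intra <- sum(is.na(d_intra))
  n_undef_inter <- sum(is.na(d_inter))
  di <- d_intra[!is.na(d_intra)]
  de <- d_inter[!is.na(d_inter)]
  sdev <- function(x) {
    if (length(x) == 0L) return(NA_real_)
    if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
  }
  zero_sel <- !is.na(d_inter) & d_inter == 0
  zero_pairs <- parts$inter[zero_sel, , drop = FALSE]
  sp <- stats::setNames(lab$species, lab$sequence_id)
  n_zero_species <- if (nrow(zero_pairs) == 0L) 0L else {
    sp_pairs <- apply(zero_pairs, 1L, function(p) {
      s <- sort(c(sp[[p[1L]]], sp[[p[2L]]]))
      paste(s, collapse = "\r")
    })
    length(unique(sp_pairs))
  }
  structure(list(
    n_intra_pairs = nrow(parts$intra),
    n_inter_pairs = nrow(parts$inter),
    n_undefined_intra = n_undef_intra,
    n_undefined_inter = n_undef_inter,
    mean_intra = if (length(di)) mean(di) else NA_real_,
    sd_intra = sdev(di),
    max_intra = if (length(di)) max(di) else NA_real_,
    mean_inter = if (length(de)) mean(de) else NA_real_,
    sd_inter = sdev(de),
    overlap_pct = overlap_percentage(di, de),
    trimmed_overlap_pct = trimmed_overlap_percentage(di, de, trim),
    trim = trim,
    sd_type = sd_type,
    n_zero_inter_seq_pairs = sum(zero_sel),
    n_zero_inter_species_pairs = n_zero_species),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  fmt <- function(m, s) if (is.na(m)) "absent" else sprintf("%.4f +/- %.4f", m, s)
  cat("Intra-/interspecific distance summary\n")
  cat(sprintf("  intraspecific pairs: %d (undefined: %d), mean %s, max %s\n",
              x$n_intra_pairs, x$n_undefined_intra,
              fmt(x$mean_intra, x$sd_intra),
              if (is.na(x$max_intra)) "absent" else sprintf("%.4f", x$max_intra)))
  cat(sprintf("  interspecific pairs: %d (undefined: %d), mean %s\n",
              x$n_inter_pairs, x$n_undefined_inter,
              fmt(x$mean_inter, x$sd_inter)))
  cat(sprintf("  overlap: %.1f%%; trimmed (%.0f%% tails): %.1f%%\n",
              x$overlap_pct, 100 * x$trim, x$trimmed_overlap_pct))
  cat(sprintf("  zero-distance interspecific pairs: %d sequence pairs, %d species pairs\n",
              x$n_zero_inter_seq_pairs, x$n_zero_inter_species_pairs))
  invisible(x)
}

#' Per-species sequence counts of the Physalis ITS2 barcoding study
#'
#' The published per-species sequence counts for the 86 ITS2 sequences of 45
#' Physalis species, shipped as a plain-text table. These counts determine
#' the intra-/interspecific pair bookkeeping (113 intraspecific pairs from
#' the 17 species with at least two sequences; 3542 interspecific pairs;
#' 3655 total) without requiring the sequences themselves.
#'
#' @return Data frame with columns `species` and `n_sequences`.
#' @export
physalis_species_counts <- function() {
  path <- system.file("extdata", "physalis_species_counts.tsv",
                      package = "k2pgap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Expand per-species counts into a pseudo-labeling
#'
#' Turns a species/count table into a concrete [partition_pairs()] labeling
#' by minting sequential sequence ids per species — sufficient for all
#' pair-count bookkeeping, which depends only on the counts.
#'
#' @param counts data frame with columns `species` and `n_sequences`.
#' @return Data frame with columns `sequence_id`, `species`.
#' @export
expand_species_counts <- function(counts) {
  stopifnot(all(c("species", "n_sequences") %in% names(counts)))
  if (any(counts$n_sequences < 1)) stop("counts must be >= 1", call. = FALSE)
  species <- rep(counts$species, counts$n_sequences)
  ord <- sequence(counts$n_sequences)
  data.frame(
    sequence_id = paste0(gsub("[^A-Za-z0-9]+", "_", species), "_", ord),
    species = species, stringsAsFactors = FALSE)
}
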