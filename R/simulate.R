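# Derive a 31-bit substream seed from the master seed and replicate/condition
# identifiers, so each replicate of each condition uses an independent,
# order-independent stream (all arithmetic kept < 2^53 to stay exact).
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (x in c(...)) {
    h <- (h * 69069 + as.double(x) %% 2147483647 + 1) %% 2147483647
  }
  as.integer(h)
}

#' Simulation configuration for the tree-accuracy benchmark
#'
#' Describes one benchmark condition: sequences of `seq_length` sites
#' evolving along a perfect binary tree with `n_taxa` leaves, where at each
#' branch every site moves to each of the 4 other states of
#' \{A, C, G, T, gap\} with probability `p_change` (so the total per-site
#' per-branch change probability is `4 * p_change`).
#'
#' @param n_taxa leaf count, a power of 2, at least 4.
#' @param seq_length number of sites in the ancestral sequence.
#' @param p_change per-site per-branch probability of change to each
#'   alternative state; at most 1/4.
#' @param n_replicates number of independent replicates.
#' @param seed master seed; each replicate derives its own substream.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(n_taxa, seq_length, p_change,
                              n_replicates = 100L, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 4 ||
      bitwAnd(as.integer(n_taxa), as.integer(n_taxa) - 1L) != 0L)
    stop("'n_taxa' must be a power of 2, at least 4", call. = FALSE)
  if (!is.numeric(seq_length) || seq_length < 1)
    stop("'seq_length' must be a positive integer", call. = FALSE)
  if (!is.numeric(p_change) || p_change < 0 || p_change > 0.25)
    stop("'p_change' must lie in [0, 1/4]", call. = FALSE)
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa),
                 seq_length = as.integer(seq_length),
                 p_change = as.double(p_change),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Random ancestral sequence
#'
#' Draws `seq_length` sites i.i.d. uniformly over the four nucleotides
#' (never a gap): the root state of every simulated replicate.
#'
#' @param seq_length number of sites.
#' @return Character vector of `seq_length` letters in \{A, C, G, T\}.
#' @export
generate_ancestor <- function(seq_length) {
  if (!is.numeric(seq_length) || length(seq_length) != 1L || seq_length < 1)
    stop("'seq_length' must be a positive integer", call. = FALSE)
  STATE_LETTERS[sample.int(4L, seq_length, replace = TRUE)]
}

# Core single-branch evolution on coded states (matrix or vector): one draw
# per site per branch; with probability 4 p the site moves to one of the
# other 4 states of {A,C,G,T,-}, each equally likely. Gaps can revert to
# nucleotides (insertion) under the same rule.
evolve_codes <- function(codes, p_change) {
  changed <- stats::runif(length(codes)) < 4 * p_change
  n_ch <- sum(changed)
  if (n_ch > 0L) {
    offset <- sample.int(4L, n_ch, replace = TRUE)
    codes[changed] <- (codes[changed] - 1L + offset) %% 5L + 1L
  }
  codes
}

#' Evolve a sequence along one branch
#'
#' Applies the five-state equal-probability change model for a single branch:
#' each site independently stays with probability `1 - 4 p_change` or
#' becomes one of the four other states of \{A, C, G, T, gap\}, each with
#' probability `p_change`. A single draw per site — the model is a
#' per-branch change probability, not a rate, so there are no multiple hits
#' within a branch.
#'
#' @param seq sequence as a character vector or single string over
#'   \{A, C, G, T, -\}.
#' @param p_change per-site probability of change to each other state.
#' @return Character vector of evolved states.
#' @export
evolve_branch <- function(seq, p_change) {
  if (p_change < 0 || p_change > 0.25)
    stop("'p_change' must lie in [0, 1/4]", call. = FALSE)
  codes <- encode_states(seq)
  if (any(codes == 0L))
    stop("sequence contains characters outside {A, C, G, T, U, -}", call. = FALSE)
  STATE_LETTERS[evolve_codes(codes, p_change)]
}

new_labeled_alignment <- function(codes, ids, replicate = NA_integer_,
                                  config = NULL) {
  colnames(codes) <- ids
  structure(list(ids = ids, codes = codes,
                 replicate = replicate, config = config),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("Labeled alignment: %d sequences x %d sites\n",
              ncol(x$codes), nrow(x$codes)))
  invisible(x)
}

#' Extract alignment sequences as character strings
#'
#' @param x a `"labeled_alignment"`.
#' @param ... unused.
#' @return Named character vector of aligned sequences ('-' for gaps;
#'   excluded states render as 'N').
#' @export
as.character.labeled_alignment <- function(x, ...) {
  letters6 <- c(STATE_LETTERS, "N")
  out <- apply(x$codes, 2L, function(cl) {
    cl[cl == 0L] <- 6L
    paste(letters6[cl], collapse = "")
  })
  names(out) <- x$ids
  out
}

#' Simulate one benchmark replicate
#'
#' Generates a random ancestor and evolves it down every edge of the perfect
#' binary tree with [evolve_branch()]'s five-state model, one change draw
#' per site per branch on every edge. Because the model replaces states in a
#' fixed-length sequence (a deletion writes a gap, an insertion overwrites
#' one), the leaf sequences are positionally homologous by construction and
#' need no realignment. The replicate's RNG substream is derived from the
#' config seed and `replicate`, so replicates are order-independent and any
#' two methods evaluated on the same `(config, replicate)` see identical
#' data.
#'
#' @param config a [simulation_config()].
#' @param replicate replicate index (1-based).
#' @return A list with `alignment` (a `"labeled_alignment"` with leaves
#'   `t1 ... tn`) and `tree` (the rooted model topology, see
#'   [perfect_binary_tree()]).
#' @export
simulate_replicate <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  seed_r <- derive_seed(config$seed, replicate, config$n_taxa,
                        config$seq_length, round(config$p_change * 1e7))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed_r)
  depth <- as.integer(log2(config$n_taxa))
  cur <- matrix(sample.int(4L, config$seq_length, replace = TRUE), ncol = 1L)
  for (d in seq_len(depth)) {
    cur <- cur[, rep(seq_len(ncol(cur)), each = 2L), drop = FALSE]
    cur <- matrix(evolve_codes(cur, config$p_change), nrow = nrow(cur))
  }
  ids <- paste0("t", seq_len(config$n_taxa))
  list(alignment = new_labeled_alignment(cur, ids, replicate, config),
       tree = perfect_binary_tree(config$n_taxa))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Topology-accuracy benchmark on simulated data
#'
#' For every combination of taxa count, sequence length and change rate,
#' simulates replicates on the perfect binary tree, computes the distance
#' matrix under each requested method, replaces undefined cells
#' ([replace_undefined()]), builds the neighbor-joining tree and scores it
#' correct when its unrooted topology equals the model tree (zero
#' Robinson–Foulds distance). All methods are evaluated on the same
#' replicate alignments (paired design).
#'
#' @param n_taxa vector of leaf counts (powers of 2).
#' @param seq_lengths vector of sequence lengths.
#' @param p_changes vector of per-site per-branch change probabilities.
#' @param methods subset of `c("k2p_gap", "k2p_complete", "k2p_pairwise")`.
#' @param n_replicates replicates per condition.
#' @param seed master seed.
#' @param verbose print a progress line per condition.
#' @return A data frame with one row per (taxa, length, rate, method):
#'   columns `n_taxa`, `seq_length`, `p_change`, `method`, `n_replicates`,
#'   `n_correct`, `accuracy_pct`.
#' @seealso [summarize_benchmark()] to average accuracies across lengths.
#' @export
run_benchmark <- function(n_taxa, seq_lengths, p_changes,
                          methods = c("k2p_gap", "k2p_complete", "k2p_pairwise"),
                          n_replicates = 100L, seed = 1L, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (taxa in n_taxa) for (len in seq_lengths) for (p in p_changes) {
    cfg <- simulation_config(taxa, len, p, n_replicates, seed)
    correct <- stats::setNames(integer(length(methods)), methods)
    for (r in seq_len(n_replicates)) {
      rep_data <- simulate_replicate(cfg, r)
      for (m in methods) {
        D <- replace_undefined(distance_matrix(rep_data$alignment, method = m))
        est <- neighbor_joining(D)
        if (unrooted_topologies_equal(est, rep_data$tree))
          correct[m] <- correct[m] + 1L
      }
    }
    for (m in methods) {
      rows[[length(rows) + 1L]] <- data.frame(
        n_taxa = taxa, seq_length = len, p_change = p, method = m,
        n_replicates = n_replicates, n_correct = correct[[m]],
        accuracy_pct = 100 * correct[[m]] / n_replicates,
        stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("taxa=%d len=%d p=%g: %s", taxa, len, p,
                      paste(sprintf("%s %d/%d", methods, correct, n_replicates),
                            collapse = ", ")))
  }
  do.call(rbind, rows)
}

#' Average benchmark accuracy across sequence lengths
#'
#' Collapses a [run_benchmark()] table to one row per (taxa, rate, method),
#' averaging the per-length accuracies with equal weight — the form in which
#' benchmark accuracies are conventionally summarized.
#'
#' @param results data frame from [run_benchmark()].
#' @return Data frame with columns `n_taxa`, `p_change`, `method`,
#'   `n_replicates` (total across lengths), `accuracy_pct`.
#' @export
summarize_benchmark <- function(results) {
  agg <- stats::aggregate(accuracy_pct ~ n_taxa + p_change + method,
                          data = results, FUN = mean)
  reps <- stats::aggregate(n_replicates ~ n_taxa + p_change + method,
                           data = results, FUN = sum)
  out <- merge(agg, reps, by = c("n_taxa", "p_change", "method"))
  out[order(out$p_change, out$n_taxa, out$method),
      c("n_taxa", "p_change", "method", "n_replicates", "accuracy_pct")]
}
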