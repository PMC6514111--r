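# Independent oracles used across the suite. Everything here is written
# naively (enumeration / first principles) and never calls the code path it
# is used to check.

# Nontrivial bipartitions of an unrooted tree, as a set of canonical
# strings. Computed by deleting each internal edge and flooding the two
# components of the resulting graph.
brute_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  edges <- tree$edge
  adj <- lapply(seq_len(max(edges)), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  internal <- edges[edges[, 1] > n & edges[, 2] > n, , drop = FALSE]
  out <- character(0)
  for (k in seq_len(nrow(internal))) {
    a <- internal[k, 1]; b <- internal[k, 2]
    seen <- rep(FALSE, length(adj))
    stack <- a; seen[a] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (u in adj[[v]]) {
        if (!seen[u] && !(v == a && u == b) && !(v == b && u == a)) {
          seen[u] <- TRUE; stack <- c(stack, u)
        }
      }
    }
    side <- sort(tree$tip.label[which(seen[seq_len(n)])])
    other <- sort(setdiff(tree$tip.label, side))
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, canon)
  }
  unique(out)
}

brute_rf <- function(t1, t2) {
  b1 <- brute_bipartitions(t1)
  b2 <- brute_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Naive per-character site classification written as explicit conditionals.
naive_classify <- function(a, b) {
  norm <- function(x) {
    x <- toupper(x)
    if (x == "U") x <- "T"
    x
  }
  a <- norm(a); b <- norm(b)
  nucs <- c("A", "C", "G", "T")
  if (!(a %in% c(nucs, "-")) || !(b %in% c(nucs, "-"))) return("excluded")
  if (a == "-" && b == "-") return("gap_gap")
  if (a == "-" || b == "-") return("nuc_gap")
  if (a == b) return("identical")
  purine <- function(x) x %in% c("A", "G")
  if (purine(a) == purine(b)) "transition" else "transversion"
}

# Brute-force overlap: literal count of interspecific values strictly below
# the intraspecific maximum.
brute_overlap <- function(intra, inter) {
  intra <- intra[!is.na(intra)]; inter <- inter[!is.na(inter)]
  100 * length(inter[inter < max(intra)]) / length(inter)
}

# pair_counts object straight from raw numbers, bypassing count_pair().
make_counts <- function(n1 = 0, n2 = 0, n3 = 0, n_g = 0, n_n = 0,
                        n_excluded = 0) {
  n <- n1 + n2 + n3 + n_g + n_n
  structure(list(n = as.integer(n), n1 = as.integer(n1), n2 = as.integer(n2),
                 n3 = as.integer(n3), n_g = as.integer(n_g),
                 n_n = as.integer(n_n), n_excluded = as.integer(n_excluded),
                 alignment_length = as.integer(n + n_excluded)),
            class = "pair_counts")
}

# Random binary tree with branch lengths, leaf labels a,b,c,... (wrapper
# kept here so tests share one convention).
random_bl_tree <- function(ntip, min_bl = 0.1, max_bl = 5) {
  tr <- ape::rtree(ntip, tip.label = paste0("x", seq_len(ntip)))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

prob_vec <- function(pr) unlist(pr[c("S", "P", "Q", "G", "N")])
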