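test_that("pair partition is exhaustive and exclusive", {
  one_sp <- data.frame(sequence_id = c("a", "b", "c"),
                       species = rep("sp1", 3))
  p1 <- partition_pairs(one_sp)
  expect_equal(nrow(p1$intra), 3L)
  expect_equal(nrow(p1$inter), 0L)

  three_sp <- data.frame(sequence_id = c("a", "b", "c"),
                         species = c("s1", "s2", "s3"))
  p3 <- partition_pairs(three_sp)
  expect_equal(nrow(p3$intra), 0L)
  expect_equal(nrow(p3$inter), 3L)

  set.seed(701)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    lab <- data.frame(sequence_id = paste0("q", 1:n),
                      species = sample(paste0("sp", 1:6), n, replace = TRUE))
    pp <- partition_pairs(lab)
    expect_equal(nrow(pp$intra) + nrow(pp$inter), choose(n, 2))
    # no pair in both lists
    key <- function(m) paste(m[, 1], m[, 2])
    expect_length(intersect(key(pp$intra), key(pp$inter)), 0)
  }
  expect_error(partition_pairs(data.frame(sequence_id = "a", species = "s")),
               "2 sequences")
})

test_that("published per-species counts give the published pair bookkeeping", {
  counts <- physalis_species_counts()
  expect_equal(nrow(counts), 45L)
  expect_equal(sum(counts$n_sequences), 86L)
  expect_equal(sum(counts$n_sequences >= 2), 17L)

  labeling <- expand_species_counts(counts)
  pp <- partition_pairs(labeling)
  expect_equal(nrow(pp$intra), 113L)
  expect_equal(nrow(pp$inter), 3542L)
  expect_equal(nrow(pp$intra) + nrow(pp$inter), 3655L)
})

test_that("overlap percentage counts strict threshold crossings", {
  expect_equal(overlap_percentage(c(0, 0.01, 0.02),
                                  c(0.015, 0.05, 0.10, 0.30)), 25)
  expect_equal(overlap_percentage(c(0.01), c(0.5, 0.6)), 0)
  # a pair exactly at the maximum is not in the overlap zone
  expect_equal(overlap_percentage(c(0.01, 0.02), c(0.02, 0.05)), 0)
  expect_true(is.na(overlap_percentage(numeric(0), c(0.1))))
  expect_true(is.na(overlap_percentage(c(NA_real_), c(0.1))))

  set.seed(702)
  for (rep in 1:20) {
    intra <- runif(sample(2:30, 1), 0, 0.08)
    inter <- runif(sample(2:80, 1), 0, 0.3)
    expect_equal(overlap_percentage(intra, inter),
                 brute_overlap(intra, inter))
    # permutation invariance
    expect_equal(overlap_percentage(sample(intra), sample(inter)),
                 overlap_percentage(intra, inter))
  }
})

test_that("trimmed overlap removes exact tail counts before comparing", {
  intra <- runif(20, 0, 0.05)
  inter <- runif(50, 0, 0.2)
  expect_equal(trimmed_overlap_percentage(intra, inter, trim = 0),
               overlap_percentage(intra, inter))

  # hand-enumerated: removing the top 5 of 100 intra values moves the
  # threshold to 0.95; every surviving inter value 0.02 stays below it
  # (one of the twenty is itself trimmed as the lowest 5%)
  expect_equal(trimmed_overlap_percentage(0.01 * (1:100), rep(0.02, 20),
                                          trim = 0.05), 100)
  # trimming a one-element inter list empties it: flagged undefined
  expect_true(is.na(trimmed_overlap_percentage(0.01 * (1:100), c(0.02),
                                               trim = 0.05)))

  # brute-force recomputation under the exact-count trimming rule
  set.seed(703)
  for (rep in 1:15) {
    ni <- sample(5:40, 1); ne <- sample(5:100, 1); trim <- 0.05
    intra <- runif(ni, 0, 0.06); inter <- runif(ne, 0, 0.25)
    si <- sort(intra); se <- sort(inter)
    kept_i <- si[seq_len(ni - ceiling(trim * ni))]
    kept_e <- se[-seq_len(ceiling(trim * ne))]
    expect_equal(trimmed_overlap_percentage(intra, inter, trim),
                 brute_overlap(kept_i, kept_e))
  }
  # an extreme intra maximum: trimming it changes the threshold
  intra2 <- c(rep(0.01, 19), 0.9)
  inter2 <- c(0.5, 0.05)
  expect_equal(overlap_percentage(intra2, inter2), 100)
  expect_equal(trimmed_overlap_percentage(intra2, inter2, 0.05), 0)

  expect_true(is.na(trimmed_overlap_percentage(c(0.1), c(0.2), 0.5)))
  expect_error(trimmed_overlap_percentage(intra, inter, 1.5), "trim")
})

test_that("the overlap summary matches a brute-force recomputation", {
  # five sequences, two species, hand-checkable distances
  aln <- c(a1 = "ACGTACGTAT", a2 = "ACGTACGTAC", a3 = "ACGTACGTCC",
           b1 = "ACGTATATAC", b2 = "ACGTACGTAC")
  lab <- data.frame(sequence_id = names(aln),
                    species = c("A", "A", "A", "B", "B"))
  D <- distance_matrix(aln, "k2p_gap")
  s <- summarize_overlap(D, lab, trim = 0.05)
  expect_equal(s$n_intra_pairs, 4L)   # C(3,2) + C(2,2)
  expect_equal(s$n_inter_pairs, 6L)

  pp <- partition_pairs(lab)
  di <- D[cbind(pp$intra[, 1], pp$intra[, 2])]
  de <- D[cbind(pp$inter[, 1], pp$inter[, 2])]
  expect_equal(s$mean_intra, mean(di))
  expect_equal(s$sd_intra, sqrt(mean((di - mean(di))^2)))  # population SD
  expect_equal(s$max_intra, max(di))
  expect_equal(s$mean_inter, mean(de))
  expect_equal(s$overlap_pct, brute_overlap(di, de))
  # a2-b2 are identical sequences across species: one zero inter pair,
  # between one distinct species pair
  expect_equal(s$n_zero_inter_seq_pairs, 1L)
  expect_equal(s$n_zero_inter_species_pairs, 1L)

  ssamp <- summarize_overlap(D, lab, sd_type = "sample")
  expect_equal(ssamp$sd_intra, stats::sd(di))

  # degenerate labeling: no species with two sequences
  lab1 <- data.frame(sequence_id = names(aln),
                     species = paste0("s", 1:5))
  s1 <- summarize_overlap(D, lab1)
  expect_equal(s1$n_intra_pairs, 0L)
  expect_true(is.na(s1$mean_intra))
  expect_false(is.na(s1$mean_inter))
  expect_true(is.na(s1$overlap_pct))
})

test_that("undefined distances are excluded and counted separately", {
  D <- matrix(0.05, 4, 4,
              dimnames = list(c("a1", "a2", "b1", "b2"),
                              c("a1", "a2", "b1", "b2")))
  diag(D) <- 0
  D["a1", "a2"] <- D["a2", "a1"] <- 0.01
  D["b1", "b2"] <- D["b2", "b1"] <- NA
  lab <- data.frame(sequence_id = rownames(D),
                    species = c("A", "A", "B", "B"))
  s <- summarize_overlap(D, lab)
  expect_equal(s$n_undefined_intra, 1L)
  expect_equal(s$mean_intra, 0.01)
  expect_equal(s$n_inter_pairs, 4L)
  expect_equal(s$n_undefined_inter, 0L)
})
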