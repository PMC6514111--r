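test_that("site-pair classification covers all 25 state combinations", {
  expect_equal(classify_site_pair("A", "G"), "transition")
  expect_equal(classify_site_pair("U", "G"), "transversion")
  expect_equal(classify_site_pair("C", "-"), "nuc_gap")
  expect_equal(classify_site_pair("-", "-"), "gap_gap")
  expect_equal(classify_site_pair("N", "A"), "excluded")
  # exhaustive: lookup path vs the naive conditional oracle
  states <- c("A", "C", "G", "T", "U", "-", "a", "u", "N", "R", "?")
  for (a in states) for (b in states)
    expect_equal(classify_site_pair(a, b), naive_classify(a, b),
                 info = paste(a, b))
})

test_that("pair counting respects the gap-handling mode", {
  cnt <- count_pair("ACGT", "ACGT")
  expect_equal(cnt$n, 4L); expect_equal(cnt$n1, 4L)
  expect_equal(cnt$n2 + cnt$n3 + cnt$n_g + cnt$n_n, 0L)

  keep <- count_pair("AC-T", "GC--")
  expect_equal(unlist(keep[c("n", "n1", "n2", "n3", "n_g", "n_n")]),
               c(n = 4L, n1 = 1L, n2 = 1L, n3 = 0L, n_g = 1L, n_n = 1L))
  drop <- count_pair("AC-T", "GC--", "drop_gap_sites")
  expect_equal(unlist(drop[c("n", "n1", "n2", "n_excluded")]),
               c(n = 2L, n1 = 1L, n2 = 1L, n_excluded = 2L))

  expect_error(count_pair("ACGT", "ACG"), "length")
})

test_that("pair counting matches per-column classification on random data", {
  set.seed(401)
  alphabet <- c("A", "C", "G", "T", "-", "N")
  for (rep in 1:20) {
    a <- sample(alphabet, 60, replace = TRUE, prob = c(rep(0.21, 4), 0.1, 0.06))
    b <- sample(alphabet, 60, replace = TRUE, prob = c(rep(0.21, 4), 0.1, 0.06))
    cats <- vapply(seq_along(a), function(i) naive_classify(a[i], b[i]), "")
    cnt <- count_pair(a, b)
    expect_equal(cnt$n1, sum(cats == "identical"))
    expect_equal(cnt$n2, sum(cats == "transition"))
    expect_equal(cnt$n3, sum(cats == "transversion"))
    expect_equal(cnt$n_g, sum(cats == "nuc_gap"))
    expect_equal(cnt$n_n, sum(cats == "gap_gap"))
    expect_equal(cnt$n_excluded, sum(cats == "excluded"))
    expect_equal(cnt$n + cnt$n_excluded, cnt$alignment_length)
  }
})

test_that("classic K2P distance reproduces hand-computed values", {
  expect_equal(k2p_distance(make_counts(n1 = 100))$value, 0)
  # P = 0.12, Q = 0.08: -log(0.68)/2 - log(0.84)/4
  res <- k2p_distance(make_counts(n1 = 80, n2 = 12, n3 = 8))
  expect_equal(res$value, -log(0.68) / 2 - log(0.84) / 4, tolerance = 1e-15)
  expect_equal(res$value, 0.2364196, tolerance = 1e-7)
  # boundary of the log domain: 1 - 2P - Q = 0
  sat <- k2p_distance(make_counts(n1 = 30, n2 = 30, n3 = 40))
  expect_true(is.na(sat$value))
  expect_true(sat$saturated)
  expect_true(is.na(k2p_distance(make_counts())$value))
})

test_that("gap-aware distance equals the classic one on gap-free counts", {
  set.seed(402)
  for (rep in 1:50) {
    # random gap-free counts inside the defined domain
    repeat {
      n2 <- sample(0:20, 1); n3 <- sample(0:15, 1)
      n1 <- 100 - n2 - n3
      if (n1 > n2 && n1 + n2 > n3) break
    }
    cnt <- make_counts(n1 = n1, n2 = n2, n3 = n3)
    g <- k2p_gap_distance(cnt)
    k <- k2p_distance(cnt)
    expect_equal(g$w_hat, 1)
    expect_equal(g$value, k$value, tolerance = 1e-12)
  }
})

test_that("gap-aware distance matches its hand-derived example and oracle", {
  res <- k2p_gap_distance(make_counts(n1 = 70, n2 = 10, n3 = 5,
                                      n_g = 10, n_n = 5))
  expect_equal(res$w_hat, 0.9)
  expect_equal(res$value,
               3 / 4 * 0.9 * log(0.9) - 0.9 / 2 * log(0.6 * sqrt(0.75)),
               tolerance = 1e-15)
  expect_equal(res$value, 0.2235, tolerance = 5e-4)

  # composition oracle: invert the proportions at w_hat, then rebuild the
  # total change count 2[w(at + 2bt + et) + (1 - w)et]; must agree exactly
  set.seed(403)
  for (rep in 1:25) {
    p <- rate_parameters(runif(1, 0.01, 0.2), runif(1, 0.01, 0.1),
                         runif(1, 0, 0.05), w = runif(1, 0.7, 1))
    t <- runif(1, 0.1, 2)
    pr <- pair_probabilities(p, t)
    n <- 1e6
    cnt <- make_counts(n1 = round(n * pr$S), n2 = round(n * pr$P),
                       n3 = round(n * pr$Q), n_g = round(n * pr$G),
                       n_n = round(n * pr$N))
    est <- k2p_gap_distance(cnt)
    S <- cnt$n1 / cnt$n; P <- cnt$n2 / cnt$n; Q <- cnt$n3 / cnt$n
    G <- cnt$n_g / cnt$n; N <- cnt$n_n / cnt$n
    w_hat <- S + P + Q + G / 2
    if (is.na(est$value) || w_hat <= 0.5) next
    iv <- invert_rates(list(S = S, P = P, Q = Q, N = N), w_hat)
    K_oracle <- 2 * (w_hat * (iv[["alpha_t"]] + 2 * iv[["beta_t"]] +
                                iv[["epsilon_t"]]) +
                       (1 - w_hat) * iv[["epsilon_t"]])
    expect_equal(est$value, K_oracle, tolerance = 1e-12)
    # inverting with the true ancestral w recovers the true change count
    iv_true <- invert_rates(pr, p$w)
    K_true <- 2 * (p$w * (iv_true[["alpha_t"]] + 2 * iv_true[["beta_t"]] +
                            iv_true[["epsilon_t"]]) +
                     (1 - p$w) * iv_true[["epsilon_t"]])
    expect_equal(K_true, expected_total_changes(p, t), tolerance = 1e-9)
  }
})

test_that("exact-proportion distance is nondecreasing in divergence time", {
  p <- rate_parameters(0.08, 0.04, 0.02, w = 0.9)
  n <- 1e7
  prev <- -Inf
  for (t in seq(0.05, 2.5, by = 0.05)) {
    pr <- pair_probabilities(p, t)
    cnt <- make_counts(n1 = round(n * pr$S), n2 = round(n * pr$P),
                       n3 = round(n * pr$Q), n_g = round(n * pr$G),
                       n_n = round(n * pr$N))
    v <- k2p_gap_distance(cnt)$value
    if (is.na(v)) break  # saturation boundary reached
    expect_gte(v, prev - 1e-9)
    prev <- v
  }
})

test_that("distance matrices implement the three gap treatments", {
  aln <- c(s1 = "AC-T", s2 = "GC--", s3 = "ACTT")

  # complete deletion keeps only the all-nucleotide columns (1 and 2)
  Dc <- distance_matrix(aln, "k2p_complete")
  cc <- count_pair("AC", "GC")
  expect_equal(Dc["s1", "s3"], 0)
  expect_equal(Dc["s1", "s2"], k2p_distance(cc)$value)

  # pairwise deletion: pair (s1, s3) compares columns 1, 2, 4
  Dp <- distance_matrix(aln, "k2p_pairwise")
  expect_equal(Dp["s1", "s3"], 0)
  # pair (s1, s2) keeps columns 1, 2 -> P = 1/2: saturated
  expect_true(is.na(Dp["s1", "s2"]))

  Dg <- distance_matrix(aln, "k2p_gap")
  expect_equal(Dg["s1", "s3"],
               k2p_gap_distance(count_pair("AC-T", "ACTT"))$value)
  for (D in list(Dc, Dp, Dg)) {
    expect_true(isSymmetric(unname(D)))
    expect_equal(unname(diag(D)), c(0, 0, 0))
  }

  two <- distance_matrix(c(a = "ACGT", b = "ACGT"), "k2p_gap")
  expect_equal(unname(two), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(distance_matrix(c(a = "ACGT")), "2 sequences")
})

test_that("matrix cells agree with the single-pair code paths", {
  set.seed(404)
  sim <- simulate_replicate(simulation_config(8, 300, 0.02, 1, seed = 5), 1)
  seqs <- as.character(sim$alignment)
  for (m in c("k2p_gap", "k2p_complete", "k2p_pairwise")) {
    D <- distance_matrix(sim$alignment, m)
    if (m == "k2p_complete") {
      chars <- do.call(rbind, strsplit(seqs, ""))
      keep <- colSums(chars == "-") == 0
      seqs_m <- apply(chars[, keep, drop = FALSE], 1,
                      paste, collapse = "")
      names(seqs_m) <- names(seqs)
    } else seqs_m <- seqs
    for (i in 1:7) for (j in (i + 1):8) {
      cnt <- count_pair(seqs_m[[i]], seqs_m[[j]],
                        mode = if (m == "k2p_pairwise") "drop_gap_sites"
                        else "keep_gaps")
      want <- if (m == "k2p_gap") k2p_gap_distance(cnt)$value
      else k2p_distance(cnt)$value
      expect_equal(D[i, j], want, info = paste(m, i, j))
    }
  }
})

test_that("undefined cells are preserved and replaced by the stated policy", {
  D <- matrix(c(0, 0.2, NA, 0.2, 0, 0.1, NA, 0.1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  R <- replace_undefined(D)
  expect_equal(R["a", "c"], 0.4)  # 2 x largest finite entry
  expect_equal(attr(R, "n_replaced"), 1L)
  R2 <- replace_undefined(D, constant = 9)
  expect_equal(R2["a", "c"], 9)
  allna <- matrix(NA_real_, 3, 3, dimnames = dimnames(D)); diag(allna) <- 0
  R3 <- replace_undefined(allna)
  expect_equal(R3["a", "b"], 1.0)
  expect_equal(unname(diag(R3)), c(0, 0, 0))
})
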