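test_that("pi matches hand-computable cases", {
  expect_equal(unname(pi_diversity(aln_from("AAAA", "AAAA"))), c(0, 0))
  expect_equal(unname(pi_diversity(aln_from("AAAA", "TTTT"))), c(4, 1))
  # n = 4, two segregating sites with minor counts {2, 1}: 7/6 mean diffs
  aln <- aln_from("AAAA", "AATA", "TAAA", "TAAA")
  expect_equal(pi_diversity(aln)[["pi_total"]], 7 / 6)
  expect_error(pi_diversity(aln_from("ACGT")), "sample-size")
})

test_that("pi equals brute-force pair enumeration on random alignments", {
  for (seed in 1:6) {
    aln <- random_alignment(8, 40, missing_prob = 0.08, seed = seed)
    expect_equal(pi_diversity(aln)[["pi_total"]], bf_pi_total(aln))
  }
})

test_that("Watterson's theta matches S/(a_n * L)", {
  expect_equal(watterson(aln_from("AAAA", "AAAA")), 0)
  # n = 2: a_2 = 1; S = 3 over L = 100 gives 0.03
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  expect_equal(watterson(aln_from(s1, s2)), 0.03)
  for (seed in 1:4) {
    aln <- random_alignment(9, 50, seed = seed)
    expect_equal(watterson(aln),
                 bf_seg_sites(aln) / (sum(1 / (1:8)) * 50))
  }
})

test_that("Tajima's D reproduces the hand-evaluated n = 4 case", {
  # pi = 7/6, S = 2, n = 4 evaluates to ~ +0.59
  aln <- aln_from("AAAA", "AATA", "TAAA", "TAAA")
  expect_equal(tajimas_d(aln), 0.5916, tolerance = 1e-3)
  expect_true(is.na(tajimas_d(aln_from("AAAA", "AAAA"))))  # S = 0: undefined
})

test_that("Tajima's D sign follows the site-frequency spectrum", {
  # all variants at intermediate frequency -> positive
  mid <- aln_from("AAAACCCC", "AAAACCCC", "AAAACCCC",
                  "TTTTCCCC", "TTTTCCCC", "TTTTCCCC")
  expect_gt(tajimas_d(mid), 0)
  # all variants are singletons -> negative
  sing <- aln_from("CCCCCCCC", "ACCCCCCC", "CACCCCCC",
                   "CCACCCCC", "CCCACCCC", "CCCCACCC")
  expect_lt(tajimas_d(sing), 0)
  # row permutation leaves all statistics unchanged
  perm <- alignment(unclass(mid)[c(4, 2, 6, 1, 3, 5), ])
  expect_equal(tajimas_d(perm), tajimas_d(mid))
  expect_equal(pi_diversity(perm), pi_diversity(mid))
})

test_that("neutral coalescent replicates center Tajima's D near zero", {
  p <- sim_params(n_A = 20, n_B = 0, L = 1000, theta = 0.005, t_dup = 100)
  set.seed(41)
  D <- vapply(1:2000, function(i) {
    r <- paraconv:::sim_once(p)
    cnt <- colSums(r$mat_A)
    S <- length(r$positions)
    paraconv:::tajima_d_core(20, S, sum(cnt * (20 - cnt)) / choose(20, 2))
  }, 0)
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.1)
})

test_that("Fu & Li's D has the forced signs and matches recomputation", {
  # no derived singletons but S > 0 forces a positive numerator
  og <- "AAAAAAAA"
  mid <- aln_from("CCCCAAAA", "CCCCAAAA", "CCCCAAAA",
                  "AAAAAAAA", "AAAAAAAA", "AAAAAAAA")
  expect_gt(fu_li_d(mid, og), 0)
  # every mutation a derived singleton forces a negative value
  sing <- aln_from("CAAAAAAA", "ACAAAAAA", "AACAAAAA",
                   "AAACAAAA", "AAAACAAA", "AAAAACAA")
  expect_lt(fu_li_d(sing, og), 0)
  for (seed in 1:5) {
    aln <- random_alignment(7, 40, seed = seed)
    set.seed(seed + 100)
    og2 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
    expect_equal(fu_li_d(aln, og2), bf_fu_li_d(aln, og2), tolerance = 1e-6)
  }
  expect_error(fu_li_d(mid, NULL), "outgroup")
})

test_that("Hudson's F_ST matches pair enumeration and its bounds", {
  g <- c(1, 1, 2, 2)
  expect_equal(fst_two_groups(aln_from("ACGT", "ACGT", "ACGT", "ACGT"), g), 0)
  # groups fixed for different alleles, no within-variation -> 1
  expect_equal(fst_two_groups(aln_from("AAAA", "AAAA", "TTTT", "TTTT"), g), 1)
  # Hw = (2 + 0)/2 = 1, Hb = 2 -> 0.5
  half <- aln_from("AA", "CC", "GG", "GG")
  expect_equal(fst_two_groups(half, g), 0.5)
  for (seed in 1:4) {
    aln <- random_alignment(8, 30, seed = seed)
    labels <- rep(c("x", "y"), each = 4)
    expect_equal(fst_two_groups(aln, labels), bf_fst(aln, labels))
    expect_lte(fst_two_groups(aln, labels), 1)
  }
  expect_error(fst_two_groups(half, c(1, 1, 1, 1)), "two groups")
})

test_that("cross-locus classification separates the four classes", {
  # 5 columns: shared, private-A, private-B, fixed, identical-monomorphic
  a <- aln_from(a1 = "ACACA", a2 = "TCACA", a3 = "TAACA")
  b <- aln_from(b1 = "ACATA", b2 = "TCGTA", b3 = "ACGTA")
  og <- "ACAAA"
  cl <- classify_cross_locus(a, b, og)
  expect_equal(cl$n_shared, 1)
  expect_equal(cl$n_private_A, 1)
  expect_equal(cl$n_private_B, 1)
  expect_equal(cl$n_fixed, 1)
  expect_equal(cl$positions$shared, 1L)
  expect_equal(cl$positions$fixed, 4L)
  # spectra bin sums equal the polarizable class counts
  expect_equal(sum(cl$sfs_shared), cl$n_shared)
  expect_equal(sum(cl$sfs_private_A), cl$n_private_A)
  expect_error(classify_cross_locus(a, aln_from(b1 = "ACC"), og),
               "coordinate")
})

test_that("identical polymorphic loci classify every variant as shared", {
  a <- aln_from(a1 = "AAAA", a2 = "ATAA", a3 = "TTAA")
  cl <- classify_cross_locus(a, a, "AAAA")
  expect_equal(cl$n_shared, 2)
  expect_equal(cl$n_private_A + cl$n_private_B + cl$n_fixed, 0)
})

test_that("sliding windows agree with direct per-window recomputation", {
  aln <- random_alignment(8, 100, seed = 9)
  one <- sliding(aln, "pi_total", window = 100, step = 25)
  expect_equal(nrow(one), 1)
  expect_equal(one$value, pi_diversity(aln)[["pi_total"]])
  win <- sliding(aln, "S", window = 40, step = 20)
  expect_equal(win$start, c(1, 21, 41, 61))
  for (i in seq_len(nrow(win))) {
    sub <- alignment(unclass(aln)[, win$start[i]:win$end[i]])
    expect_equal(win$value[i], bf_seg_sites(sub))
  }
  expect_error(sliding(aln, "S", window = 0, step = 5), "positive")
  expect_error(sliding(aln, "S", window = 200, step = 5), "exceeds")
})

test_that("summary vectors match independent per-statistic calls", {
  p <- sim_params(n_A = 6, n_B = 5, L = 300, theta = 0.02, C = 1,
                  lambda_tract = 100, t_dup = 0.5)
  r <- simulate(p, seed = 77)
  sv <- summary_vector(r)
  n <- 6
  cnt <- colSums(r$mat_A)
  expect_equal(sv[["S_A"]], sum(cnt > 0 & cnt < n))
  expect_equal(sv[["pi_total_A"]], sum(cnt * (n - cnt)) / choose(n, 2))
  expect_equal(sv[["n_private"]], sv[["n_private_A"]] + sv[["n_private_B"]])
  # symmetric input gives symmetric per-locus fields
  r2 <- r
  r2$mat_B <- r$mat_A
  sv2 <- summary_vector(r2)
  expect_equal(sv2[["S_A"]], sv2[["S_B"]])
  expect_equal(sv2[["pi_total_A"]], sv2[["pi_total_B"]])
  # monomorphic loci give all-zero counts
  r3 <- r
  r3$positions <- integer(0)
  r3$mat_A <- r$mat_A[, 0, drop = FALSE]
  r3$mat_B <- r$mat_B[, 0, drop = FALSE]
  sv3 <- summary_vector(r3)
  expect_equal(unname(sv3[c("S_A", "S_B", "n_shared", "n_fixed")]),
               c(0, 0, 0, 0))
})
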