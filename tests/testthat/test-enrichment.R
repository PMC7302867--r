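make_territory <- function() {
  tr <- data.frame(chrom = "c1", start = c(10L, 40L), end = c(20L, 50L),
                   clade = "MNR", species = "A/T", unit_len = 1L,
                   length = 10L, complete_units = 10L,
                   stringsAsFactors = FALSE)
  polytract_territory(tr, c(c1 = 100L), extend = FALSE)
}

test_that("overlap counting in singleton and multiplex modes", {
  terr <- make_territory()
  pt <- data.frame(chrom = "c1", start = 12L, end = 13L)
  expect_identical(compute_overlap(pt, terr, "singleton")[c("k", "M")],
                   list(k = 1L, M = 1L))
  iv <- data.frame(chrom = "c1", start = 5L, end = 15L)
  ov <- compute_overlap(iv, terr, "multiplex")
  expect_equal(ov$k, 5)
  expect_equal(ov$M, 10)
  # instance spanning two disjoint territory intervals counts once
  span <- data.frame(chrom = "c1", start = 15L, end = 45L)
  expect_identical(compute_overlap(span, terr, "singleton")$k, 1L)
  expect_equal(compute_overlap(span, terr, "multiplex")$k, 10)
})

test_that("overlap counts equal the per-nucleotide brute force", {
  set.seed(41)
  tr <- scan_sequence(random_seq(3000), chrom = "c1")
  terr <- polytract_territory(tr, c(c1 = 3000L))
  st <- sample(0:2950, 200, replace = TRUE)
  feats <- data.frame(chrom = "c1", start = st,
                      end = st + sample(1:40, 200, replace = TRUE))
  expect_equal(compute_overlap(feats, terr, "multiplex")$k,
               oracle_overlap_multiplex(feats, terr))
  expect_equal(compute_overlap(feats, terr, "singleton")$k,
               oracle_overlap_singleton(feats, terr))
})

test_that("out-of-bounds features are clipped with a warning", {
  terr <- make_territory()
  feats <- data.frame(chrom = "c1", start = 95L, end = 110L)
  expect_warning(ov <- compute_overlap(feats, terr, "multiplex"), "clip")
  expect_equal(ov$M, 5)
  expect_warning(compute_overlap(data.frame(chrom = "c9", start = 1L,
                                            end = 2L), terr), "unknown")
})

test_that("binomial tails match frozen exact-rational values", {
  # expected values computed once by exact rational summation of
  # sum_i C(M,i) (n/N)^i (1-n/N)^(M-i) (Python fractions; see the
  # acceptance suite for the full grid)
  expect_equal(binom_p(2, 2, 50, 100, "over"), 0.25)
  expect_equal(binom_p(0, 17, 50, 100, "over"), 1.0)
  expect_equal(binom_p(3, 10, 100, 1000, "over"),
               0.070190826400000003, tolerance = 1e-14)
  expect_equal(binom_p(3, 10, 100, 1000, "under"),
               0.98720480160000001, tolerance = 1e-14)
  # printed parameterization swaps the feature and territory roles
  expect_equal(binom_p(3, 10, 100, 1000, "over",
                       parameterization = "printed"),
               0.079373202252180336, tolerance = 1e-14)
  expect_error(binom_p(5, 2, 50, 100), "k <= M")
  expect_error(binom_p(1, 2, 500, 100), "n <= N")
})

test_that("binomial tails are complementary and monotone", {
  for (M in c(5L, 20L)) {
    for (k in 1:M) {
      expect_equal(binom_p(k, M, 30, 100, "over") +
                     binom_p(k - 1, M, 30, 100, "under"), 1.0)
    }
    over <- vapply(0:M, binom_p, numeric(1), M = M, n = 30, N = 100,
                   direction = "over")
    under <- vapply(0:M, binom_p, numeric(1), M = M, n = 30, N = 100,
                    direction = "under")
    expect_true(all(diff(over) <= 1e-15))
    expect_true(all(diff(under) >= -1e-15))
  }
})

test_that("relative risk and Katz interval behave as designed", {
  expect_equal(relative_risk(5, 10, 50, 100)$RR, 1.0)
  expect_equal(relative_risk(10, 10, 50, 100)$RR, 2.0)
  rr0 <- relative_risk(0, 10, 50, 100)
  expect_identical(rr0$RR, 0)
  expect_false(rr0$ci_defined)
  expect_true(is.na(rr0$ci_low))

  rr <- relative_risk(40, 100, 200, 1000)
  expect_equal(rr$RR, 2.0)
  expect_true(rr$ci_low < 2 && 2 < rr$ci_high)
  # parametric bootstrap oracle: resample k ~ Binomial(100, 0.4)
  set.seed(42)
  ks <- rbinom(40000, 100, 0.4)
  boot <- quantile((ks / 100) / 0.2, c(0.025, 0.975))
  expect_equal(rr$ci_low, unname(boot[1]), tolerance = 0.1)
  expect_equal(rr$ci_high, unname(boot[2]), tolerance = 0.1)
})

test_that("hypergeometric embedding test matches enumeration", {
  # full enumeration over X in 0..E with exact binomial coefficients
  E <- 5L; k_e <- 4L; N <- 100L; n <- 20L
  mass <- vapply(0:E, function(x)
    choose(n, x) * choose(N - n, E - x) / choose(N, E), numeric(1))
  expect_equal(hypergeom_embed_test(E, k_e, N, n), sum(mass[(k_e + 1):(E + 1)]),
               tolerance = 1e-14)
  expect_equal(hypergeom_embed_test(5, 0, 100, 20), 1.0)
  expect_equal(hypergeom_embed_test(5, 5, 100, 100), 1.0)
  expect_error(hypergeom_embed_test(200, 5, 100, 20), "E must not")
})

test_that("Bonferroni flags and landscape threshold", {
  expect_true(bonferroni_flag(5e-5, alpha = 0.01, m_tests = 94))
  expect_false(bonferroni_flag(2e-4, alpha = 0.01, m_tests = 94))
  expect_true(bonferroni_flag(5e-3, alpha = 0.01, m_tests = 1))
  expect_identical(bonferroni_flag(c(1e-9, 0.5), 0.01, 10),
                   c(TRUE, FALSE))
})

test_that("RR heatmap imputation gates on direction and significance", {
  expect_equal(rr_heatmap_impute(0.5, 1e-9, "over"), 1.0)
  expect_equal(rr_heatmap_impute(3.2, 0.2, "over"), 1.0)
  expect_equal(rr_heatmap_impute(3.2, 1e-5, "over"), 3.2)
  expect_equal(rr_heatmap_impute(c(0.4, 2), c(1e-5, 1e-5), "under"),
               c(0.4, 1.0))
})

test_that("end-to-end enrichment row is internally consistent", {
  terr <- make_territory()
  feats <- data.frame(chrom = "c1", start = c(11L, 12L, 44L, 70L),
                      end = c(12L, 13L, 45L, 71L))
  res <- polytract_enrichment(feats, terr, feature_id = "toy")
  expect_identical(res$k, 3L)
  expect_identical(res$M, 4L)
  expect_equal(res$RR, (3 / 4) / (20 / 100))
  expect_equal(res$p, binom_p(3, 4, 20, 100, "over"))
  expect_true(res$ci_low <= res$RR && res$RR <= res$ci_high)
})
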