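test_that("ECDF statistics reproduce hand-derived values", {
  x <- c(1, 3); y <- c(2, 4)
  expect_equal(ks_stat(x, y), 0.5)
  expect_equal(kuiper_stat(x, y), 0.5)        # D+ = 0.5, D- = 0
  expect_equal(ad_stat(x, y), 2 / 3)
  expect_equal(wasserstein_stat(x, y), 1)     # pure unit translation
  expect_equal(cvm_stat(x, y), oracle_cvm(x, y))
  expect_equal(dts_stat(x, y), oracle_dts(x, y))

  expect_equal(ks_stat(c(0, 0), c(1, 1)), 1)  # disjoint supports
  expect_equal(kuiper_stat(c(0, 0), c(1, 1)), 1)  # one-sided dominance
})

test_that("identical samples score zero (rank-form minimum) everywhere", {
  x <- c(1, 2, 3)
  expect_equal(ks_stat(x, x), 0)
  expect_equal(kuiper_stat(x, x), 0)
  expect_equal(wasserstein_stat(x, x), 0)
  expect_equal(dts_stat(x, x), 0)
  expect_equal(ad_stat(x, x), 0)
  expect_equal(cvm_stat(x, x), 0)
})

test_that("all six ECDF statistics match the naive oracles", {
  withr::with_seed(7, {
    for (i in 1:300) {
      pr <- random_pair()
      for (m in names(oracle_for)) {
        got <- compare_distributions(pr$x, c(pr$x, pr$y), m) # just dispatch
        expect_equal(.subset2(list(
          ks = ks_stat, kuiper = kuiper_stat, wass = wasserstein_stat,
          dts = dts_stat, cvm = cvm_stat, ad = ad_stat), m)(pr$x, pr$y),
          oracle_for[[m]](pr$x, pr$y), tolerance = 1e-10,
          label = sprintf("%s on pair %d", m, i))
        expect_true(is.finite(got))
      }
    }
  })
})

test_that("translation and monotonicity behave as expected", {
  withr::with_seed(13, x <- rnorm(25))
  # Wasserstein of a pure translation equals the shift, and scales linearly
  expect_equal(wasserstein_stat(x, x + 2.5), 2.5)
  expect_equal(wasserstein_stat(3 * x, 3 * (x + 2.5)), 7.5)
  # shifting one sample far away increases CvM
  y <- rnorm(10); x10 <- rnorm(10)
  expect_gt(cvm_stat(x10, y + 1000), cvm_stat(x10, y))
})

test_that("rank-based statistics are invariant under monotone transforms", {
  withr::with_seed(17, { x <- rnorm(20); y <- rnorm(30, 0.5) })
  tf <- function(v) exp(v)  # strictly increasing
  for (f in list(ks_stat, kuiper_stat, cvm_stat, ad_stat)) {
    expect_equal(f(tf(x), tf(y)), f(x, y), tolerance = 1e-12)
  }
})

test_that("the DTS weight inflates tail discrepancies", {
  # equal unweighted ECDF area (wasserstein), discrepancy in the tail vs
  # the center
  tail_x <- c(1, 2, 3); tail_y <- c(1, 2, 4)
  mid_x <- c(1, 2, 4);  mid_y <- c(1, 3, 4)
  expect_equal(wasserstein_stat(tail_x, tail_y),
               wasserstein_stat(mid_x, mid_y))
  expect_gt(dts_stat(tail_x, tail_y), dts_stat(mid_x, mid_y))
})

test_that("PDF distances match their direct formulas", {
  mk <- function(dens) structure(list(centers = c(0, 1), density = dens,
                                      bin_width = 1),
                                 class = "density_estimate")
  p <- mk(c(0.5, 0.5)); q <- mk(c(0.25, 0.75))
  expect_equal(euclidean_pdf_dist(mk(c(1, 0)), mk(c(0, 1))), sqrt(2))
  expect_equal(euclidean_pdf_dist(p, p), 0)
  expect_equal(amrdd_dist(p, p), 0)
  expect_equal(amrdd_dist(p, q), (0.25 / 0.375 + 0.25 / 0.625) / 2)
  # both-zero kernels contribute nothing
  expect_equal(amrdd_dist(mk(c(1, 0)), mk(c(1, 0))), 0)
  # symmetric KL: direct summation oracle on the mass vectors
  kl_oracle <- sum((c(0.5, 0.5) - c(0.25, 0.75)) * log(c(0.5, 0.5) /
                                                       c(0.25, 0.75)))
  expect_equal(kld_sym_dist(p, q), kl_oracle)
  expect_equal(kld_sym_dist(p, q), kld_sym_dist(q, p))
  expect_error(euclidean_pdf_dist(p, structure(list(centers = c(0, 2),
                                                    density = c(1, 0),
                                                    bin_width = 2),
                                               class = "density_estimate")),
               "mismatched grids")
})

test_that("symmetrised KLD is symmetric and zero only at equality", {
  withr::with_seed(19, {
    for (i in 1:20) {
      vals <- rnorm(200)
      g <- make_grid(vals)
      p <- estimate_pdf(vals[1:100], g)
      q <- estimate_pdf(vals, g)
      expect_equal(kld_sym_dist(p, q), kld_sym_dist(q, p))
      expect_gte(kld_sym_dist(p, q), 0)
      expect_equal(kld_sym_dist(p, p), 0)
    }
  })
})

test_that("compare_distributions dispatches and handles degenerate columns", {
  x <- c(1, 2, 3, 4)
  expect_equal(compare_distributions(x, x, "ks"), 0)
  g <- make_grid(x)
  expect_equal(compare_distributions(c(1, 3), x, "amrdd"),
               amrdd_dist(estimate_pdf(c(1, 3), g), estimate_pdf(x, g)))
  for (m in metric_ids()) {
    expect_equal(compare_distributions(c(7, 7), rep(7, 10), m), 0)
  }
  expect_error(compare_distributions(1:3, 1:5, "bogus"), "legal tokens")
  expect_error(compare_distributions(numeric(0), 1:5, "ks"), "empty")
})

test_that("identity of indiscernibles: d(x, x) never exceeds d(x, y)", {
  stats6 <- list(ks = ks_stat, kuiper = kuiper_stat, wass = wasserstein_stat,
                 dts = dts_stat, cvm = cvm_stat, ad = ad_stat)
  withr::with_seed(23, {
    for (i in 1:25) {
      x <- rnorm(15)
      y <- rnorm(15, mean = runif(1, -2, 2))
      for (m in names(stats6)) {
        expect_lte(stats6[[m]](x, x), stats6[[m]](x, y) + 1e-12)
      }
      g <- make_grid(c(x, y))
      px <- estimate_pdf(x, g); py <- estimate_pdf(y, g)
      expect_lte(kld_sym_dist(px, px), kld_sym_dist(px, py) + 1e-12)
      expect_lte(euclidean_pdf_dist(px, px),
                 euclidean_pdf_dist(px, py) + 1e-12)
      expect_lte(amrdd_dist(px, px), amrdd_dist(px, py) + 1e-12)
    }
  })
})

test_that("the merged subset fast path equals the generic statistics", {
  # the trial runner merges a sorted subset into the presorted full column
  # instead of re-sorting the pool; both routes must agree exactly,
  # including the all-tied case of a subset drawn from the full data
  withr::with_seed(29, {
    for (i in 1:20) {
      full <- rnorm(100)
      idx <- sample.int(100, 30)
      x <- full[idx]
      po <- dpsample:::.pooled_merge(sort(x), sort(full))
      for (m in names(dpsample:::.ecdf_cores)) {
        core <- dpsample:::.ecdf_cores[[m]]
        generic <- switch(m, ks = ks_stat, kuiper = kuiper_stat,
                          wass = wasserstein_stat, dts = dts_stat,
                          cvm = cvm_stat, ad = ad_stat)
        expect_equal(core(po$z, po$isx, 30L, 100L), generic(x, full),
                     tolerance = 1e-12, label = m)
      }
    }
  })
})
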