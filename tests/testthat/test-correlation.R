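biv_blocks <- function(g, e, l = NULL) {
  b <- list(g = matrix(g, 2), e = matrix(e, 2))
  if (!is.null(l)) b$l <- matrix(l, 2)
  b[c(setdiff(names(b), "e"), "e")]
}

test_that("genetic correlation follows cov / sqrt(v1 v2) with boundary flags", {
  fit <- fake_biv(biv_blocks(g = c(0.4, 0, 0, 0.9), e = c(1, 0, 0, 1)))
  rg <- genetic_correlation(fit)
  expect_equal(rg$estimate, 0)
  expect_false(rg$boundary)
  # perfect covariance: correlation pinned to the boundary
  fit2 <- fake_biv(biv_blocks(g = c(0.4, sqrt(0.4 * 0.9), sqrt(0.4 * 0.9), 0.9),
                              e = c(1, 0, 0, 1)))
  rg2 <- genetic_correlation(fit2)
  expect_equal(rg2$estimate, 1)
  expect_true(rg2$boundary)
  # zero genomic variance: undefined with a reason code, not silently 0
  fit3 <- fake_biv(biv_blocks(g = c(0, 0, 0, 0.9), e = c(1, 0, 0, 1)))
  rg3 <- genetic_correlation(fit3)
  expect_true(is.na(rg3$estimate))
  expect_match(rg3$reason, "zero_g_variance")
})

test_that("phenotypic correlation mirrors the univariate variance identity", {
  fit <- fake_biv(biv_blocks(g = c(0.4, 0, 0, 0.9), e = c(1, 0, 0, 1)))
  expect_equal(phenotypic_correlation(fit)$estimate, 0)
  # identical responses: every block has correlation 1
  fit2 <- fake_biv(biv_blocks(g = c(0.4, 0.4, 0.4, 0.4), e = c(1, 1, 1, 1)))
  expect_equal(phenotypic_correlation(fit2)$estimate, 1)
  # Gbar weighting of the genomic block
  fit3 <- fake_biv(biv_blocks(g = c(0.5, 0.5, 0.5, 0.5), e = c(1, 0, 0, 1)),
                   g_bar = 1.5)
  rp <- phenotypic_correlation(fit3)
  expect_equal(rp$estimate, 1.5 * 0.5 / (1.5 * 0.5 + 1), tolerance = 1e-12)
})

test_that("the z test is strict at the threshold", {
  expect_true(z_test(0.5, 0.2))             # z = 2.5
  expect_false(z_test(0.465, 0.2))          # z = 2.325
  expect_false(z_test(0, 0.3))
  expect_true(z_test(-0.6, 0.2))            # two-sided
  expect_error(z_test(0.5, 0), "positive")
})

test_that("trait summaries use defined estimates and report denominators", {
  res <- data.frame(
    feature = rep(c("f1", "f2", "f3", "f4"), 2),
    trait = rep(c("BG", "WV"), each = 4),
    r_g = c(-0.9, -0.5, 0.2, NA, 0.1, 0.2, 0.3, 0.4),
    r_g_sig = c(TRUE, FALSE, FALSE, NA, FALSE, FALSE, FALSE, FALSE),
    r_p = c(-0.3, -0.2, 0.1, NA, 0.05, 0.1, 0.15, 0.2),
    r_p_sig = c(TRUE, TRUE, FALSE, NA, FALSE, FALSE, FALSE, FALSE),
    reason = c(NA, NA, NA, "zero_g_variance", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  s <- summarize_trait(res)
  bg <- s[s$trait == "BG", ]
  expect_equal(bg$n_pairs, 4L)
  expect_equal(bg$n_defined_g, 3L)
  expect_equal(bg$pct_sig_g, 100 / 3, tolerance = 1e-12)
  expect_equal(bg$min_r_g, -0.9)
  expect_equal(bg$max_r_g, 0.2)
  wv <- s[s$trait == "WV", ]
  expect_equal(wv$pct_sig_g, 0)
  # row order does not matter
  s2 <- summarize_trait(res[sample(nrow(res)), ])
  expect_equal(s2[order(s2$trait), ], s[order(s$trait), ], ignore_attr = TRUE)
})

test_that("descriptive statistics reproduce the CV definition", {
  # two-point sample with exact mean 224.75 and SD 133.65
  delta <- 133.65 / sqrt(2)
  bg <- c(224.75 - delta, 224.75 + delta)
  tab <- compute_descriptives(data.frame(plot = c("a", "b"), BG = bg))
  expect_equal(tab$mean, 224.75, tolerance = 1e-12)
  expect_equal(tab$sd, 133.65, tolerance = 1e-12)
  expect_equal(round(tab$cv, 2), 59.47)
  # hand evaluation on [1, 3]
  tab2 <- compute_descriptives(data.frame(plot = c("a", "b"), X = c(1, 3)))
  expect_equal(tab2$mean, 2)
  expect_equal(tab2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(round(tab2$cv, 2), 70.71)
  # constant trait
  tab3 <- compute_descriptives(data.frame(plot = c("a", "b"), C = c(5, 5)))
  expect_equal(tab3$sd, 0)
  expect_equal(tab3$cv, 0)
  expect_error(compute_descriptives(data.frame(plot = c("a", "b"),
                                               M = c(NA_real_, NA_real_))),
               "M")
  expect_error(compute_descriptives(data.frame(plot = c("a", "b"),
                                               S = c(1, NA))), "fewer than 2")
})

test_that("correlation scans produce one row per pair with consistent flags", {
  ts <- list(TT = list(variances = c(g = 0.3, l = 0.05, ig = 0.05, il = 0.1,
                                     t = 0.05, e = 0.45),
                       cov_g = c(-0.27, 0), cov_e = c(0, 0),
                       missing_rate = 0.05))
  fx <- small_sim(n_lines = 60, n_features = 2, seed = 81, h2 = 0.35,
                  trait_specs = ts)
  res <- estimate_correlations(fx$sim$features, fx$sim$traits, fx$design,
                               fx$sim$grm, trait_ids = "TT")
  expect_s3_class(res, "correlation_result")
  expect_equal(nrow(res), 2L)
  ok <- is.finite(res$r_g)
  expect_true(all(abs(res$r_g[ok]) <= 1))
  expect_true(all(abs(res$r_p[is.finite(res$r_p)]) <= 1))
  # z flags agree with the reported z scores
  for (i in which(ok & is.finite(res$r_g_z)))
    expect_equal(res$r_g_sig[i], abs(res$r_g_z[i]) > 2.326)
})
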