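make_fits <- function(D, mode = "brownian", alpha = 1) {
  data.frame(traj_id = seq_along(D), D_um2_s = D, intercept_um2 = 0,
             alpha = alpha, mode = mode, r2 = 1, n_frames = 100,
             flagged = FALSE, true_mode = mode, true_D = D)
}

test_that("summaries report median D, IQR and mode fractions", {
  fits <- make_fits(c(0.1, 0.2, 0.3), mode = c("confined", "brownian", "brownian"))
  expect_error(summarize_population(fits), "min_traj")
  sm <- suppressWarnings(summarize_population(fits, "g", override = TRUE))
  expect_identical(sm$median_D, 0.2)
  expect_equal(sm$mode_fractions[["confined"]], 1 / 3)
  expect_equal(sum(sm$mode_fractions), 1)
  # invariant to trajectory order
  sm2 <- suppressWarnings(summarize_population(fits[c(3, 1, 2), ], "g", override = TRUE))
  expect_identical(sm$median_D, sm2$median_D)
  expect_identical(sm$mode_fractions, sm2$mode_fractions)
})

test_that("undefined-alpha trajectories stay in D medians but not fractions", {
  fits <- make_fits(c(0.1, 0.2, 0.4, 0.8))
  fits$mode[4] <- NA; fits$alpha[4] <- NA
  sm <- suppressWarnings(summarize_population(fits, override = TRUE))
  expect_equal(sm$median_D, 0.3)  # pools all four
  expect_identical(sm$n_classified, 3L)
  expect_identical(sm$n_alpha_undefined, 1L)
})

test_that("group comparison runs ANOVA with Tukey HSD", {
  set.seed(15)
  base <- rlnorm(500, log(0.1), 0.5)
  # identical groups: Tukey p ~ 1
  cg <- compare_groups(list(a = base, b = base))
  expect_gt(cg$pairwise$p_adj, 0.99)
  # clearly separated groups at realistic spreads: p < 1e-4
  g1 <- rlnorm(1000, log(0.07), 0.5); g2 <- rlnorm(1000, log(0.18), 0.5)
  cg2 <- compare_groups(list(hpne = g1, patu = g2))
  expect_lt(cg2$pairwise$p_adj, 1e-4)
  expect_lt(cg2$p, 1e-4)
  # permutation invariance of the pairwise p-values
  g3 <- rlnorm(400, log(0.1), 0.5)
  pa <- compare_groups(list(x = g1, y = g2, z = g3))$pairwise
  pb <- compare_groups(list(z = g3, x = g1, y = g2))$pairwise
  key <- function(tab) {
    pairs <- strsplit(tab$pair, "-")
    nm <- vapply(pairs, function(p) paste(sort(p), collapse = "-"), "")
    setNames(tab$p_adj, nm)[order(nm)]
  }
  expect_equal(key(pa), key(pb), tolerance = 1e-9)
  expect_error(compare_groups(list(a = 1:5)), "2 groups")
  expect_error(compare_groups(list(a = 1:5, b = 1:2)), "n >= 3")
})

test_that("ANOVA holds its nominal type-I error on null simulations", {
  # 200 replicate null simulations, three identically distributed groups
  set.seed(99)
  rej <- vapply(1:200, function(i) {
    g <- lapply(1:3, function(j) rlnorm(50, log(0.1), 0.5))
    compare_groups(setNames(g, c("a", "b", "c")))$p < 0.05
  }, TRUE)
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("mobility-phenotype correlation follows Pearson conventions", {
  expect_equal(correlate_mobility(1:4, 2 * (1:4))$r, 1, tolerance = 1e-12)
  # published wound-closure ratios against per-line D medians
  ct <- correlate_mobility(c(0.07, 0.10, 0.13, 0.18), c(1.0, 1.7, 2.5, 4.0))
  expect_gt(ct$r, 0.95)
  expect_lt(correlate_mobility(1:5, c(5, 4, 3, 2, 1))$r, 0)
  expect_error(correlate_mobility(rep(1, 4), 1:4), "zero variance")
  expect_error(correlate_mobility(1:2, 1:2), "n >= 3")
})

test_that("percent change is exact, seeded, and bootstrap-covered", {
  set.seed(23)
  d <- rlnorm(800, log(0.18), 0.5)
  pc0 <- percent_change(d, d, seed = 7)
  expect_identical(pc0$percent_change, 0)
  expect_lte(pc0$ci[1], 0); expect_gte(pc0$ci[2], 0)
  # deterministic given seed
  pc1 <- percent_change(d, d * 0.78, seed = 7)
  pc2 <- percent_change(d, d * 0.78, seed = 7)
  expect_identical(pc1$ci, pc2$ci)
  expect_equal(pc1$percent_change, -22, tolerance = 1e-9)
  expect_error(percent_change(rep(0, 5), 1:5), "median is 0")
  expect_error(percent_change(numeric(0), 1:5), "nonempty")
})
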