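test_that("BSA formulas reproduce reference values and scaling", {
  expect_equal(compute_bsa(180, 72), sqrt(3.6), tolerance = 1e-12)
  # adolescent cohort group means give ~1.80 m^2
  expect_equal(compute_bsa(181.1, 64.4), 1.80, tolerance = 0.01)
  expect_equal(compute_bsa(170, 120) / compute_bsa(170, 60), sqrt(2),
               tolerance = 1e-12)
  expect_lt(abs(compute_bsa(180, 72, "dubois") - compute_bsa(180, 72)), 0.1)
  expect_error(compute_bsa(-1, 70), "positive")
})

test_that("Z-scores are affine-equivariant and flag dilation above 2", {
  m <- normative_model("sinus", "BSA", mean_coef = c(24), sd_coef = c(3),
                       range = c(0.4, 2.5))
  expect_equal(as.numeric(zscore(30, 1.5, m)), 2)
  expect_equal(as.numeric(zscore(24, 1.5, m)), 0)
  expect_true(attr(zscore(30.1, 1.5, m), "dilated"))
  expect_false(attr(zscore(29.9, 1.5, m), "dilated"))
  # shifting diameters and the normative mean by c leaves z unchanged
  m2 <- normative_model("sinus", "BSA", mean_coef = c(24 + 5), sd_coef = c(3),
                        range = c(0.4, 2.5))
  expect_equal(as.numeric(zscore(30 + 5, 1.5, m2)),
               as.numeric(zscore(30, 1.5, m)))
  expect_error(zscore(30, 3.5, m), "range")
  expect_error(normative_model("x", "BSA", c(24), c(-1), c(0.4, 2.5)), "SD")
})

test_that("shipped synthetic normative models load and evaluate", {
  mods <- load_normative_models()
  expect_true(all(c("sinus", "proximal_DAo") %in% names(mods)))
  z <- zscore(13.5 + 9.0 * 1.5 + 4, 1.5, mods$sinus)   # mean + 2 SD
  expect_equal(as.numeric(z), 2)
  expect_false(attr(z, "dilated"))
})

test_that("cohort reports run the full battery over a subject table", {
  path <- system.file("extdata", "subjects_synthetic.csv",
                      package = "aorta4d")
  subj <- read_subject_table(path)
  expect_true("bsa_m2" %in% names(subj))
  rep <- cohort_report(
    subj, normative = load_normative_models(),
    correlations = list(c("wss_prox_inner_dao", "z_proximal_DAo"),
                        c("wss_prox_inner_dao", "helix_vortex_grade")))
  expect_s3_class(rep, "cohort_report")
  expect_true(all(c("z_sinus", "z_proximal_DAo") %in% names(rep$subjects)))
  cmp <- rep$comparisons
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # every variable gets the paired and both group contrasts
  expect_true(all(table(cmp$contrast) > 0))
  expect_setequal(unique(cmp$contrast),
                  c("t1_vs_t2", "t1_vs_volunteer", "t2_vs_volunteer"))
  # the synthetic cohort encodes a lower patient WSS in the proximal
  # inner DAo than in volunteers
  row <- cmp[cmp$variable == "wss_prox_inner_dao" &
             cmp$contrast == "t2_vs_volunteer", ]
  expect_lt(row$p_value, 0.05)
  # correlations table covers both timepoints for each requested pair
  expect_equal(nrow(rep$correlations), 4)
  expect_true(all(abs(rep$correlations$r) <= 1))
})

test_that("paired comparisons gate on normality and handle degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_warning(r <- compare_paired(x, x), "zero")
  expect_equal(r$p_value, 1)
  expect_warning(r2 <- compare_paired(x, x + 1), "constant")
  set.seed(42)
  a <- rnorm(19); b <- a + rnorm(19, 0.5)
  r3 <- compare_paired(a, b)
  expect_true(r3$test %in% c("paired_t", "wilcoxon_signed_rank"))
  expect_true(r3$p_value >= 0 && r3$p_value <= 1)
})

test_that("gated paired test power tracks the closed-form t-test oracle", {
  set.seed(7)
  nrep <- 400
  rej <- mean(replicate(nrep, {
    x1 <- rnorm(19); x2 <- rnorm(19, 0.5)
    compare_paired(x1, x2)$p_value < 0.05
  }))
  oracle <- stats::power.t.test(n = 19, delta = 0.5, sd = sqrt(2),
                                type = "paired")$power
  expect_lt(abs(rej - oracle), 0.06)
})

test_that("two-group comparison holds its size and detects the WSS contrast", {
  set.seed(11)
  t1 <- mean(replicate(600, compare_groups(rnorm(19), rnorm(10))$p_value < 0.05))
  expect_gt(t1, 0.03); expect_lt(t1, 0.07)
  # group summaries like the proximal inner DAo contrast reject mostly
  pw <- mean(replicate(300, {
    compare_groups(rnorm(19, 0.60, 0.18), rnorm(10, 0.78, 0.15))$p_value < 0.05
  }))
  expect_gt(pw, 0.5)
  expect_warning(r <- compare_groups(rep(1, 5), rep(1, 5)), "constant")
  expect_equal(r$p_value, 1)
})

test_that("pearson correlation reproduces exact and simulated values", {
  x <- c(1, 2, 3, 4, 6)
  expect_equal(pearson(x, 2 * x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 5)), "variance")
  set.seed(5)
  rs <- replicate(400, {
    z <- rnorm(18); e <- rnorm(18)
    x <- z; y <- -0.6 * z + sqrt(1 - 0.36) * e
    pearson(x, y)$r
  })
  expect_lt(abs(mean(rs) - (-0.6)), 0.05)
})

test_that("Cohen's kappa matches the chance-corrected formula", {
  expect_equal(cohens_kappa(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # 2x2 table a=20, b=5, c=5, d=20: po=0.8, pe=0.5 -> kappa 0.6
  r1 <- rep(c(0, 0, 1, 1), c(20, 5, 5, 20))
  r2 <- rep(c(0, 1, 0, 1), c(20, 5, 5, 20))
  expect_equal(cohens_kappa(r1, r2), 0.6)
  # invariance under relabelling of categories
  expect_equal(cohens_kappa(3 - r1, 3 - r2), 0.6)
  # independent uniform ratings: kappa near zero
  set.seed(9)
  expect_lt(abs(cohens_kappa(sample(0:2, 3000, TRUE),
                             sample(0:2, 3000, TRUE))), 0.05)
  expect_error(cohens_kappa(rep(1, 4), rep(1, 4)), "single")
})

test_that("Bland-Altman limits are bias +/- 1.96 sd and flip with order", {
  m2 <- c(1, 1.1, 0.9)
  m1 <- m2 + c(-0.1, 0.1, 0.0)
  ba <- bland_altman(m1, m2)
  expect_equal(ba$bias, 0)
  expect_equal(ba$upper, 1.96 * sd(c(-0.1, 0.1, 0)), tolerance = 1e-12)
  expect_equal(ba$lower, -ba$upper, tolerance = 1e-12)
  expect_equal((ba$upper - ba$bias) + (ba$lower - ba$bias), 0,
               tolerance = 1e-12)
  # identical pairs: zero bias and zero-width limits
  b0 <- bland_altman(m2, m2)
  expect_equal(c(b0$bias, b0$lower, b0$upper), c(0, 0, 0))
  # swapping the pair order flips the bias sign
  ba2 <- bland_altman(m2, m1)
  expect_equal(ba2$bias, -ba$bias)
  # percent-of-mean bookkeeping
  set.seed(2)
  a <- rnorm(20, 0.74, 0.05); b <- a + rnorm(20, 0, 0.05)
  bb <- bland_altman(a, b)
  expect_equal(unname(bb$percent_of_mean["bias"]),
               100 * abs(bb$bias) / bb$mean_value, tolerance = 1e-12)
})
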