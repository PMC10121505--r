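# Oracles used here: stats::aov mean squares for the ICC ANOVA route and
# stats::binom.test for the exact binomial interval.

aov_icc_a1 <- function(x) {
  # independent ANOVA route via stats::aov on the long table
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

test_that("ICC forms behave as expected on canonical tables", {
  x <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  r <- icc(x)
  expect_equal(r$estimate, 1)
  expect_identical(r$band, "excellent")

  # constant offset: consistency perfect, absolute agreement below 1
  y <- cbind(1:5, 2:6)
  expect_equal(icc(y, form = "consistency")$estimate, 1)
  expect_lt(icc(y, form = "agreement")$estimate, 1)
  # frozen from the closed-form two-way ANOVA of the 5x2 table:
  # msr = 5, msc = 2.5, mse = 0 -> icc = 5 / (5 + 2*2.5/5)
  expect_equal(icc(y, form = "agreement")$estimate, 5 / 6)

  expect_error(icc(cbind(rep(1, 6), rep(1, 6))), "variance")
  expect_error(icc(x[1:3, ]), "subjects")
  expect_identical(vertmorph:::koo_band(0.85), "good")
  expect_identical(vertmorph:::koo_band(0.49), "poor")
})

test_that("ANOVA ICC matches the aov-based oracle on random tables", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(20, sd = 2), 10, 2) + rnorm(10)
    expect_equal(icc(x)$estimate, aov_icc_a1(x), tolerance = 1e-8)
  }
})

test_that("Cohen's kappa matches closed forms", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1))$estimate, 1)
  # perfect disagreement with balanced margins
  expect_equal(cohens_kappa(c("+", "+", "-", "-"), c("-", "-", "+", "+"))$estimate, -1)
  # the (45, 5; 5, 45) agreement table: po = 0.9, pe = 0.5 -> kappa 0.8
  a <- rep(c("pos", "pos", "neg", "neg"), c(45, 5, 5, 45))
  b <- rep(c("pos", "neg", "pos", "neg"), c(45, 5, 5, 45))
  r <- cohens_kappa(a, b)
  expect_equal(r$estimate, 0.8)
  expect_identical(r$band, "substantial")
  expect_error(cohens_kappa(rep("x", 5), rep("x", 5)), "undefined")
  # range property on random labelings
  set.seed(2)
  for (i in 1:25) {
    u <- sample(c("a", "b"), 30, replace = TRUE)
    v <- sample(c("a", "b"), 30, replace = TRUE)
    k <- try(cohens_kappa(u, v)$estimate, silent = TRUE)
    if (!inherits(k, "try-error")) expect_true(k >= -1 && k <= 1)
  }
})

test_that("Bland-Altman limits follow the 1.96 SD construction", {
  a <- c(10, 12, 14, 16)
  expect_equal(bland_altman(a, a)$loa_halfwidth, 0)
  r <- bland_altman(a, a + 0.5)
  expect_equal(r$mean_diff, -0.5)   # first minus second
  expect_equal(r$loa_halfwidth, 0)
  d <- c(1, -1, 1, -1)
  r2 <- bland_altman(d, rep(0, 4))
  expect_equal(r2$mean_diff, 0)
  expect_equal(r2$sd_diff, sd(d))
  expect_equal(r2$loa_halfwidth, 1.96 * 1.1547005, tolerance = 1e-6)
  expect_error(bland_altman(1, numeric(0)))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Clopper-Pearson matches binom.test and brackets the estimate", {
  for (x in c(0, 1, 7, 50)) {
    for (n in c(7, 50, 120)) {
      if (x > n) next
      ours <- clopper_pearson(x, n)
      ref <- stats::binom.test(x, n)$conf.int
      expect_equal(unname(ours), as.vector(ref), tolerance = 1e-10)
      expect_true(ours["lower"] <= x / n && x / n <= ours["upper"])
    }
  }
  # width shrinks with n at fixed proportion
  w <- vapply(c(10, 40, 160, 640),
              function(n) diff(clopper_pearson(round(0.3 * n), n)),
              numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("diagnostic metrics handle edge cases and report exact CIs", {
  cc <- contingency_counts(50, 0, 50, 0)
  m <- diagnostic_metrics(cc)
  expect_equal(m$estimate, c(1, 1, 1))
  # zero denominator: metric flagged NA, others intact
  cc2 <- contingency_counts(0, 3, 40, 0)
  m2 <- diagnostic_metrics(cc2)
  expect_true(is.na(m2$estimate[m2$metric == "sensitivity"]))
  expect_false(anyNA(m2$estimate[m2$metric != "sensitivity"]))
  # Wilson alternative stays inside [0, 1] and brackets the estimate
  m3 <- diagnostic_metrics(cc2, method = "wilson")
  sp3 <- m3[m3$metric == "specificity", ]
  expect_true(sp3$lower <= sp3$estimate && sp3$estimate <= sp3$upper)
  expect_error(contingency_counts(-1, 0, 1, 0))
  expect_error(contingency_counts(0, 0, 0, 0), "empty")
})

test_that("CI overlap decides significance with touching = overlap", {
  a <- list(lower = 0.903, upper = 0.968)
  b <- list(lower = 0.954, upper = 0.980)
  expect_false(ci_overlap_significant(a, b))
  expect_true(ci_overlap_significant(list(lower = 0.10, upper = 0.20),
                                     list(lower = 0.30, upper = 0.40)))
  expect_false(ci_overlap_significant(list(lower = 0.10, upper = 0.30),
                                      list(lower = 0.30, upper = 0.40)))
})
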