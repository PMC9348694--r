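# Textbook pooled-variance two-sample t, used as the independent oracle
# for the two-condition GLM.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
}

test_that("condition summaries report closed-form means/SEMs and tie-break to the lower numerosity", {
  cs <- condition_summary(c(1, 3, 2, 2), c("1", "1", "4", "4"))
  expect_equal(cs$summary$mean, c(2, 2))
  expect_equal(cs$summary$sem[1], 1)   # sd(c(1,3))/sqrt(2)
  # equal means: preferred is the lower numerosity
  expect_equal(cs$preferred, "1")

  # levels ordered numerically, not lexically
  cs2 <- condition_summary(c(0, 0, 1, 2, 5, 5),
                           c("20", "20", "3", "3", "7", "7"))
  expect_equal(cs2$summary$condition, c("3", "7", "20"))
  expect_equal(cs2$preferred, "7")

  expect_error(condition_summary(c(1, 2), c("1", "1"), levels = c("1", "2")),
               "no retained trials")
})

test_that("dummy-coded GLM matches the pooled two-sample t oracle", {
  # fixed two-condition example
  fitx <- fit_condition_glm(c(1, 2, 3, 2, 3, 4),
                            rep(c("A", "B"), each = 3), reference = "A")
  expect_equal(fitx$glm$t[2], pooled_t(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-9)

  # 100 random two-condition fixtures
  set.seed(61)
  for (i in 1:100) {
    na <- sample(3:30, 1); nb <- sample(3:30, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 2))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    fit <- fit_condition_glm(c(a, b), c(rep("A", na), rep("B", nb)),
                             reference = "A")
    expect_equal(fit$glm$t[fit$glm$term == "B"], pooled_t(a, b),
                 tolerance = 1e-9)
    expect_equal(fit$df, na + nb - 2)
  }

  # identical scalar sets give a dummy t of exactly 0
  same <- fit_condition_glm(c(1, 2, 3, 1, 2, 3),
                            rep(c("A", "B"), each = 3), reference = "A")
  expect_equal(same$glm$t[2], 0)
})

test_that("GLM df bookkeeping gives N_kept minus n_conditions", {
  set.seed(62)
  scalars <- rnorm(216)
  conds <- rep(as.character(c(1:7, 20)), each = 27)
  keep <- rep(TRUE, 216)
  keep[sample(216, 36)] <- FALSE
  fit <- fit_condition_glm(scalars, conds, keep = keep)
  expect_equal(fit$df, 180 - 8)
  expect_true(all(fit$glm$df == 172))
  # intercept is the preferred-condition mean
  cs <- condition_summary(scalars, conds, keep)
  expect_equal(fit$glm$estimate[1],
               cs$summary$mean[cs$summary$condition == fit$preferred])
})

test_that("electrode classification separates tuned, energy, flat, and nonresponsive patterns", {
  set.seed(63)
  lv <- as.character(c(1:7, 20))
  mk <- function(mu_by_cond, n = 20, sd = 1) {
    scal <- unlist(lapply(mu_by_cond, function(m) rnorm(n, m, sd)))
    conds <- rep(lv, each = n)
    classify_electrode(fit_condition_glm(scal, conds))
  }
  # sharp peak at 4
  tuned <- mk(c(0, 0.5, 2, 5, 2, 0.5, 0, 0))
  expect_equal(tuned$label, "tuned")
  expect_equal(tuned$preferred, "4")
  # monotone increase peaking at 20
  energy <- mk(c(1, 1.5, 2, 2.5, 3, 3.5, 4, 8))
  expect_equal(energy$label, "energy_monotonic")
  # strong uniform response
  flat <- mk(rep(5, 8))
  expect_equal(flat$label, "flat_responsive")
  # no response: the gate is calibrated to a 5% false-responsive rate,
  # so check the rate over repetitions rather than a single draw
  null_labels <- replicate(20, mk(rep(0, 8))$label)
  expect_gte(sum(null_labels == "nonresponsive"), 16)
  # preference at the lowest numerosity still counts as tuned
  low <- mk(c(5, 2, 0.5, 0, 0, 0, 0, 0))
  expect_equal(low$label, "tuned")
  expect_equal(low$preferred, "1")
})

test_that("category comparison contrasts each category against the preferred numerosity", {
  set.seed(64)
  num <- rnorm(20, mean = 3)
  cats <- rep(c("face", "letter", "house"), each = 12)

  # categories 5 SDs below the numerosity response: all strongly negative
  low <- rnorm(36, mean = -2)
  cmp <- compare_with_categories(num, low, cats)
  expect_true(all(cmp$glm$estimate[-1] < 0))
  expect_true(all(cmp$glm$p[-1] < 0.001))
  expect_equal(cmp$df, 20 + 36 - 4)

  # same-distribution null: dummy t equals the pooled two-sample t oracle
  same <- rnorm(36, mean = 3)
  cmp2 <- compare_with_categories(num, same, cats)
  for (cc in c("face", "letter", "house")) {
    expect_lt(abs(cmp2$glm$t[cmp2$glm$term == cc]), 4)
  }

  expect_error(compare_with_categories(num, low[1:24], cats[1:24]),
               "house")
})

test_that("category-comparison false-positive rate is nominal under the null", {
  # seeded null calibration: category trials drawn from the same
  # distribution as the reference trials
  set.seed(6)
  reps <- 500
  hits <- 0
  tests <- 0
  for (i in seq_len(reps)) {
    num <- rnorm(20)
    cat_s <- rnorm(36)
    cats <- rep(c("face", "letter", "house"), each = 12)
    cmp <- compare_with_categories(num, cat_s, cats)
    hits <- hits + sum(cmp$glm$p[-1] < 0.05)
    tests <- tests + 3
  }
  expect_equal(hits / tests, 0.05, tolerance = 0.35)
})
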