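# AUC, bootstrap CIs, correlation screening, model selection, ANOVA,
# descriptive tables.

test_that("AUC matches hand-enumerated pair counts", {
  v <- c(2, 3, 4, 1, 2, 3)
  l <- rep(c("control", "case"), each = 3)
  expect_equal(auc_scalar(v, l), 7 / 9)
  expect_equal(auc_scalar(c(5, 6, 1, 2), c("control", "control", "case", "case")), 1)
  expect_equal(auc_scalar(rep(1, 8), rep(c("control", "case"), 4)), 0.5)
  expect_error(auc_scalar(1:4, rep("control", 4)), class = "invalidLabels")
})

test_that("threshold-sweep AUC equals brute-force pair counting exactly", {
  phonmark:::with_seed(61, {
    for (i in 1:500) {
      n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
      v <- sample(1:6, n1 + n2, replace = TRUE)  # heavy ties
      l <- c(rep("control", n1), rep("case", n2))
      expect_identical(auc_scalar(v, l), auc_brute_force(v, l, "control"))
    }
  })
})

test_that("reversing class labels maps AUC to its complement", {
  phonmark:::with_seed(62, {
    v <- stats::rnorm(30)
    l <- rep(c("control", "case"), 15)
    expect_equal(auc_scalar(v, l, controls = "control"),
                 1 - auc_scalar(v, l, controls = "case"))
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  phonmark:::with_seed(63, {
    v <- c(stats::rnorm(25, 1), stats::rnorm(20))
    l <- c(rep("control", 25), rep("case", 20))
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(l, v, levels = c("case", "control"),
                          direction = "<"))))
    expect_equal(auc_scalar(v, l), ref, tolerance = 1e-12)
  })
})

test_that("bootstrap CI brackets the point estimate and is reproducible", {
  phonmark:::with_seed(64, {
    v <- c(stats::rnorm(20, 1.5), stats::rnorm(20))
    l <- c(rep("control", 20), rep("case", 20))
  })
  r1 <- bootstrap_auc_ci(v, l, n_boot = 500, seed = 9)
  r2 <- bootstrap_auc_ci(v, l, n_boot = 500, seed = 9)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, r1$auc)
  expect_gte(r1$ci_high, r1$auc)
  expect_equal(r1$n_controls, 20)
  # all-tie degenerate data: CI collapses on 0.5
  rt <- bootstrap_auc_ci(rep(3, 20), rep(c("control", "case"), 10),
                         n_boot = 500, seed = 10)
  expect_lt(rt$ci_high - rt$ci_low, 0.05)
  expect_equal(rt$auc, 0.5)
})

test_that("correlation screen retains related features and drops noise", {
  tab <- phonmark:::with_seed(65, {
    base <- stats::rnorm(200)
    data.frame(mfcc_mn_2 = base,
               linear = 2 * base + 1,
               monotone = exp(base),
               noise = stats::rnorm(200))
  })
  sc_p <- correlation_screen(tab, "mfcc_mn_2", c("linear", "monotone", "noise"),
                             method = "pearson")
  expect_equal(unname(sc_p$full_matrix["linear", "mfcc_mn_2"]), 1)
  expect_true("linear" %in% sc_p$retained)
  expect_false("noise" %in% sc_p$retained)
  sc_s <- correlation_screen(tab, "mfcc_mn_2", c("monotone", "noise"),
                             method = "spearman")
  expect_equal(unname(sc_s$full_matrix["monotone", "mfcc_mn_2"]), 1)
  # constant column: zeroed with warning
  tab$flat <- 1
  expect_warning(sc_c <- correlation_screen(tab, "mfcc_mn_2", "flat"),
                 "constant")
  expect_equal(unname(sc_c$full_matrix["flat", "mfcc_mn_2"]), 0)
  expect_error(correlation_screen(tab[1:5, ], "mfcc_mn_2", "noise"),
               class = "invalidInput")
})

test_that("AIC selection recovers an injected sex effect", {
  tab <- phonmark:::with_seed(66, {
    sex <- rep(c("male", "female"), 200)
    data.frame(sex = sex, age = stats::runif(400, 40, 80),
               y = 10 + 5 * (sex == "male") + stats::rnorm(400))
  })
  sel <- ols_aic_select(tab, "y", factors = c("sex", "age"))
  expect_true("sex" %in% sel$best$factor_set)
  co <- sel$best$coefficients
  expect_true(co["sexmale", "Estimate"] >= 4 && co["sexmale", "Estimate"] <= 6)
})

test_that("AIC selection rejects pure-noise factors most of the time", {
  hits <- phonmark:::with_seed(67, {
    vapply(1:25, function(i) {
      tab <- data.frame(sex = rep(c("male", "female"), 200),
                        y = stats::rnorm(400))
      sel <- ols_aic_select(tab, "y", factors = "sex")
      length(sel$best$factor_set) == 0
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("duplicated factor columns raise a rank error", {
  tab <- data.frame(y = stats::rnorm(20), a = rep(c("x", "y"), 10))
  tab$b <- tab$a
  expect_error(ols_aic_select(tab, "y", list(c("a", "b"))),
               class = "rankDeficient")
})

test_that("one-way ANOVA handles separation, null and degenerate input", {
  g <- rep(c("a", "b"), each = 50)
  v <- phonmark:::with_seed(68, c(stats::rnorm(50), stats::rnorm(50, 5)))
  res <- one_way_anova(v, g)
  expect_lt(res$p_value, 1e-6)
  # identical copies of one group: F = 0
  same <- rep(c(1, 2, 3), 2)
  res0 <- one_way_anova(same, rep(c("a", "b"), each = 3))
  expect_equal(res0$f_statistic, 0)
  # fully degenerate: constant everywhere
  resd <- one_way_anova(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(resd$f_statistic, 0)
  expect_equal(resd$p_value, 1)
  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")),
               class = "invalidInput")
})

test_that("null ANOVA p-values are uniform across seeded replicates", {
  ps <- phonmark:::with_seed(69, {
    vapply(1:200, function(i) {
      v <- stats::rnorm(45)
      one_way_anova(v, rep(c("a", "b", "c"), each = 15))$p_value
    }, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("descriptive table has the documented shape and degenerate SDs", {
  tab <- data.frame(dataset = "synth", sex = rep(c("m", "f"), each = 2),
                    group = rep(c("control", "case"), 2),
                    m1 = c(1, 2, 3, 4), m2 = c(5, 6, 7, 8))
  dt <- descriptive_table(tab, c("m1", "m2"))
  expect_equal(nrow(dt), 4)                      # one row per populated cell
  expect_equal(ncol(dt), 2 * 2 + 3 + 1)          # metrics*2 + grouping + n
  expect_true(all(dt$m1_sd == 0))                # single row per cell
  expect_error(descriptive_table(tab, "m1", by = "absent"),
               class = "invalidInput")
})
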