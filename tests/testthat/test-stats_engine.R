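mk_groups <- function(n0, n1, n2) {
  factor(rep(c("control", "case_I", "case_II"), c(n0, n1, n2)),
         levels = c("control", "case_I", "case_II"))
}

test_that("Dunnett reduces to the pooled t-test and matches multcomp", {
  set.seed(210)
  g <- mk_groups(40, 15, 25)
  x <- stats::rnorm(80) + 0.8 * (g == "case_II")
  dt <- dunnett_test(x, g)
  expect_true(all(dt$p_adjusted >= dt$p_unadjusted))
  expect_true(all(dt$p_adjusted >= 0 & dt$p_adjusted <= 1))
  # independent oracle
  fit <- stats::aov(x ~ g)
  glh <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(unname(dt$p_adjusted), as.numeric(glh$test$pvalues),
               tolerance = 1e-4)
  # one case group: plain two-sample pooled t-test
  keep <- g != "case_II"
  dt1 <- dunnett_test(x[keep], droplevels(g[keep]))
  tt <- stats::t.test(x[keep] ~ droplevels(g[keep]), var.equal = TRUE)
  expect_equal(dt1$p_adjusted, tt$p.value, tolerance = 1e-12)
})

test_that("Dunnett handles degenerate input", {
  g <- mk_groups(5, 5, 5)
  expect_warning(dt <- dunnett_test(rep(3, 15), g), "zero pooled variance")
  expect_equal(dt$p_adjusted, c(1, 1))
  expect_equal(dt$statistic, c(0, 0))
  expect_error(dunnett_test(rnorm(11), mk_groups(5, 1, 5)), "at least 2")
})

test_that("Steel reduces to the tie-corrected Wilcoxon and flags extremes", {
  set.seed(77)
  g <- mk_groups(50, 20, 30)
  x <- stats::rbinom(100, 1, ifelse(g == "control", 0.3, 0.6))
  st <- steel_test(x, g)
  expect_true(all(st$p_adjusted >= st$p_unadjusted))
  keep <- g != "case_II"
  st1 <- steel_test(x[keep], droplevels(g[keep]))
  wt <- stats::wilcox.test(x[g == "case_I"], x[g == "control"],
                           correct = FALSE, exact = FALSE)
  expect_equal(st1$p_adjusted, wt$p.value, tolerance = 1e-12)
  # complete separation at n = 50 per arm
  g2 <- mk_groups(50, 50, 50)
  x2 <- c(rep(0, 50), rep(1, 100))
  st2 <- steel_test(x2, g2)
  expect_true(all(st2$p_adjusted < 0.001))
  expect_warning(steel_test(rep(1, 150), g2), "constant")
})

test_that("Steel normal approximation tracks the permutation null", {
  set.seed(90)
  g <- mk_groups(60, 20, 40)
  x <- stats::rbinom(120, 1, 0.4 + 0.15 * (g != "control"))
  st <- steel_test(x, g)
  stp <- steel_test(x, g, method = "permutation", n_perm = 20000)
  expect_equal(st$p_adjusted, stp$p_adjusted, tolerance = 0.015)
})

test_that("proportional-odds fit matches the reference implementation", {
  d <- generate_regression_dataset(3000, c(x1 = log(2), x2 = -0.5),
                                   c(-1.5, -2.5), seed = 12)
  f <- fit_proportional_odds(d$x, d$y)
  df <- cbind(as.data.frame(d$x), y = factor(d$y, ordered = TRUE))
  pf <- MASS::polr(y ~ x1 + x2, data = df, Hess = TRUE)
  expect_equal(f$coefficients$estimate, unname(stats::coef(pf)),
               tolerance = 1e-5)
  expect_equal(unname(f$intercepts), unname(-pf$zeta), tolerance = 1e-5)
  expect_equal(f$coefficients$std_error,
               unname(sqrt(diag(stats::vcov(pf)))[1:2]), tolerance = 1e-4)
  expect_lt(f$gradient_norm, 1e-6)
  expect_true(f$converged)
  expect_true(all(f$coefficients$ci_low <= f$coefficients$or &
                    f$coefficients$or <= f$coefficients$ci_high))
})

test_that("intercept-only fit equals empirical cumulative logits", {
  d <- generate_regression_dataset(400, c(x1 = 0.4), c(-0.5, -1.5), seed = 5)
  f0 <- fit_proportional_odds(NULL, d$y)
  emp <- rev(cumsum(rev(table(d$y) / length(d$y))))[-1]
  expect_equal(unname(f0$intercepts), unname(stats::qlogis(emp)),
               tolerance = 1e-10)
})

test_that("reversing the outcome order negates and swaps the parameters", {
  d <- generate_regression_dataset(2000, c(x1 = log(2)), c(-1, -2), seed = 9)
  f <- fit_proportional_odds(d$x, d$y)
  fr <- fit_proportional_odds(d$x, 2L - d$y)
  expect_equal(fr$coefficients$estimate, -f$coefficients$estimate,
               tolerance = 1e-7)
  expect_equal(unname(fr$intercepts), unname(-rev(f$intercepts)),
               tolerance = 1e-7)
})

test_that("fit rejects unusable inputs", {
  d <- generate_regression_dataset(100, c(x1 = 0), c(-1, -2), seed = 2)
  expect_error(fit_proportional_odds(d$x, rep(0:1, 50)), "at least 3")
  x_const <- cbind(d$x, z = 1)
  expect_error(fit_proportional_odds(x_const, d$y), "constant covariate")
})

test_that("two-step selection applies significance, incidence, collinearity
           and forcing rules with an audit trail", {
  desc <- tibble::tibble(
    variable = c("back_pain", "bone_metastasis", "distant_metastasis",
                 "rare_flag", "spondylosis", "age"),
    type = c(rep("categorical", 5), "continuous"),
    stat_control = c(44.1, 15.2, 32.0, 1.2, 8.1, 64.5),
    stat_case_I = c(67.6, 43.2, 62.2, 2.1, 6.3, 60.5),
    stat_case_II = c(64.7, 40.8, 63.2, 2.2, 13.0, 60.9),
    p_case_I = c(1e-5, 1e-5, 1e-5, 0.001, 0.74, 0.002),
    p_case_II = c(1e-5, 1e-5, 1e-5, 0.002, 1e-5, 1e-5))
  sel <- select_variables(desc, selection_config(
    collinear_pairs = list(c(drop = "bone_metastasis",
                             keep = "distant_metastasis")),
    force_include = c(spondylosis = "clinical perspective")))
  expect_true("back_pain" %in% sel$selected)
  expect_true("age" %in% sel$selected)
  expect_false("bone_metastasis" %in% sel$selected)
  expect_true("distant_metastasis" %in% sel$selected)
  # significant in both but below the 5% incidence floor
  expect_false("rare_flag" %in% sel$selected)
  expect_true("spondylosis" %in% sel$selected)
  aud <- sel$audit
  expect_match(aud$reason[aud$variable == "spondylosis" &
                            aud$stage == "step2"], "clinical perspective")
  expect_match(aud$reason[aud$variable == "bone_metastasis" &
                            aud$stage == "step2"], "distant_metastasis")
  # the permissive reading keeps the rare-but-significant flag
  sel_or <- select_variables(desc, selection_config(categorical_rule = "or"))
  expect_true("rare_flag" %in% sel_or$selected)
})
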