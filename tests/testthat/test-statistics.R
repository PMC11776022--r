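test_that("tertile cuts and tie handling follow the percentile convention", {
  t9 <- assign_tertiles(1:9)
  expect_equal(t9$cuts, as.numeric(quantile(1:9, c(1, 2) / 3, type = 7)))
  expect_equal(as.vector(table(t9$group)), c(3, 3, 3))

  expect_error(assign_tertiles(rep(5, 10)), "distinct")
  expect_error(assign_tertiles(c(1, 2)), "distinct")

  # ties on a cut point fall into the lower group
  x <- c(1, 2, 3, 3, 3, 5, 6, 7, 9)
  tt <- assign_tertiles(x)
  expect_true(all(tt$group[x == tt$cuts[1]] == "T1"))
  # groups are exhaustive and disjoint
  expect_false(anyNA(tt$group))

  # a cohort simulated at the calibrated MVPA distribution reproduces the
  # observed tertile boundaries (first < 30.7, third > 49.3)
  co <- generate_cohort(cohort_spec(n = 92, seed = 29))
  cuts <- assign_tertiles(co$mvpa)$cuts
  expect_lt(abs(cuts[1] - 30.7), 5)
  expect_lt(abs(cuts[2] - 49.3), 6)
})

test_that("tertile comparison gates between ANOVA/Tukey and KW/Bonferroni-MWU", {
  # three identical groups: omnibus p ~ 1, no significant pairs
  g <- factor(rep(c("T1", "T2", "T3"), each = 9))
  y <- rep(rep(c(1, 2, 3), each = 3), 3)
  res <- compare_tertiles(y, g)
  expect_gte(res$p_value, 0.99)
  expect_true(all(res$posthoc$p_adjusted > 0.9))

  # separated third group: omnibus significant, only pairs with group 3
  set.seed(42)
  y2 <- c(rnorm(30, 0, 0.5), rnorm(30, 0, 0.5), rnorm(30, 1, 0.5))
  g2 <- factor(rep(c("T1", "T2", "T3"), each = 30))
  res2 <- compare_tertiles(y2, g2)
  expect_lt(res2$p_value, 0.01)
  ph <- res2$posthoc
  sig <- ph$p_adjusted < 0.05
  expect_identical(sig, ph$group2 == "T3" | ph$group1 == "T3")

  # agreement with direct reference computations on random data
  set.seed(7)
  for (i in 1:10) {
    y3 <- rnorm(45) + rep(c(0, 0.3, 0.8), each = 15)
    g3 <- factor(rep(c("a", "b", "c"), each = 15))
    mine <- compare_tertiles(y3, g3, force = "anova")
    ref <- summary(aov(y3 ~ g3))[[1]]
    expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
    tuk <- TukeyHSD(aov(y3 ~ g3))$g3
    expect_equal(mine$posthoc$p_adjusted,
                 unname(tuk[c("b-a", "c-a", "c-b"), "p adj"]), tolerance = 1e-8)

    mine_kw <- compare_tertiles(y3, g3, force = "kruskal")
    ref_kw <- kruskal.test(y3, g3)
    expect_equal(mine_kw$statistic, unname(ref_kw$statistic), tolerance = 1e-8)
    w_ab <- wilcox.test(y3[g3 == "a"], y3[g3 == "b"], exact = FALSE)$p.value
    expect_equal(mine_kw$posthoc$p_adjusted[1], min(3 * w_ab, 1), tolerance = 1e-8)
  }

  expect_error(compare_tertiles(1:5, factor(c("a", "a", "a", "a", "b"))),
               "n >= 2")
})

test_that("the adjusted model matches exact and analytic oracles", {
  # noiseless outcome: exact recovery with zero-width intervals
  set.seed(5)
  n <- 40
  co <- data.frame(mvpa = rnorm(n, 40, 15), st_pct = rnorm(n, 72, 7),
                   age = rnorm(n, 33, 5), bmi = rnorm(n, 33, 2),
                   gdm = rbinom(n, 1, 0.3), fetal_sex = rbinom(n, 1, 0.5))
  co$y <- 2 * co$mvpa + 1
  fit <- suppressWarnings(fit_adjusted_model(co, "y"))  # perfect-fit notice
  b <- fit$table
  expect_equal(b$beta[b$term == "mvpa"], 2, tolerance = 1e-10)
  expect_lt(max(b$ci_high - b$ci_low), 1e-6)

  # standardized beta equals beta * sd(x) / sd(y)
  co$y <- co$y + rnorm(n, 0, 3)
  fit2 <- fit_adjusted_model(co, "y")
  b2 <- fit2$table
  expect_equal(b2$sb[b2$term == "mvpa"],
               b2$beta[b2$term == "mvpa"] * sd(co$mvpa) / sd(co$y),
               tolerance = 1e-10)

  # normal-equations oracle on random full-rank designs
  set.seed(11)
  for (i in 1:5) {
    co_i <- co
    co_i$y <- rnorm(n, 50, 6)
    fit_i <- fit_adjusted_model(co_i, "y")
    X <- cbind(1, as.matrix(co_i[c("mvpa", "st_pct", "age", "bmi", "gdm",
                                   "fetal_sex")]))
    beta_ne <- solve(t(X) %*% X, t(X) %*% co_i$y)
    expect_equal(fit_i$table$beta, as.numeric(beta_ne), tolerance = 1e-8)
  }

  # permuting rows changes nothing
  perm <- sample(n)
  fit_p <- fit_adjusted_model(co[perm, ], "y")
  expect_equal(fit_p$table$beta, fit2$table$beta, tolerance = 1e-12)

  # rank-deficient design names the collinear term
  co_bad <- co
  co_bad$bmi <- co_bad$age
  expect_error(fit_adjusted_model(co_bad, "y"), "collinear")

  # sex-interaction variant adds the two interaction terms
  fit_sx <- fit_adjusted_model(co, "y", sex_interaction = TRUE)
  expect_true(all(c("mvpa:fetal_sex", "st_pct:fetal_sex") %in% fit_sx$table$term))
})

test_that("the mixed model matches OLS in the no-clustering limit and reports an LRT", {
  coeffs <- outcome_model_coefficients("density_whole")
  co <- generate_cohort(cohort_spec(n = 90, coefficients = coeffs,
                                    country_random_intercept_sd = 0, seed = 32))
  mf <- fit_mixed_model(co, "density_whole")
  ols <- fit_adjusted_model(co, "density_whole")
  # at the estimated zero-variance boundary GLS collapses to OLS
  expect_lt(mf$cluster_variance, 1e-6)
  expect_equal(mf$fixed$beta[mf$fixed$term == "mvpa"],
               ols$table$beta[ols$table$term == "mvpa"], tolerance = 1e-3)
  expect_gte(mf$cluster_variance, 0)
  expect_gte(mf$lrt$statistic, 0)
  expect_identical(mf$lrt$df, 2)
  expect_error(fit_mixed_model(transform(co, country = "AT"), "density_whole"),
               "two clusters")

  # curvature-based SE of the cluster variance is finite when tau^2 > 0
  co2 <- generate_cohort(cohort_spec(n = 90, country_random_intercept_sd = 2,
                                     seed = 33))
  mf2 <- fit_mixed_model(co2, "density_whole")
  expect_gt(mf2$cluster_variance, 0)
  if (!is.na(mf2$cluster_variance_se)) expect_gt(mf2$cluster_variance_se, 0)
})

test_that("sensitivity analyses exclude the right rows and keep subsets honest", {
  co <- generate_cohort(cohort_spec(n = 92, seed = 37))
  sens <- sensitivity_analysis(co, "density_whole")
  expect_setequal(unique(sens$analysis),
                  c("main", "no_smokers", "no_gdm", "no_pe_pih"))

  main_n <- unique(sens$n_used[sens$analysis == "main"])
  # complete data: each subset drops exactly the flagged rows
  expect_identical(unique(sens$n_used[sens$analysis == "no_smokers"]),
                   main_n - sum(co$smoking == 1))
  expect_identical(unique(sens$n_used[sens$analysis == "no_gdm"]),
                   main_n - sum(co$gdm == 1))
  expect_identical(unique(sens$n_used[sens$analysis == "no_pe_pih"]),
                   main_n - sum(co$pe_pih == 1))
  # the GDM covariate is dropped where it is constant
  expect_false("gdm" %in% sens$term[sens$analysis == "no_gdm"])
  expect_true("gdm" %in% sens$term[sens$analysis == "main"])

  # no excluded rows: those subsets reproduce the main fit exactly
  co0 <- co
  co0$smoking <- 0L; co0$pe_pih <- 0L
  sens0 <- sensitivity_analysis(co0, "density_whole")
  for (an in c("no_smokers", "no_pe_pih")) {
    expect_equal(sens0$beta[sens0$analysis == an],
                 sens0$beta[sens0$analysis == "main"], tolerance = 1e-12)
  }

  # effects homogeneous across subgroups: subset betas near the main beta
  b_main <- sens$beta[sens$analysis == "main" & sens$term == "mvpa"]
  for (an in c("no_smokers", "no_gdm", "no_pe_pih")) {
    b_sub <- sens$beta[sens$analysis == an & sens$term == "mvpa"]
    expect_lt(abs(b_sub - b_main), 0.1)
  }
})
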