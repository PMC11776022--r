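#' Tertile assignment
#'
#' Cut points at the 33.33rd and 66.67th percentiles (linear
#' interpolation, `stats::quantile` type 7); values equal to a cut point
#' fall in the lower group, so the groups are exhaustive and disjoint.
#'
#' @param values numeric vector, n >= 3 with >= 3 distinct values.
#' @return list: `group` (ordered factor T1 < T2 < T3), `cuts` (the two
#'   cut points).
#' @export
assign_tertiles <- function(values) {
  abort_if(length(values) < 3 || length(unique(values)) < 3,
           "tertiles need at least 3 distinct values")
  cuts <- as.numeric(stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE))
  abort_if(cuts[1] >= cuts[2], "tertile cut points are not distinct")
  group <- cut(values, breaks = c(-Inf, cuts, Inf),
               labels = c("T1", "T2", "T3"), right = TRUE, ordered_result = TRUE)
  list(group = group, cuts = cuts)
}

#' Compare an outcome between tertile groups
#'
#' Gate: Shapiro-Wilk per group at `alpha_normality`; if every group is
#' compatible with normality, one-way ANOVA with Tukey HSD post-hoc,
#' otherwise Kruskal-Wallis with Bonferroni-corrected pairwise
#' Mann-Whitney U tests (correction factor = number of pairs).
#'
#' @param outcome numeric outcome vector.
#' @param groups factor of group labels (same length).
#' @param alpha_normality Shapiro-Wilk significance gate (default 0.05).
#' @param force one of "auto", "anova", "kruskal" to override the gate.
#' @return list of class `tertile_result`: `test` ("anova_tukey" or
#'   "kw_bonf_mwu"), `statistic`, `p_value`, `posthoc` data.frame
#'   (group1, group2, p_adjusted), `group_n`.
#' @export
compare_tertiles <- function(outcome, groups, alpha_normality = 0.05,
                             force = c("auto", "anova", "kruskal")) {
  force <- match.arg(force)
  keep <- is.finite(outcome) & !is.na(groups)
  outcome <- outcome[keep]; groups <- droplevels(factor(groups[keep]))
  abort_if(nlevels(groups) < 2, "need at least two non-empty groups")
  n_by <- table(groups)
  abort_if(any(n_by < 2), "every group needs n >= 2")

  use_anova <- switch(force,
    anova = TRUE, kruskal = FALSE,
    auto = all(vapply(levels(groups), function(g) {
      x <- outcome[groups == g]
      if (length(unique(x)) < 3) return(FALSE)   # SW undefined; be conservative
      stats::shapiro.test(x)$p.value >= alpha_normality
    }, logical(1))))

  pairs <- utils::combn(levels(groups), 2)
  if (use_anova) {
    fit <- stats::aov(outcome ~ groups)
    an <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)$groups
    key <- paste(pairs[2, ], pairs[1, ], sep = "-")
    posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          p_adjusted = tuk[key, "p adj"],
                          stringsAsFactors = FALSE)
    res <- list(test = "anova_tukey", statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1])
  } else {
    kw <- stats::kruskal.test(outcome, groups)
    praw <- apply(pairs, 2, function(pr) {
      stats::wilcox.test(outcome[groups == pr[1]], outcome[groups == pr[2]],
                         exact = FALSE)$p.value
    })
    posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          p_adjusted = pmin(praw * ncol(pairs), 1),
                          stringsAsFactors = FALSE)
    res <- list(test = "kw_bonf_mwu", statistic = unname(kw$statistic),
                p_value = kw$p.value)
  }
  rownames(posthoc) <- NULL
  structure(c(res, list(posthoc = posthoc, group_n = as.vector(n_by))),
            class = "tertile_result")
}

default_adjustment_set <- function() c("age", "bmi", "gdm", "fetal_sex")

#' Adjusted linear model of a placental outcome on MVPA and % ST
#'
#' Ordinary least squares of the outcome on both exposures jointly plus
#' the adjustment set (maternal age, pre-pregnancy BMI, GDM, fetal sex),
#' complete cases only. 95% CIs use the t distribution; the standardized
#' beta of each term is beta x sd(x)/sd(y) on the analysed rows.
#' `sex_interaction = TRUE` adds MVPA x sex and ST x sex terms (the
#' effect-modification check).
#'
#' @param cohort cohort data.frame.
#' @param outcome name of the outcome column.
#' @param exposures exposure column names (default mvpa, st_pct).
#' @param covariates adjustment columns.
#' @param sex_interaction add exposure-by-sex interaction terms.
#' @param conf_level CI level (default 0.95).
#' @return object of class `model_fit`: data.frame `table` (term, beta,
#'   ci_low, ci_high, sb, p), `n_used`, `outcome`, `lm` (the fitted
#'   model).
#' @export
fit_adjusted_model <- function(cohort, outcome,
                               exposures = c("mvpa", "st_pct"),
                               covariates = default_adjustment_set(),
                               sex_interaction = FALSE,
                               conf_level = 0.95) {
  terms <- c(exposures, covariates)
  abort_if(!all(c(terms, outcome) %in% names(cohort)),
           "cohort lacks required columns")
  dat <- cohort[stats::complete.cases(cohort[, c(outcome, terms)]),
                c(outcome, terms), drop = FALSE]
  abort_if(nrow(dat) < length(terms) + 2, "too few complete cases")
  rhs <- terms
  if (sex_interaction) {
    abort_if(!"fetal_sex" %in% names(dat), "sex interaction needs fetal_sex")
    rhs <- c(rhs, paste0(exposures, ":fetal_sex"))
  }
  f <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(f, data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  ci <- stats::confint(fit, level = conf_level)
  sm <- summary(fit)$coefficients
  sdy <- stats::sd(dat[[outcome]])
  mm <- stats::model.matrix(fit)
  sb <- vapply(names(co), function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    unname(co[tm] * stats::sd(mm[, tm]) / sdy)
  }, numeric(1))
  tab <- data.frame(term = names(co), beta = unname(co),
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    sb = sb, p = sm[, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, n_used = nrow(dat), outcome = outcome, lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Adjusted linear model of %s (n = %d)\n", x$outcome, x$n_used))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Profiled ML log-likelihood of the random-intercept model as a function
# of (cluster variance, residual variance); beta is profiled out by GLS.
# Used to attach a curvature-based SE to the cluster variance.
ri_profile_loglik <- function(y, X, cluster) {
  cl <- split(seq_along(y), cluster)
  function(par) {
    tau2 <- par[1]; sig2 <- par[2]
    if (sig2 <= 0 || tau2 < 0) return(-Inf)
    XtVX <- 0; XtVy <- 0; quad <- 0; logdet <- 0
    for (idx in cl) {
      ni <- length(idx)
      w <- tau2 / (sig2 * (sig2 + ni * tau2))
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      sx <- colSums(Xi); sy <- sum(yi)
      XtVX <- XtVX + crossprod(Xi) / sig2 - w * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xi, yi) / sig2 - w * sx * sy
      logdet <- logdet + (ni - 1) * log(sig2) + log(sig2 + ni * tau2)
    }
    beta <- solve(XtVX, XtVy)
    for (idx in cl) {
      ni <- length(idx)
      w <- tau2 / (sig2 * (sig2 + ni * tau2))
      ri <- y[idx] - X[idx, , drop = FALSE] %*% beta
      quad <- quad + sum(ri^2) / sig2 - w * sum(ri)^2
    }
    -0.5 * (length(y) * log(2 * pi) + logdet + quad)
  }
}

#' Country-clustered mixed model with random-slope likelihood ratio test
#'
#' Fits a linear mixed model with the adjusted fixed effects and a random
#' intercept for the cluster (country), by maximum likelihood. Reports
#' the cluster-level variance with a curvature-based SE (inverse observed
#' information of the profiled ML likelihood; NA at the tau^2 = 0
#' boundary), and the likelihood ratio test of a random-MVPA-slope model
#' against the random-intercept model, referred to chi-square with df = 2
#' (slope variance + covariance). Because the null puts the slope
#' variance on the boundary of its space, this reference is conservative.
#'
#' @param cohort cohort data.frame.
#' @param outcome outcome column name.
#' @param cluster clustering column (default "country").
#' @param exposures,covariates fixed-effect columns as in
#'   [fit_adjusted_model()].
#' @param slope_term term given a random slope in the LRT (default
#'   "mvpa").
#' @return object of class `mixed_fit`: `fixed` (term, beta, se, p),
#'   `cluster_variance`, `cluster_variance_se`, `residual_variance`,
#'   `lrt` (statistic, df, p_value), `n_used`, `n_clusters`, `model`.
#' @export
fit_mixed_model <- function(cohort, outcome, cluster = "country",
                            exposures = c("mvpa", "st_pct"),
                            covariates = default_adjustment_set(),
                            slope_term = "mvpa") {
  terms <- c(exposures, covariates)
  abort_if(!all(c(terms, outcome, cluster) %in% names(cohort)),
           "cohort lacks required columns")
  dat <- cohort[stats::complete.cases(cohort[, c(outcome, terms, cluster)]),
                c(outcome, terms, cluster), drop = FALSE]
  abort_if(length(unique(dat[[cluster]])) < 2, "need at least two clusters")
  f_ri <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + "),
                                  "+ (1 |", cluster, ")"))
  f_rs <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + "),
                                  "+ (1 +", slope_term, "|", cluster, ")"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fm_ri <- lme4::lmer(f_ri, data = dat, REML = FALSE, control = ctrl)
  fm_rs <- suppressWarnings(lme4::lmer(f_rs, data = dat, REML = FALSE,
                                       control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fm_ri))
  tau2 <- vc$vcov[vc$grp == cluster]
  sig2 <- vc$vcov[vc$grp == "Residual"]

  # SE of the cluster variance from the observed information of the
  # profiled likelihood (delta-free; matches Wald SEs of ML software).
  se_tau2 <- NA_real_
  if (tau2 > 1e-8) {
    ll <- ri_profile_loglik(dat[[outcome]],
                            stats::model.matrix(~ ., dat[, terms, drop = FALSE]),
                            dat[[cluster]])
    H <- tryCatch(pracma::hessian(ll, c(tau2, sig2)), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(V) && V[1, 1] > 0) se_tau2 <- sqrt(V[1, 1])
    }
  }

  lrt_tab <- suppressMessages(stats::anova(fm_ri, fm_rs))
  lrt_stat <- max(lrt_tab$Chisq[2], 0)
  lrt <- list(statistic = lrt_stat, df = 2,
              p_value = stats::pchisq(lrt_stat, df = 2, lower.tail = FALSE))
  sm <- summary(fm_ri)$coefficients
  fixed <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      p = 2 * stats::pnorm(-abs(sm[, "t value"])),
                      stringsAsFactors = FALSE)
  rownames(fixed) <- NULL
  structure(list(fixed = fixed, cluster_variance = tau2,
                 cluster_variance_se = se_tau2, residual_variance = sig2,
                 lrt = lrt, n_used = nrow(dat),
                 n_clusters = length(unique(dat[[cluster]])), model = fm_ri),
            class = "mixed_fit")
}

#' Sensitivity analyses by subgroup exclusion
#'
#' Refits the adjusted model after excluding, in turn, smokers, women who
#' developed GDM (with the GDM covariate dropped in that subset, where it
#' is constant), and women with pre-eclampsia and/or pregnancy-induced
#' hypertension. Subsets too small for the model are flagged, not fatal.
#'
#' @param cohort cohort data.frame with flag columns `smoking`, `gdm`,
#'   `pe_pih`.
#' @param outcome outcome column name.
#' @param ... forwarded to [fit_adjusted_model()].
#' @return data.frame of class `sensitivity_table`: analysis, term, beta,
#'   ci_low, ci_high, sb, p, n_used, flagged.
#' @export
sensitivity_analysis <- function(cohort, outcome, ...) {
  abort_if(!all(c("smoking", "gdm", "pe_pih") %in% names(cohort)),
           "cohort lacks exclusion flags (smoking, gdm, pe_pih)")
  specs <- list(
    main = list(rows = rep(TRUE, nrow(cohort)), covars = default_adjustment_set()),
    no_smokers = list(rows = cohort$smoking == 0, covars = default_adjustment_set()),
    no_gdm = list(rows = cohort$gdm == 0,
                  covars = setdiff(default_adjustment_set(), "gdm")),
    no_pe_pih = list(rows = cohort$pe_pih == 0, covars = default_adjustment_set())
  )
  out <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    sub <- cohort[sp$rows, , drop = FALSE]
    fit <- tryCatch(fit_adjusted_model(sub, outcome, covariates = sp$covars, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(analysis = nm, term = NA_character_, beta = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, sb = NA_real_,
                        p = NA_real_, n_used = nrow(sub), flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    cbind(analysis = nm, fit$table, n_used = fit$n_used, flagged = FALSE,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("sensitivity_table", class(out))
  out
}
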