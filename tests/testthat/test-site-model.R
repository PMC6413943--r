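test_that("one record per group collapses to OLS with zero group variance", {
  set.seed(1)
  rec <- tibble::tibble(tag_id = sprintf("g%d", 1:30),
                        site = factor(rep(c("a", "b"), 15)),
                        response = rnorm(30))
  f <- fit_lmm(rec, "ML")
  expect_equal(f$sigma2_group, 0)
  ols <- unname(coef(lm(response ~ site, data = rec)))
  expect_equal(unname(f$beta), ols, tolerance = 1e-8)
})

test_that("ML fit agrees with direct numerical likelihood maximization", {
  set.seed(8)
  rec <- simulate_visit_records(n_groups = 3, site_mu = c(a = 1, b = 0.5),
                                sigma2_g = 0.3, sigma2_r = 1,
                                records_per_group = 8)
  f <- fit_lmm(rec, "ML")
  X <- model.matrix(~ site, data = rec)
  orc <- oracle_lmm_ml(rec$response, X, rec$tag_id)
  expect_equal(unname(f$beta), unname(orc$beta), tolerance = 1e-4)
  expect_equal(f$sigma2_group, unname(orc$sigma2_group), tolerance = 1e-4)
  expect_equal(f$sigma2_resid, unname(orc$sigma2_resid), tolerance = 1e-4)
  expect_equal(f$loglik, orc$loglik, tolerance = 1e-6)
  # the fitted parameters also maximize the oracle's likelihood surface
  expect_gte(f$loglik + 1e-8,
             oracle_lmm_loglik(f$beta, f$sigma2_group, f$sigma2_resid,
                               rec$response, X, rec$tag_id))
})

test_that("REML fit reproduces lme4 on a simulated design", {
  skip_if_not_installed("lmerTest")
  set.seed(12)
  rec <- simulate_visit_records(n_groups = 10, site_mu = table1_site_mu(),
                                sigma2_g = 0.29, sigma2_r = 1.06,
                                records_per_group = 40)
  f <- fit_lmm(rec, "REML")
  m <- lmerTest::lmer(response ~ site + (1 | tag_id), data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(f$sigma2_group, vc$vcov[1], tolerance = 1e-6)
  expect_equal(f$sigma2_resid, vc$vcov[2], tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  sm <- coef(summary(m))
  expect_equal(unname(f$se_beta), unname(sm[, "Std. Error"]), tolerance = 1e-6)
  expect_equal(unname(f$satterthwaite_df), unname(sm[, "df"]), tolerance = 1e-3)
})

test_that("REML and ML fixed effects coincide on a balanced one-way design", {
  set.seed(4)
  rec <- tibble::tibble(
    tag_id = rep(sprintf("g%d", 1:6), each = 10),
    response = rnorm(60) + rep(rnorm(6, 0, 0.5), each = 10))
  f_reml <- fit_lmm(rec, "REML")
  f_ml <- fit_lmm(rec, "ML")
  expect_equal(unname(f_reml$beta), unname(f_ml$beta), tolerance = 1e-6)
})

test_that("optimum log-likelihood dominates the OLS boundary; shift equivariance", {
  set.seed(16)
  rec <- simulate_visit_records(n_groups = 6, site_mu = c(a = 0, b = 1),
                                sigma2_g = 0.5, sigma2_r = 1,
                                records_per_group = 12)
  f <- fit_lmm(rec, "ML")
  X <- model.matrix(~ site, data = rec)
  ll0 <- oracle_lmm_loglik(qr.solve(X, rec$response), 1e-10,
                           mean(resid(lm(response ~ site, rec))^2),
                           rec$response, X, rec$tag_id)
  expect_gte(f$loglik, ll0 - 1e-6)

  rec2 <- rec; rec2$response <- rec$response + 7
  f2 <- fit_lmm(rec2, "ML")
  expect_equal(unname(f2$beta[1] - f$beta[1]), 7, tolerance = 1e-6)
  expect_equal(unname(f2$beta[-1]), unname(f$beta[-1]), tolerance = 1e-6)
  expect_equal(f2$sigma2_group, f$sigma2_group, tolerance = 1e-6)
})

test_that("likelihood-ratio test: identical models give chi2 = 0, p = 1", {
  set.seed(2)
  rec <- simulate_visit_records(n_groups = 4, site_mu = c(a = 0, b = 0),
                                sigma2_g = 0.2, sigma2_r = 1,
                                records_per_group = 10)
  f <- fit_lmm(rec, "ML")
  out <- lrt_site_effect(f, f)
  expect_equal(out$chi2, 0)
  expect_equal(out$p.value, 1)
  expect_error(lrt_site_effect(fit_lmm(rec, "REML"), f), "ML")
})

test_that("strong site effects are detected with high power", {
  set.seed(31)
  rej <- vapply(1:30, function(i) {
    rec <- simulate_visit_records(n_groups = 8,
                                  site_mu = c(a = 0, b = 1.2, c = -0.8),
                                  sigma2_g = 0.3, sigma2_r = 1,
                                  records_per_group = 25)
    full <- fit_lmm(rec, "ML")
    null <- fit_lmm(rec[, c("tag_id", "response")], "ML")
    lrt_site_effect(null, full)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("pairwise contrasts are internally consistent and Holm-adjusted", {
  set.seed(23)
  rec <- simulate_visit_records(n_groups = 8, site_mu = table1_site_mu(),
                                sigma2_g = 0.29, sigma2_r = 1.06,
                                records_per_group = 50)
  f <- fit_lmm(rec, "REML")
  ct <- pairwise_site_contrasts(f)
  expect_equal(nrow(ct), choose(6, 2))
  # transitivity of estimated differences: (a-b) + (b-c) = (a-c)
  g <- function(i, j) ct$estimate[ct$site_i == i & ct$site_j == j]
  expect_equal(g("alcyone", "canal") + g("canal", "lobster"),
               g("alcyone", "lobster"), tolerance = 1e-10)
  expect_equal(ct$p.adjusted, p.adjust(ct$p.value, "holm"))
  expect_true(all(ct$p.adjusted >= ct$p.value))
})

test_that("tidy and glance expose the fit in broom layout", {
  set.seed(3)
  rec <- simulate_visit_records(n_groups = 5, site_mu = c(a = 1, b = 0),
                                sigma2_g = 0.3, sigma2_r = 1,
                                records_per_group = 10)
  f <- fit_lmm(rec)
  td <- tidy(f)
  expect_true(all(c("effect", "term", "estimate", "std.error") %in% names(td)))
  expect_equal(sum(td$effect == "fixed"), 2)
  expect_equal(sum(td$effect == "ran_pars"), 2)
  gl <- glance(f)
  expect_equal(gl$nobs, 50)
  expect_equal(gl$criterion, "REML")
})

test_that("visit records transform durations to log hours with Alcyone first", {
  v <- make_visits(c("roca_sucia", "alcyone"), c(0, 5), c(2, 3))
  rec <- visit_records(v)
  expect_equal(levels(rec$site), c("alcyone", "roca_sucia"))
  expect_equal(rec$response, log(c(2, 3)))
  rec2 <- visit_records(v, response = "hours")
  expect_equal(rec2$response, c(2, 3))
  v$duration_s[1] <- 0
  expect_error(visit_records(v), "log")
})
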