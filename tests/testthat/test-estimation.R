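test_that("negative log-likelihood matches hand-computed Bernoulli sums", {
  set.seed(51)
  cfg <- cohort_config(6, seed = 51)
  d <- simulate_cohort(cfg)
  # zero inverse temperature: every probability is sigmoid(beta0)
  expect_equal(
    negative_log_likelihood(c(beta0 = 0, beta1 = 0, w = 0.5), d, "dtm"),
    6 * log(2))
  # three-row arithmetic oracle, summed term by term with plogis
  d3 <- data.frame(
    p_s1_a1 = c(0.9, 0.5, 0.2), p_s1_a2 = c(0.1, 0.5, 0.3),
    se_i1 = c(0.8, 0.6, 0.9), se_i2 = c(0.1, 0.2, 0.0),
    u_self_a1_s1 = c(1, 0.5, -0.2), u_self_a1_s2 = c(0, -0.5, 0.1),
    u_self_a2_s1 = c(0.3, 0, 0.6), u_self_a2_s2 = c(-0.1, 0.2, -0.6),
    u_others_a1_s1 = c(0.5, 0, 1), u_others_a1_s2 = c(0, 0, -1),
    u_others_a2_s1 = c(-0.5, 0.1, 0), u_others_a2_s2 = c(0.2, 0.3, 0),
    intention = c(1, 0, 1))
  beta0 <- -0.2; beta1 <- 1.5; w <- 0.7
  manual <- 0
  for (r in 1:3) {
    g1 <- d3$p_s1_a1[r] * (d3$u_self_a1_s1[r] + w * d3$u_others_a1_s1[r]) +
      (1 - d3$p_s1_a1[r]) * (d3$u_self_a1_s2[r] + w * d3$u_others_a1_s2[r])
    g2 <- d3$p_s1_a2[r] * (d3$u_self_a2_s1[r] + w * d3$u_others_a2_s1[r]) +
      (1 - d3$p_s1_a2[r]) * (d3$u_self_a2_s2[r] + w * d3$u_others_a2_s2[r])
    eu_diff <- (d3$se_i1[r] - d3$se_i2[r]) * (g1 - g2)
    p <- stats::plogis(beta1 * eu_diff + beta0)
    manual <- manual - (d3$intention[r] * log(p) + (1 - d3$intention[r]) * log(1 - p))
  }
  expect_equal(
    negative_log_likelihood(c(beta0 = beta0, beta1 = beta1, w = w), d3, "dtm"),
    manual, tolerance = 1e-12)
  # a respondent predicted perfectly contributes ~0
  d1 <- d3[1, ]; d1$se_i2 <- 0; d1$intention <- 1
  big <- negative_log_likelihood(c(beta0 = 50, beta1 = 1, w = 0.7), d1, "dtm")
  expect_lt(big, 1e-8)
  expect_error(negative_log_likelihood(c(beta0 = 0, beta1 = 1, w = 0), d3[0, ], "dtm"),
               class = "dtmbc_invalid_argument")
})

test_that("NLL is invariant under respondent reordering", {
  set.seed(52)
  d <- simulate_cohort(cohort_config(40, seed = 52))
  perm <- sample(nrow(d))
  par <- c(beta0 = 0.3, beta1 = 1.2, w = 0.4)
  expect_equal(negative_log_likelihood(par, d, "dtm"),
               negative_log_likelihood(par, d[perm, ], "dtm"))
})

test_that("analytic gradients match central finite differences", {
  set.seed(53)
  d <- simulate_cohort(cohort_config(50, seed = 53))
  d$attitude <- runif(50, -1, 1); d$norm <- runif(50, -1, 1)
  d$u_self_s1 <- runif(50, -1, 1); d$u_self_s2 <- runif(50, -1, 1)
  d$action <- d$intention
  h <- 1e-6
  for (model in c("dtm", "tpb", "eut")) {
    nm <- switch(model, dtm = c("beta0", "beta1", "w"),
                 tpb = c("beta0", "w1", "w2", "w3"),
                 eut = c("beta0", "beta1"))
    for (rep in 1:4) {
      par <- stats::setNames(runif(length(nm), 0.05, 1.5), nm)
      g <- nll_gradient(par, d, model)
      fd <- vapply(nm, function(k) {
        up <- par; up[k] <- up[k] + h
        dn <- par; dn[k] <- dn[k] - h
        (negative_log_likelihood(up, d, model) -
           negative_log_likelihood(dn, d, model)) / (2 * h)
      }, numeric(1))
      expect_equal(g, fd, tolerance = 1e-5)
    }
  }
})

test_that("DTM parameters are recovered from simulated cohorts", {
  cfg <- cohort_config(5000, params = decision_params(beta1 = 2, beta0 = -0.5),
                       w = 0.5, seed = 42)
  d <- simulate_cohort(cfg)
  fit <- fit_decision_model(d, "dtm", seed = 42)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates["beta0"] + 0.5), 0.15)
  expect_lt(abs(fit$estimates["beta1"] - 2), 0.15)
  expect_lt(abs(fit$estimates["w"] - 0.5), 0.15)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  expect_lte(fit$loglik, 0)
  # refitting the same data and seed is bit-identical
  fit2 <- fit_decision_model(simulate_cohort(cfg), "dtm", seed = 42)
  expect_identical(fit$estimates, fit2$estimates)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("estimate error shrinks as the cohort grows", {
  truth <- c(beta0 = -0.5, beta1 = 2, w = 0.5)
  med_err <- vapply(c(500, 2000, 5000), function(n) {
    median(vapply(1:5, function(r) {
      cfg <- cohort_config(n, params = decision_params(2, -0.5), w = 0.5,
                           seed = 100 * r)
      f <- fit_decision_model(simulate_cohort(cfg), "dtm",
                              n_starts = 4, seed = 100 * r)
      median(abs(f$estimates - truth))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("the TPB fit agrees with logistic regression on the same covariates", {
  set.seed(55)
  n <- 800
  d <- data.frame(attitude = runif(n, -1, 1), norm = runif(n, -1, 1),
                  se_i1 = runif(n))
  eta <- -0.3 + 0.8 * d$attitude + 0.5 * d$norm + 1.2 * d$se_i1
  d$intention <- rbinom(n, 1, plogis(eta))
  fit <- fit_decision_model(d, "tpb", seed = 55)
  ref <- stats::glm(intention ~ attitude + norm + se_i1, binomial(), d)
  expect_equal(unname(fit$estimates[c("beta0", "w1", "w2", "w3")]),
               unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("degenerate datasets raise diagnostics instead of fitting", {
  set.seed(56)
  d <- simulate_cohort(cohort_config(30, seed = 56))
  d$intention <- 1
  expect_error(fit_decision_model(d, "dtm", seed = 1),
               class = "dtmbc_separation_error")
  expect_error(fit_decision_model(d[0, ], "dtm", seed = 1))
})

test_that("model comparison reports AIC on matched outcomes only", {
  set.seed(57)
  d <- simulate_cohort(cohort_config(400, params = decision_params(2, 0),
                                     w = 0.5, seed = 57))
  d$attitude <- d$p_s1_a1 * d$u_self_a1_s1 + (1 - d$p_s1_a1) * d$u_self_a1_s2
  d$norm <- d$u_others_a1_s1
  fit_dtm <- fit_decision_model(d, "dtm", seed = 57)
  fit_tpb <- fit_decision_model(d, "tpb", seed = 57)
  cmp <- compare_models(fit_dtm, fit_dtm)
  expect_equal(cmp$delta_aic, 0)
  cmp2 <- compare_models(fit_tpb, fit_dtm)
  expect_equal(nrow(cmp2$table), 2)
  expect_equal(cmp2$delta_aic, fit_tpb$aic - fit_dtm$aic)
  # under DTM-generated data the DTM likelihood is at least TPB's
  expect_gte(fit_dtm$loglik, fit_tpb$loglik - 1e-6)
  d2 <- d[1:399, ]
  fit_short <- fit_decision_model(d2, "dtm", seed = 57)
  expect_error(compare_models(fit_short, fit_dtm), "same outcomes")
})

test_that("fit datasets and results round-trip through files", {
  set.seed(58)
  d <- simulate_cohort(cohort_config(60, seed = 58))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, csv)
  back <- read_fit_dataset(csv, "dtm")
  fit1 <- fit_decision_model(d, "dtm", seed = 3)
  fit2 <- fit_decision_model(back, "dtm", seed = 3)
  expect_equal(fit1$estimates, fit2$estimates, tolerance = 1e-10)
  js <- withr::local_tempfile(fileext = ".json")
  write_fit_result(fit1, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$model, "dtm")
  expect_equal(parsed$estimates$w, unname(fit1$estimates["w"]), tolerance = 1e-12)
})
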