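# Likelihood machinery. Each model's intention (or action) probability is
# logistic in a linear predictor built from per-respondent beliefs and
# utilities, so the negative log-likelihood and its gradient vectorise.

LIK_EPS <- 1e-12  # probability clipping for likelihood stability

DTM_COLS <- c("p_s1_a1", "p_s1_a2", "se_i1", "se_i2",
              "u_self_a1_s1", "u_self_a1_s2", "u_self_a2_s1", "u_self_a2_s2",
              "u_others_a1_s1", "u_others_a1_s2", "u_others_a2_s1",
              "u_others_a2_s2")
TPB_COLS <- c("attitude", "norm", "se_i1")
EUT_COLS <- c("p_s1_a1", "p_s1_a2", "u_self_s1", "u_self_s2")

outcome_col <- function(model) if (model == "eut") "action" else "intention"

check_dataset <- function(dataset, model) {
  need <- switch(model, dtm = DTM_COLS, tpb = TPB_COLS, eut = EUT_COLS)
  need <- c(need, outcome_col(model))
  missing <- setdiff(need, names(dataset))
  if (length(missing) > 0) {
    stop_config("dataset is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(dataset) < 1) stop_invalid("dataset must have at least one respondent")
  y <- dataset[[outcome_col(model)]]
  if (!all(y %in% c(0, 1))) stop_invalid("outcomes must be 0/1")
  pred <- as.matrix(dataset[, setdiff(need, outcome_col(model))])
  if (any(!is.finite(pred))) stop_invalid("predictors must be finite")
  invisible(dataset)
}

# Per-respondent pieces of the DTM expected-utility difference:
# EU(i1) - EU(i2) = (se_i1 - se_i2) * {(g_self_a1 - g_self_a2)
#                   + w (g_others_a1 - g_others_a2)} = A + w B,
# with g_*_aj the state-expected utility of action j.
dtm_design <- function(dataset) {
  d <- dataset
  g_self_a1 <- d$p_s1_a1 * d$u_self_a1_s1 + (1 - d$p_s1_a1) * d$u_self_a1_s2
  g_self_a2 <- d$p_s1_a2 * d$u_self_a2_s1 + (1 - d$p_s1_a2) * d$u_self_a2_s2
  g_oth_a1 <- d$p_s1_a1 * d$u_others_a1_s1 + (1 - d$p_s1_a1) * d$u_others_a1_s2
  g_oth_a2 <- d$p_s1_a2 * d$u_others_a2_s1 + (1 - d$p_s1_a2) * d$u_others_a2_s2
  dse <- d$se_i1 - d$se_i2
  list(A = dse * (g_self_a1 - g_self_a2), B = dse * (g_oth_a1 - g_oth_a2))
}

linear_predictor <- function(params, dataset, model) {
  switch(model,
    dtm = {
      z <- dtm_design(dataset)
      params[["beta1"]] * (z$A + params[["w"]] * z$B) + params[["beta0"]]
    },
    tpb = {
      # beta1 fixed at 1: Eq-style weights and the inverse temperature
      # enter only as products, so only their products are identifiable.
      params[["w1"]] * dataset$attitude + params[["w2"]] * dataset$norm +
        params[["w3"]] * dataset$se_i1 + params[["beta0"]]
    },
    eut = {
      d <- (dataset$p_s1_a1 - dataset$p_s1_a2) *
        (dataset$u_self_s1 - dataset$u_self_s2)
      params[["beta1"]] * d + params[["beta0"]]
    },
    stop_invalid("unknown model: ", model)
  )
}

param_names <- function(model) {
  switch(model,
    dtm = c("beta0", "beta1", "w"),
    tpb = c("beta0", "w1", "w2", "w3"),
    eut = c("beta0", "beta1"))
}

as_param_vec <- function(params, model) {
  nm <- param_names(model)
  p <- unlist(params)[nm]
  if (any(is.na(p))) {
    stop_config("params for model '", model, "' must name: ",
                paste(nm, collapse = ", "))
  }
  p
}

#' Negative log-likelihood of binary outcomes under a choice model
#'
#' Bernoulli deviance (halved):
#' `-sum_r [y_r log p_r + (1 - y_r) log(1 - p_r)]`, where `p_r` is the
#' model's intention probability (action probability for EUT) for
#' respondent r given their elicited beliefs and utilities. Probabilities
#' are clipped to `[1e-12, 1 - 1e-12]` so the value stays finite.
#'
#' @param params Named numeric vector / list: `beta0, beta1, w` for DTM;
#'   `beta0, w1, w2, w3` for TPB (inverse temperature fixed at 1);
#'   `beta0, beta1` for EUT.
#' @param dataset Data frame of per-respondent scored parameters plus an
#'   `intention` (or, for EUT, `action`) 0/1 outcome column; see
#'   [score_responses()] and [simulate_outcomes()] for producers.
#' @param model `"dtm"`, `"tpb"` or `"eut"`.
#' @return Scalar negative log-likelihood (>= 0).
#' @export
negative_log_likelihood <- function(params, dataset, model = c("dtm", "tpb", "eut")) {
  model <- match.arg(model)
  check_dataset(dataset, model)
  p <- as_param_vec(params, model)
  y <- dataset[[outcome_col(model)]]
  pr <- sigmoid(linear_predictor(p, dataset, model))
  pr <- pmin(pmax(pr, LIK_EPS), 1 - LIK_EPS)
  -sum(y * log(pr) + (1 - y) * log(1 - pr))
}

#' Gradient of the negative log-likelihood
#'
#' Analytic gradient in the model's parameters; matches a central finite
#' difference of [negative_log_likelihood()].
#'
#' @inheritParams negative_log_likelihood
#' @return Named numeric gradient vector.
#' @export
nll_gradient <- function(params, dataset, model = c("dtm", "tpb", "eut")) {
  model <- match.arg(model)
  check_dataset(dataset, model)
  p <- as_param_vec(params, model)
  y <- dataset[[outcome_col(model)]]
  pr <- sigmoid(linear_predictor(p, dataset, model))
  r <- pr - y  # d(-loglik)/d(eta), per respondent
  g <- switch(model,
    dtm = {
      z <- dtm_design(dataset)
      c(beta0 = sum(r),
        beta1 = sum(r * (z$A + p[["w"]] * z$B)),
        w = sum(r * p[["beta1"]] * z$B))
    },
    tpb = c(beta0 = sum(r), w1 = sum(r * dataset$attitude),
            w2 = sum(r * dataset$norm), w3 = sum(r * dataset$se_i1)),
    eut = {
      d <- (dataset$p_s1_a1 - dataset$p_s1_a2) *
        (dataset$u_self_s1 - dataset$u_self_s2)
      c(beta0 = sum(r), beta1 = sum(r * d))
    })
  g[param_names(model)]
}

lower_bounds <- function(model) {
  switch(model,
    dtm = c(beta0 = -Inf, beta1 = 0, w = 0),
    tpb = c(beta0 = -Inf, w1 = -Inf, w2 = -Inf, w3 = -Inf),
    eut = c(beta0 = -Inf, beta1 = 0))
}

default_start <- function(model) {
  switch(model,
    dtm = c(beta0 = 0, beta1 = 1, w = 0.5),
    tpb = c(beta0 = 0, w1 = 0, w2 = 0, w3 = 0),
    eut = c(beta0 = 0, beta1 = 1))
}

#' Fit decision parameters by maximum likelihood
#'
#' Minimises [negative_log_likelihood()] with L-BFGS-B using the analytic
#' gradient, from multiple seeded starting points (the model's default
#' start plus random perturbations) to guard against local optima.
#' Beliefs and utilities are treated as known covariates; only the
#' decision parameters are estimated. Standard errors come from the
#' observed information (inverse Hessian at the optimum).
#'
#' @inheritParams negative_log_likelihood
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed making the start points, and hence the whole
#'   fit, reproducible.
#' @return Object of class `dtmbc_fit`: list with `model`, `estimates`,
#'   `se`, `loglik`, `aic`, `n`, `n_params`, `converged`, `n_starts_ok`,
#'   and the outcome vector used (for model-comparison integrity checks).
#' @export
fit_decision_model <- function(dataset, model = c("dtm", "tpb", "eut"),
                               n_starts = 8, seed = 1) {
  model <- match.arg(model)
  check_dataset(dataset, model)
  nm <- param_names(model)
  if (nrow(dataset) < length(nm)) {
    stop_invalid("need at least ", length(nm), " respondents to fit ", model)
  }
  y <- dataset[[outcome_col(model)]]
  if (length(unique(y)) < 2) {
    stop(errorCondition(
      paste0("outcome is constant (all ", y[1], "): complete separation, ",
             "the likelihood has no interior optimum"),
      class = c("dtmbc_separation_error", "error")))
  }

  obj <- function(par) {
    names(par) <- nm
    negative_log_likelihood(par, dataset, model)
  }
  grad <- function(par) {
    names(par) <- nm
    unname(nll_gradient(par, dataset, model))
  }

  set.seed(seed)
  starts <- list(default_start(model))
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      s <- default_start(model) + stats::runif(length(nm), -2, 2)
      starts[[k + 1]] <- pmax(s, lower_bounds(model))
    }
  }

  best <- NULL
  ok <- 0L
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower_bounds(model),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) ok <- ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || ok == 0) {
    msg <- "no optimizer start converged"
    if (!is.null(best)) {
      msg <- paste0(msg, "; best point found: ",
                    paste(sprintf("%s=%.4g", nm, best$par), collapse = ", "),
                    " (nll ", sprintf("%.4g", best$value), ")")
    }
    stop(errorCondition(msg, class = c("dtmbc_fit_error", "error")))
  }

  est <- stats::setNames(as.numeric(best$par), nm)
  se <- rep(NA_real_, length(nm))
  H <- tryCatch(stats::optimHess(est, obj, gr = grad), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      v <- diag(V)
      pos <- is.finite(v) & v > 0
      se[pos] <- sqrt(v[pos])
    }
  }
  loglik <- -best$value
  structure(
    list(model = model,
         estimates = est,
         se = stats::setNames(se, nm),
         loglik = loglik,
         aic = 2 * length(nm) - 2 * loglik,
         n = nrow(dataset),
         n_params = length(nm),
         converged = TRUE,
         n_starts_ok = ok,
         outcome = as.integer(y)),
    class = "dtmbc_fit"
  )
}

#' @export
print.dtmbc_fit <- function(x, ...) {
  cat(sprintf("%s fit, n = %d respondents\n", toupper(x$model), x$n))
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  cat(sprintf("log-likelihood %.3f, AIC %.2f (%d starts converged)\n",
              x$loglik, x$aic, x$n_starts_ok))
  invisible(x)
}

#' Compare two fitted models on the same outcomes
#'
#' Reports log-likelihoods, parameter counts and AIC for two fits of the
#' same outcome vector, plus the AIC difference (first minus second). No
#' verdict is attached; a negative difference favors the first model.
#'
#' @param fit_a,fit_b `dtmbc_fit` objects fitted to identical outcomes.
#' @return List with a per-model `table` data frame and `delta_aic`.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dtmbc_fit"), inherits(fit_b, "dtmbc_fit"))
  if (fit_a$n != fit_b$n || !identical(fit_a$outcome, fit_b$outcome)) {
    stop_invalid("fits were not computed on the same outcomes")
  }
  tab <- data.frame(
    model = c(fit_a$model, fit_b$model),
    loglik = c(fit_a$loglik, fit_b$loglik),
    n_params = c(fit_a$n_params, fit_b$n_params),
    aic = c(fit_a$aic, fit_b$aic)
  )
  list(table = tab, delta_aic = fit_a$aic - fit_b$aic)
}

#' Read a fitting dataset from CSV
#'
#' @param path CSV with scored parameter columns and a 0/1 outcome column
#'   (`intention`, or `action` for EUT).
#' @param model Model the dataset will be fitted with; used to validate
#'   the required columns on read.
#' @return Validated data frame.
#' @export
read_fit_dataset <- function(path, model = c("dtm", "tpb", "eut")) {
  model <- match.arg(model)
  if (!file.exists(path)) stop_config("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_dataset(df, model)
  df
}

#' Write a fit result as JSON
#'
#' @param fit A `dtmbc_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "dtmbc_fit"))
  out <- fit[c("model", "estimates", "se", "loglik", "aic", "n",
               "n_params", "converged", "n_starts_ok")]
  out$estimates <- as.list(out$estimates)
  out$se <- as.list(out$se)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
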