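# Cohort generator: heterogeneous agents drawn from bounded distribution
# families, pushed through the intention -> action -> state Bernoulli chain.

#' Distribution specifications for cohort fields
#'
#' Bounded families for drawing per-agent beliefs and utilities:
#' `dist_point()` a degenerate point mass, `dist_uniform()` uniform on
#' `[min, max]`, `dist_beta()` a Beta distribution (support `[0, 1]`).
#' Supports are validated against each field's valid range at config
#' time, so no draw ever needs rejection.
#'
#' @param value Point-mass value.
#' @param min,max Uniform support endpoints.
#' @param shape1,shape2 Beta shape parameters.
#' @return A `dtmbc_dist` specification.
#' @name cohort_distributions
NULL

#' @rdname cohort_distributions
#' @export
dist_point <- function(value) {
  check_finite(value, "value")
  structure(list(family = "point", value = value,
                 support = c(value, value)), class = "dtmbc_dist")
}

#' @rdname cohort_distributions
#' @export
dist_uniform <- function(min, max) {
  check_finite(c(min, max), "uniform bounds")
  if (min > max) stop_config("uniform needs min <= max")
  structure(list(family = "uniform", min = min, max = max,
                 support = c(min, max)), class = "dtmbc_dist")
}

#' @rdname cohort_distributions
#' @export
dist_beta <- function(shape1, shape2) {
  check_finite(c(shape1, shape2), "beta shapes")
  if (shape1 <= 0 || shape2 <= 0) stop_config("beta shapes must be > 0")
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2,
                 support = c(0, 1)), class = "dtmbc_dist")
}

draw_dist <- function(d, n) {
  switch(d$family,
    point = rep(d$value, n),
    uniform = stats::runif(n, d$min, d$max),
    beta = stats::rbeta(n, d$shape1, d$shape2))
}

PROB_FIELDS <- c("p_s1_a1", "p_s1_a2", "se_i1", "se_i2")
UTIL_FIELDS <- c("u_self_a1_s1", "u_self_a1_s2", "u_self_a2_s1", "u_self_a2_s2",
                 "u_others_a1_s1", "u_others_a1_s2", "u_others_a2_s1",
                 "u_others_a2_s2")

default_cohort_fields <- function() {
  f <- list(
    # beliefs: agents tend to think the behavior helps and its omission
    # does not; self-efficacy with intention is usually high, without it low
    p_s1_a1 = dist_beta(4, 2),
    p_s1_a2 = dist_beta(2, 4),
    se_i1 = dist_beta(4, 2),
    se_i2 = dist_beta(2, 6)
  )
  for (u in UTIL_FIELDS) f[[u]] <- dist_uniform(-1, 1)
  f
}

#' Configure a synthetic agent cohort
#'
#' Defines the population a cohort is drawn from: one bounded
#' distribution per belief/utility field (two-state behavior model), the
#' true decision parameters and social weight used generatively, the
#' actual (not perceived) self-efficacies driving the action draw, and
#' the seed. Defaults describe a population mildly favorable to the
#' target behavior: beliefs and with-intention self-efficacy Beta(4, 2),
#' without-intention self-efficacy Beta(2, 6), counterfactual belief
#' Beta(2, 4), all utilities uniform on [-1, 1].
#'
#' @param n_agents Number of agents (>= 1).
#' @param fields Named list of `dtmbc_dist` overriding any of the
#'   defaults (`p_s1_a1`, `p_s1_a2`, `se_i1`, `se_i2`, and the eight
#'   `u_self_*` / `u_others_*` cells).
#' @param params True [decision_params()] of the intention rule.
#' @param w True social weight applied to U_others.
#' @param actual_se Optional list with `dtmbc_dist` entries `i1`, `i2`
#'   for actual self-efficacies; by default they equal the perceived ones
#'   (the proxy assumption the prediction formulas make, applied to the
#'   generator too).
#' @param seed Integer seed for the single RNG stream.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_agents, fields = list(),
                          params = decision_params(beta1 = 1, beta0 = 0),
                          w = 0.5, actual_se = NULL, seed = 1) {
  stopifnot(inherits(params, "decision_params"))
  if (n_agents < 1) stop_config("n_agents must be >= 1")
  check_finite(w, "w")
  if (w < 0) stop_invalid("w must be non-negative")
  f <- default_cohort_fields()
  unknown <- setdiff(names(fields), names(f))
  if (length(unknown) > 0) {
    stop_config("unknown cohort fields: ", paste(unknown, collapse = ", "))
  }
  f[names(fields)] <- fields
  for (nm in names(f)) {
    if (!inherits(f[[nm]], "dtmbc_dist")) {
      stop_config("field '", nm, "' must be a dtmbc_dist specification")
    }
    rng <- if (nm %in% PROB_FIELDS) c(0, 1) else c(-1, 1)
    sup <- f[[nm]]$support
    if (sup[1] < rng[1] || sup[2] > rng[2]) {
      stop_config("field '", nm, "': support [", sup[1], ", ", sup[2],
                  "] outside valid range [", rng[1], ", ", rng[2], "]")
    }
  }
  if (!is.null(actual_se)) {
    if (!all(names(actual_se) %in% c("i1", "i2"))) {
      stop_config("actual_se entries must be named i1/i2")
    }
    for (nm in names(actual_se)) {
      sup <- actual_se[[nm]]$support
      if (sup[1] < 0 || sup[2] > 1) {
        stop_config("actual_se '", nm, "' support outside [0, 1]")
      }
    }
  }
  structure(
    list(n_agents = as.integer(n_agents), fields = f, params = params,
         w = w, actual_se = actual_se, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Draw a cohort of agent parameterizations
#'
#' Samples `n_agents` independent agents field by field (fixed field
#' order, one seeded stream). All families are bounded within their
#' field's valid range at configuration time, so no draws are rejected;
#' the rejection count is still recorded as an attribute for audit.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per agent: a `respondent_id`, the
#'   twelve belief/utility columns, and `actual_se_i1` / `actual_se_i2`.
#'   Attribute `rejections` records discarded draws (always 0 for the
#'   built-in families).
#' @export
sample_agents <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sample_agents_stream(config)
}

# body shared with simulate_cohort(), which seeds the stream once
sample_agents_stream <- function(config) {
  n <- config$n_agents
  cols <- lapply(config$fields, draw_dist, n = n)
  df <- as.data.frame(cols)
  df <- cbind(respondent_id = sprintf("agent_%05d", seq_len(n)), df)
  df$actual_se_i1 <- if (!is.null(config$actual_se$i1)) {
    draw_dist(config$actual_se$i1, n)
  } else df$se_i1
  df$actual_se_i2 <- if (!is.null(config$actual_se$i2)) {
    draw_dist(config$actual_se$i2, n)
  } else df$se_i2
  attr(df, "rejections") <- 0L
  df
}

#' Closed-form intention and behavior probabilities for agent rows
#'
#' Vectorised evaluation of the DTM intention rule and the two-term
#' behavior mixture over a cohort data frame, using the actual
#' self-efficacies for the behavior step when present.
#'
#' @param agents Data frame as from [sample_agents()].
#' @param params [decision_params()] of the intention rule.
#' @param w Social weight applied to U_others.
#' @return Data frame with columns `p_i1` and `p_a1`.
#' @export
cohort_probabilities <- function(agents, params, w) {
  z <- dtm_design(agents)
  p_i1 <- sigmoid(params$beta1 * (z$A + w * z$B) + params$beta0)
  se1 <- if ("actual_se_i1" %in% names(agents)) agents$actual_se_i1 else agents$se_i1
  se2 <- if ("actual_se_i2" %in% names(agents)) agents$actual_se_i2 else agents$se_i2
  data.frame(p_i1 = p_i1, p_a1 = se1 * p_i1 + se2 * (1 - p_i1))
}

#' Simulate binary intention, action and state outcomes for a cohort
#'
#' The generative chain: each agent's intention is Bernoulli in the DTM
#' intention probability; the action is Bernoulli in the actual
#' self-efficacy of the realised intention; the state is Bernoulli in
#' the action-state belief of the realised action. Draws happen in the
#' fixed order intention, action, state on one seeded stream.
#'
#' @param agents Data frame as from [sample_agents()].
#' @param params True [decision_params()].
#' @param w True social weight.
#' @param seed Optional seed; omit to continue the current RNG stream
#'   (as [simulate_cohort()] does).
#' @return `agents` with columns `p_i1`, `intention`, `action`, `state1`
#'   appended (`state1` = 1 when the first state occurred).
#' @export
simulate_outcomes <- function(agents, params, w, seed = NULL) {
  stopifnot(inherits(params, "decision_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(agents)
  pr <- cohort_probabilities(agents, params, w)
  intention <- stats::rbinom(n, 1, pr$p_i1)
  se1 <- if ("actual_se_i1" %in% names(agents)) agents$actual_se_i1 else agents$se_i1
  se2 <- if ("actual_se_i2" %in% names(agents)) agents$actual_se_i2 else agents$se_i2
  p_act <- ifelse(intention == 1, se1, se2)
  action <- stats::rbinom(n, 1, p_act)
  p_state <- ifelse(action == 1, agents$p_s1_a1, agents$p_s1_a2)
  state1 <- stats::rbinom(n, 1, p_state)
  out <- agents
  out$p_i1 <- pr$p_i1
  out$intention <- intention
  out$action <- action
  out$state1 <- state1
  out
}

#' Sample agents and simulate their outcomes in one seeded pass
#'
#' Convenience wrapper: seeds once from the config, draws the agents,
#' then the outcomes, all on a single stream, so the whole cohort is
#' reproducible from the config alone.
#'
#' @param config A [cohort_config()].
#' @return Outcome data frame as from [simulate_outcomes()], ready for
#'   [fit_decision_model()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  agents <- sample_agents_stream(config)
  simulate_outcomes(agents, config$params, config$w)
}

#' The exercising worked scenario
#'
#' The canonical two-state exercise-after-surgery setup: states
#' {recovery, no recovery}, beliefs P(s1|a1) = 0.8, P(s1|a2) = 0.2,
#' state utilities (1, 0). Reports the EUT expected utilities of both
#' actions and the logistic action probability at beta1 = 1, beta0 = 0,
#' plus the DTM extension of the same scenario with self-efficacies
#' P(a1|i1) = 0.9, P(a1|i2) = 0.1: expected total utilities of both
#' intentions and the DTM intention and behavior probabilities.
#'
#' @param params [decision_params()] of the choice rule.
#' @param se_i1,se_i2 Self-efficacies of the DTM extension.
#' @return Object of class `exercise_report` (a named list of the
#'   quantities above).
#' @export
exercise_scenario <- function(params = decision_params(beta1 = 1, beta0 = 0),
                              se_i1 = 0.9, se_i2 = 0.1) {
  beliefs <- belief_set_binary(p_s1_a1 = 0.8, p_s1_a2 = 0.2,
                               se_i1 = se_i1, se_i2 = se_i2)
  u <- utility_table(u_self_s = c(1, 0),
                     u_self_as = rbind(c(1, 0), c(1, 0)),
                     w_social = 0)
  p_i1 <- dtm_intention_probability(beliefs, u, params)
  structure(
    list(
      eut_eu_a1 = eut_expected_utility(beliefs, u, 1),
      eut_eu_a2 = eut_expected_utility(beliefs, u, 2),
      eut_p_a1 = eut_action_probability(beliefs, u, params),
      dtm_eu_i1 = dtm_expected_utility(beliefs, u, 1),
      dtm_eu_i2 = dtm_expected_utility(beliefs, u, 2),
      dtm_p_i1 = p_i1,
      dtm_p_a1 = dtm_behavior_probability(p_i1, beliefs),
      params = params
    ),
    class = "exercise_report"
  )
}

#' @export
print.exercise_report <- function(x, ...) {
  cat("Exercise scenario (recovery vs no recovery)\n")
  cat(sprintf("  EUT: E[U|a1] = %.4g, E[U|a2] = %.4g, P(a1) = %.2f\n",
              x$eut_eu_a1, x$eut_eu_a2, x$eut_p_a1))
  cat(sprintf("  DTM: E[U|i1] = %.4g, E[U|i2] = %.4g, P(i1) = %.4f, P(a1) = %.4f\n",
              x$dtm_eu_i1, x$dtm_eu_i2, x$dtm_p_i1, x$dtm_p_a1))
  invisible(x)
}

#' The jar-lid paralysis scenario
#'
#' A fully paralyzed agent considers straining the wrist to open a jar;
#' both self-efficacies are zero, no referents are present, and the
#' value of the jar's contents varies. TPB's additive intention score
#' (weights w = (1, 0, 1)) keeps rising with the contents' value even
#' though the act is impossible, while the multiplicative DTM leaves the
#' intention probability flat (the expected-utility difference is
#' identically zero) and the behavior probability at exactly zero.
#'
#' @param content_values Utilities of the jar contents to sweep.
#' @param params [decision_params()]; the TPB weights default to
#'   (1, 0, 1) — subjective norm dropped, no referents present.
#' @return Object of class `jar_lid_report`: data frame with columns
#'   `content_value`, `tpb_bi`, `dtm_p_i1`, `dtm_p_a1`.
#' @export
jar_lid_scenario <- function(content_values = c(0, 0.5, 1),
                             params = decision_params(
                               beta1 = 1, beta0 = 0,
                               tpb_weights = c(1, 0, 1))) {
  check_finite(content_values, "content_values")
  beliefs <- belief_set_binary(p_s1_a1 = 1, p_s1_a2 = 0,
                               se_i1 = 0, se_i2 = 0)
  rows <- lapply(content_values, function(v) {
    u <- utility_table(u_self_s = c(v, 0),
                       u_self_as = rbind(c(v, 0), c(v, 0)),
                       w_social = 0)
    p_i1 <- dtm_intention_probability(beliefs, u, params)
    data.frame(
      content_value = v,
      tpb_bi = tpb_behavioral_intention(beliefs, u, params),
      dtm_p_i1 = p_i1,
      dtm_p_a1 = dtm_behavior_probability(p_i1, beliefs)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("jar_lid_report", "data.frame"))
}

#' @export
print.jar_lid_report <- function(x, ...) {
  cat("Jar-lid scenario (both self-efficacies 0, no referents)\n")
  print.data.frame(round(as.data.frame(x), 4))
  cat("TPB intention score tracks the contents' value;",
      "DTM behavior probability stays 0.\n")
  invisible(x)
}

#' Write a simulated cohort as a fitting-ready CSV
#'
#' @param cohort Data frame from [simulate_cohort()] / [simulate_outcomes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
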