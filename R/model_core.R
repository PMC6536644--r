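#' Logistic choice function
#'
#' Standard logistic map of a decision variable to a probability,
#' `1 / (1 + exp(-x))`. This is the sigmoidal action/intention selection
#' rule shared by all three models.
#'
#' @param x Finite numeric vector.
#' @return Probabilities in (0, 1), same length as `x`.
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(0.6)  # ~0.6457
#' @export
sigmoid <- function(x) {
  check_finite(x, "x")
  1 / (1 + exp(-x))
}

#' Expected subjective utility of an action (EUT)
#'
#' Computes `E[U_self | a_j] = sum_n P(s_n | a_j) * U_self(s_n)`, the
#' standard expected-utility valuation of one action over the outcome
#' states, using the state-only utilities.
#'
#' @param beliefs A [belief_set()].
#' @param utilities A [utility_table()] with `u_self_s` set.
#' @param action Action index, 1 (perform) or 2 (not perform).
#' @return Scalar expected utility.
#' @examples
#' b <- belief_set_binary(p_s1_a1 = 0.8, p_s1_a2 = 0.2)
#' u <- utility_table(u_self_s = c(1, 0))
#' eut_expected_utility(b, u, action = 1)  # 0.8
#' @export
eut_expected_utility <- function(beliefs, utilities, action = 1) {
  stopifnot(inherits(beliefs, "belief_set"), inherits(utilities, "utility_table"))
  if (is.null(utilities$u_self_s)) {
    stop_config("state-only utilities u_self_s are required for EUT")
  }
  if (length(utilities$u_self_s) != n_states(beliefs)) {
    stop_config("u_self_s length must match the number of states")
  }
  if (!action %in% c(1, 2)) stop_invalid("action must be 1 or 2")
  sum(beliefs$p_state_given_action[, action] * utilities$u_self_s)
}

#' Probability of performing the behavior under EUT
#'
#' Applies the logistic choice rule to the expected-utility difference:
#' `P(a1) = sigmoid(beta1 * (E[U|a1] - E[U|a2]) + beta0)`.
#'
#' @inheritParams eut_expected_utility
#' @param params A [decision_params()].
#' @return Probability of the target behavior, `P(a1)`.
#' @export
eut_action_probability <- function(beliefs, utilities, params) {
  stopifnot(inherits(params, "decision_params"))
  d <- eut_expected_utility(beliefs, utilities, 1) -
    eut_expected_utility(beliefs, utilities, 2)
  sigmoid(params$beta1 * d + params$beta0)
}

#' Attitude toward the behavior (TPB)
#'
#' The TPB attitude is the expected subjective utility of performing the
#' target behavior, `sum_n P(s_n | a1) * U_self(s_n)` — numerically the
#' same quantity as [eut_expected_utility()] at `action = 1`, named for
#' the TPB construct it measures.
#'
#' @inheritParams eut_expected_utility
#' @return Scalar attitude.
#' @export
tpb_attitude <- function(beliefs, utilities) {
  eut_expected_utility(beliefs, utilities, action = 1)
}

#' Subjective norm (TPB)
#'
#' Perceived social pressure, aggregated over normative referents as
#' `U_others(a1) = sum_k m_k * U_k(a1)`. With no referents the norm is 0.
#'
#' @param utilities A [utility_table()]; uses its `referents` table.
#' @return Scalar subjective norm.
#' @export
tpb_subjective_norm <- function(utilities) {
  stopifnot(inherits(utilities, "utility_table"))
  r <- utilities$referents
  if (nrow(r) == 0) return(0)
  sum(r$m * r$u_a1)
}

#' Behavioral intention score (TPB)
#'
#' The weighted sum of attitude, subjective norm and perceived
#' self-efficacy:
#' `BI(i1) = w1 * E[U_self|a1] + w2 * U_others(a1) + w3 * P(a1|i1)`.
#'
#' Two algebraically equivalent forms are provided: `"weighted_sum"`
#' (the definition above) and `"regrouped"`, which folds attitude and
#' norm into one sum over states,
#' `BI(i1) = w3 P(a1|i1) + sum_n P(s_n|a1) {w1 U_self(s_n) + w2 U_others(a1)}`.
#' They agree because the behavioral beliefs sum to one.
#'
#' @inheritParams eut_action_probability
#' @param form Which algebraic form to evaluate.
#' @return Scalar behavioral intention (unbounded; not a probability).
#' @export
tpb_behavioral_intention <- function(beliefs, utilities, params,
                                     form = c("weighted_sum", "regrouped")) {
  stopifnot(inherits(params, "decision_params"))
  form <- match.arg(form)
  w <- params$tpb_weights
  if (length(w) != 3 || any(!is.finite(w))) {
    stop_config("tpb_weights (w1, w2, w3) must be set and finite")
  }
  se <- beliefs$p_act_given_intent["a1", "i1"]
  if (form == "weighted_sum") {
    w[1] * tpb_attitude(beliefs, utilities) +
      w[2] * tpb_subjective_norm(utilities) +
      w[3] * se
  } else {
    norm <- tpb_subjective_norm(utilities)
    p_s_a1 <- beliefs$p_state_given_action[, 1]
    w[3] * se + sum(p_s_a1 * (w[1] * utilities$u_self_s + w[2] * norm))
  }
}

#' Probability of intending the behavior (TPB)
#'
#' Logistic intention-selection rule on the behavioral intention score:
#' `P(i1) = sigmoid(beta1 * BI(i1) + beta0)`.
#'
#' @param bi Behavioral intention score, as from [tpb_behavioral_intention()].
#' @param params A [decision_params()].
#' @return Probability of intending the behavior.
#' @export
tpb_intention_probability <- function(bi, params) {
  stopifnot(inherits(params, "decision_params"))
  check_finite(bi, "bi")
  sigmoid(params$beta1 * bi + params$beta0)
}

#' Probability of performing the behavior (TPB)
#'
#' `P(a1) = P(a1|i1) * P(i1)`, using self-efficacy as the intention-action
#' link. The TPB instrument never elicits P(a1|i2), so this formula
#' implicitly assumes an agent without the intention never performs the
#' behavior; see [dtm_behavior_probability()] for the two-term mixture
#' that drops that assumption.
#'
#' @param p_i1 Probability of intending the behavior.
#' @param beliefs A [belief_set()]; perceived self-efficacy P(a1|i1) is
#'   used as proxy for the actual one unless `p_a1_i1` overrides it.
#' @param p_a1_i1 Optional actual self-efficacy overriding the perceived one.
#' @return Probability of the target behavior.
#' @export
tpb_behavior_probability <- function(p_i1, beliefs, p_a1_i1 = NULL) {
  check_prob(p_i1, "p_i1")
  se <- if (is.null(p_a1_i1)) beliefs$p_act_given_intent["a1", "i1"] else p_a1_i1
  check_prob(se, "P(a1|i1)")
  se * p_i1
}

#' Expected total utility of an intention (DTM)
#'
#' The decision-theoretic model values intentions, not actions, by
#' propagating each intention through the intention-action and
#' action-state links:
#' `E[U_total | i_h] = sum_j P(a_j|i_h) sum_n P(s_n|a_j)
#'   {U_self(a_j,s_n) + w U_others(a_j,s_n)}`.
#'
#' Both the nested double sum (`"nested"`) and the per-action expanded
#' form (`"expanded"`) are implemented as independent code paths; they are
#' algebraically identical.
#'
#' @inheritParams eut_expected_utility
#' @param intention Intention index, 1 (intend) or 2 (not intend).
#' @param form Which algebraic form to evaluate.
#' @return Scalar expected total utility.
#' @export
dtm_expected_utility <- function(beliefs, utilities, intention = 1,
                                 form = c("nested", "expanded")) {
  stopifnot(inherits(beliefs, "belief_set"), inherits(utilities, "utility_table"))
  form <- match.arg(form)
  if (!intention %in% c(1, 2)) stop_invalid("intention must be 1 or 2")
  if (is.null(utilities$u_self_as)) {
    stop_config("action-by-state utilities u_self_as are required for DTM")
  }
  N <- n_states(beliefs)
  if (ncol(utilities$u_self_as) != N) {
    stop_config("u_self_as must have one column per state")
  }
  u_o <- utilities$u_others_as
  if (is.null(u_o)) u_o <- matrix(0, 2, N)
  if (ncol(u_o) != N) stop_config("u_others_as must have one column per state")
  u_tot <- utilities$u_self_as + utilities$w_social * u_o  # 2 x N
  p_a <- unname(beliefs$p_act_given_intent[, intention])   # length 2
  p_s <- beliefs$p_state_given_action                      # N x 2
  if (form == "nested") {
    acc <- 0
    for (j in 1:2) {
      acc <- acc + p_a[j] * sum(p_s[, j] * u_tot[j, ])
    }
    acc
  } else {
    p_a[1] * sum(p_s[, 1] * u_tot[1, ]) + p_a[2] * sum(p_s[, 2] * u_tot[2, ])
  }
}

#' Probability of intending the behavior (DTM)
#'
#' Logistic intention-selection rule on the expected-utility difference
#' between the two intentions:
#' `P(i1) = sigmoid(beta1 * (E[U_total|i1] - E[U_total|i2]) + beta0)`.
#' Only the difference matters: shifting both expected utilities by a
#' constant leaves the probability unchanged.
#'
#' @inheritParams eut_action_probability
#' @return Probability of intending the behavior.
#' @export
dtm_intention_probability <- function(beliefs, utilities, params) {
  stopifnot(inherits(params, "decision_params"))
  d <- dtm_expected_utility(beliefs, utilities, 1) -
    dtm_expected_utility(beliefs, utilities, 2)
  sigmoid(params$beta1 * d + params$beta0)
}

#' Probability of performing the behavior (DTM)
#'
#' Two-term mixture over intentions:
#' `P(a1) = P(a1|i1) * P(i1) + P(a1|i2) * (1 - P(i1))`,
#' which reduces to the TPB product when `P(a1|i2) = 0`.
#'
#' @param p_i1 Probability of intending the behavior.
#' @param beliefs A [belief_set()]; its intention-action links are used as
#'   self-efficacies unless overridden.
#' @param p_a1_i1,p_a1_i2 Optional actual self-efficacies overriding the
#'   perceived ones (the generative chain uses actual values; prediction
#'   from questionnaires uses perceived ones as proxy).
#' @return Probability of the target behavior.
#' @export
dtm_behavior_probability <- function(p_i1, beliefs,
                                     p_a1_i1 = NULL, p_a1_i2 = NULL) {
  check_prob(p_i1, "p_i1")
  se1 <- if (is.null(p_a1_i1)) beliefs$p_act_given_intent["a1", "i1"] else p_a1_i1
  se2 <- if (is.null(p_a1_i2)) beliefs$p_act_given_intent["a1", "i2"] else p_a1_i2
  check_prob(c(se1, se2), "self-efficacies")
  se1 * p_i1 + se2 * (1 - p_i1)
}

#' Convert a TPB parameterization to DTM utilities
#'
#' Lifts state-only and referent utilities into the action-by-state
#' matrices DTM expects: `U_self(a_j, s_n) := U_self(s_n)` (utility
#' independent of the action taken) and
#' `U_others(a1, s_n) := sum_k m_k U_k(a1)`, `U_others(a2, s_n) := 0`
#' (the subjective norm attaches to performing the behavior, not to its
#' outcomes). This preserves the correspondence between the TPB
#' regrouped intention form and the DTM expected utility given i1.
#'
#' @param utilities A [utility_table()] with `u_self_s` (and optionally
#'   referents) set.
#' @param n_states Number of outcome states.
#' @param w_social Social weight carried into the DTM table.
#' @return A [utility_table()] with `u_self_as`/`u_others_as` filled.
#' @export
tpb_to_dtm_utilities <- function(utilities, n_states = length(utilities$u_self_s),
                                 w_social = utilities$w_social) {
  stopifnot(inherits(utilities, "utility_table"))
  if (is.null(utilities$u_self_s)) {
    stop_config("u_self_s is required to lift a TPB parameterization")
  }
  norm <- tpb_subjective_norm(utilities)
  utility_table(
    u_self_s = utilities$u_self_s,
    u_self_as = rbind(utilities$u_self_s, utilities$u_self_s),
    u_others_as = rbind(rep(norm, n_states), rep(0, n_states)),
    w_social = w_social,
    referents = utilities$referents
  )
}
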