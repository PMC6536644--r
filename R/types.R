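#' @keywords internal
"_PACKAGE"

# Tolerance accepted on elicited probability columns; inputs further off are
# refused rather than silently renormalised.
PROB_SUM_TOL <- 1e-6

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("dtmbc_config_error", "error")))
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("dtmbc_invalid_argument", "error")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid(what, " must be finite numeric")
  }
  invisible(x)
}

check_prob <- function(x, what) {
  check_finite(x, what)
  if (any(x < 0 | x > 1)) stop_invalid(what, " must lie in [0, 1]")
  invisible(x)
}

#' Define the state/action/intention space for one target behavior
#'
#' A behavior model couples a named set of outcome states with the fixed
#' binary action set (perform / not perform the target behavior) and the
#' fixed binary intention set (intend / not intend). All three models
#' (EUT, TPB, DTM) share this space.
#'
#' @param states Character vector of unique state labels, length >= 2.
#' @param target_behavior Free-text description of the target behavior.
#' @return An object of class `behavior_spec`.
#' @examples
#' behavior_spec(c("health", "disease"), "exercising 20 min, 3x/week")
#' @export
behavior_spec <- function(states = c("s1", "s2"),
                          target_behavior = "target behavior") {
  states <- as.character(states)
  if (length(states) < 2) stop_invalid("need at least 2 states")
  if (anyDuplicated(states)) stop_invalid("state labels must be unique")
  structure(
    list(
      states = states,
      actions = c(a1 = "perform", a2 = "not_perform"),
      intentions = c(i1 = "intend", i2 = "not_intend"),
      target_behavior = as.character(target_behavior)[1]
    ),
    class = "behavior_spec"
  )
}

#' Subjective beliefs: action-state links and intention-action links
#'
#' Holds the agent's subjective probabilities P(s_n | a_j) (behavioral
#' beliefs / outcome expectations) and P(a_j | i_h) (perceived
#' self-efficacies). Columns must be proper conditional distributions;
#' off-by-more-than-tolerance columns are an error, never renormalised,
#' so elicited beliefs are not silently altered.
#'
#' @param p_state_given_action N x 2 matrix, column j = P(. | a_j).
#' @param p_act_given_intent 2 x 2 matrix, column h = P(. | i_h); row 1 is
#'   the probability of performing the behavior, row 2 its complement.
#' @return An object of class `belief_set`.
#' @seealso [belief_set_binary()] for the common two-state shortcut.
#' @export
belief_set <- function(p_state_given_action, p_act_given_intent) {
  p_state_given_action <- as.matrix(p_state_given_action)
  p_act_given_intent <- as.matrix(p_act_given_intent)
  if (ncol(p_state_given_action) != 2 || nrow(p_state_given_action) < 2) {
    stop_config("p_state_given_action must be an N x 2 matrix with N >= 2")
  }
  if (!all(dim(p_act_given_intent) == c(2, 2))) {
    stop_config("p_act_given_intent must be a 2 x 2 matrix")
  }
  check_prob(p_state_given_action, "P(s|a)")
  check_prob(p_act_given_intent, "P(a|i)")
  if (any(abs(colSums(p_state_given_action) - 1) > PROB_SUM_TOL)) {
    stop_invalid("each column of P(s|a) must sum to 1 (tolerance ",
                 PROB_SUM_TOL, "); refusing to renormalise")
  }
  if (any(abs(colSums(p_act_given_intent) - 1) > PROB_SUM_TOL)) {
    stop_invalid("each column of P(a|i) must sum to 1 (tolerance ",
                 PROB_SUM_TOL, "); refusing to renormalise")
  }
  dimnames(p_state_given_action) <- list(
    paste0("s", seq_len(nrow(p_state_given_action))), c("a1", "a2"))
  dimnames(p_act_given_intent) <- list(c("a1", "a2"), c("i1", "i2"))
  structure(
    list(p_state_given_action = p_state_given_action,
         p_act_given_intent = p_act_given_intent),
    class = "belief_set"
  )
}

#' Two-state belief set from the positively worded items alone
#'
#' Questionnaires elicit only the positive-outcome and perform-the-behavior
#' probabilities; complements are filled in here.
#'
#' @param p_s1_a1 P(s1 | a1), e.g. "exercising leads to recovery".
#' @param p_s1_a2 P(s1 | a2); defaults to 0.5 (uninformative) when the
#'   instrument does not elicit it (TPB never does).
#' @param se_i1 Perceived self-efficacy P(a1 | i1).
#' @param se_i2 P(a1 | i2), performing despite no intention; TPB assumes 0.
#' @return A [belief_set()].
#' @export
belief_set_binary <- function(p_s1_a1, p_s1_a2 = 0.5, se_i1 = 1, se_i2 = 0) {
  check_prob(c(p_s1_a1, p_s1_a2, se_i1, se_i2), "belief probabilities")
  belief_set(
    p_state_given_action = cbind(c(p_s1_a1, 1 - p_s1_a1),
                                 c(p_s1_a2, 1 - p_s1_a2)),
    p_act_given_intent = cbind(c(se_i1, 1 - se_i1), c(se_i2, 1 - se_i2))
  )
}

#' Utilities of actions, states and referents
#'
#' Carries both parameterizations used across the three models: the
#' state-only subjective utilities U_self(s_n) of EUT/TPB, the
#' action-by-state matrices U_self(a_j, s_n) and U_others(a_j, s_n) of DTM
#' with their social weight w, and the TPB normative referents
#' (U_k(a1), m_k) whose weighted sum is the subjective norm.
#'
#' @param u_self_s Length-N vector U_self(s_n), or NULL.
#' @param u_self_as 2 x N matrix U_self(a_j, s_n) (rows a1, a2), or NULL.
#' @param u_others_as 2 x N matrix U_others(a_j, s_n), or NULL.
#' @param w_social Non-negative weight of others' utility relative to own.
#' @param referents Data frame with columns `u_a1` (referent's utility of
#'   the behavior) and `m` (motivation to comply); may have zero rows.
#' @return An object of class `utility_table`.
#' @export
utility_table <- function(u_self_s = NULL, u_self_as = NULL,
                          u_others_as = NULL, w_social = 0,
                          referents = NULL) {
  if (!is.null(u_self_s)) check_finite(u_self_s, "u_self_s")
  if (!is.null(u_self_as)) {
    u_self_as <- as.matrix(u_self_as)
    check_finite(u_self_as, "u_self_as")
    if (nrow(u_self_as) != 2) stop_config("u_self_as must have 2 rows (a1, a2)")
  }
  if (!is.null(u_others_as)) {
    u_others_as <- as.matrix(u_others_as)
    check_finite(u_others_as, "u_others_as")
    if (nrow(u_others_as) != 2) {
      stop_config("u_others_as must have 2 rows (a1, a2)")
    }
    if (!is.null(u_self_as) && ncol(u_others_as) != ncol(u_self_as)) {
      stop_config("u_self_as and u_others_as must agree on the number of states")
    }
  }
  check_finite(w_social, "w_social")
  if (w_social < 0) stop_invalid("w_social must be non-negative")
  if (is.null(referents)) {
    referents <- data.frame(u_a1 = numeric(0), m = numeric(0))
  }
  referents <- as.data.frame(referents)
  if (!all(c("u_a1", "m") %in% names(referents))) {
    stop_config("referents needs columns u_a1 and m")
  }
  if (nrow(referents) > 0) {
    check_finite(referents$u_a1, "referent utilities")
    check_finite(referents$m, "motivations to comply")
  }
  structure(
    list(u_self_s = u_self_s, u_self_as = u_self_as,
         u_others_as = u_others_as, w_social = w_social,
         referents = referents),
    class = "utility_table"
  )
}

#' Decision parameters of the logistic choice rule
#'
#' @param beta1 Inverse temperature (>= 0): scales utility differences;
#'   0 means fully random choice.
#' @param beta0 Decision bias: additive shift of baseline propensity.
#' @param tpb_weights Length-3 weights (w1, w2, w3) of attitude, subjective
#'   norm and perceived self-efficacy in the TPB intention sum.
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(beta1 = 1, beta0 = 0, tpb_weights = c(1, 1, 1)) {
  check_finite(beta1, "beta1")
  check_finite(beta0, "beta0")
  check_finite(tpb_weights, "tpb_weights")
  if (beta1 < 0) stop_invalid("beta1 must be >= 0 (anti-rational agents out of scope)")
  if (length(tpb_weights) != 3) stop_config("tpb_weights must have length 3")
  structure(
    list(beta1 = beta1, beta0 = beta0,
         tpb_weights = as.numeric(tpb_weights)),
    class = "decision_params"
  )
}

n_states <- function(beliefs) nrow(beliefs$p_state_given_action)

#' @export
print.behavior_spec <- function(x, ...) {
  cat("Behavior model:", x$target_behavior, "\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  actions: a1 =", x$actions[["a1"]], ", a2 =", x$actions[["a2"]], "\n")
  cat("  intentions: i1 =", x$intentions[["i1"]],
      ", i2 =", x$intentions[["i2"]], "\n")
  invisible(x)
}

#' @export
print.belief_set <- function(x, ...) {
  cat("Belief set\n P(s|a):\n")
  print(round(x$p_state_given_action, 4))
  cat(" P(a|i):\n")
  print(round(x$p_act_given_intent, 4))
  invisible(x)
}

#' @export
print.decision_params <- function(x, ...) {
  cat(sprintf("Decision parameters: beta1 = %g, beta0 = %g, TPB weights = (%s)\n",
              x$beta1, x$beta0, paste(x$tpb_weights, collapse = ", ")))
  invisible(x)
}
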