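# frozen logistic values, computed from the closed form 1/(1+exp(-x))
SIG_0.6 <- 0.6457
SIG_M0.5 <- 0.3775
SIG_2.2 <- 0.9002
SIG_0.48 <- 0.6177

test_that("logistic choice function matches its closed form and rejects non-finite input", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(round(sigmoid(0.6), 4), SIG_0.6)
  expect_equal(round(sigmoid(-0.5), 4), SIG_M0.5)
  expect_true(all(diff(sigmoid(seq(-5, 5, 0.1))) > 0))  # strictly increasing
  expect_error(sigmoid(Inf), "finite")
  expect_error(sigmoid(NA_real_), "finite")
})

test_that("EUT expected utilities and action probability reproduce the exercise case", {
  fx <- exercise_fixture()
  expect_equal(eut_expected_utility(fx$beliefs, fx$utilities, 1), 0.8)
  expect_equal(eut_expected_utility(fx$beliefs, fx$utilities, 2), 0.2)
  expect_equal(round(eut_action_probability(fx$beliefs, fx$utilities, fx$params), 2),
               0.65)
  # zero utility annihilates the sum
  u0 <- utility_table(u_self_s = c(0, 0))
  expect_equal(eut_expected_utility(fx$beliefs, u0, 1), 0)
  # symmetric choice and zero inverse temperature both give 0.5
  bsym <- belief_set_binary(0.5, 0.5)
  expect_equal(eut_action_probability(bsym, fx$utilities, fx$params), 0.5)
  expect_equal(eut_action_probability(fx$beliefs, fx$utilities,
                                      decision_params(beta1 = 0)), 0.5)
  expect_error(eut_expected_utility(fx$beliefs, utility_table(u_self_as = rbind(1:2, 1:2)), 1),
               class = "dtmbc_config_error")
})

test_that("TPB constructs score as expected on hand-computable cases", {
  fx <- exercise_fixture()
  expect_equal(tpb_attitude(fx$beliefs, fx$utilities), 0.8)
  expect_equal(tpb_attitude(belief_set_binary(0.5, 0.5), fx$utilities), 0.5)
  # constant utilities: probabilities sum to one, attitude equals the constant
  uc <- utility_table(u_self_s = c(0.3, 0.3))
  expect_equal(tpb_attitude(fx$beliefs, uc), 0.3)

  expect_equal(tpb_subjective_norm(utility_table()), 0)
  u1 <- utility_table(referents = data.frame(u_a1 = 0.5, m = 1))
  expect_equal(tpb_subjective_norm(u1), 0.5)
  u2 <- utility_table(referents = data.frame(u_a1 = c(1, -1), m = c(0.5, 0.5)))
  expect_equal(tpb_subjective_norm(u2), 0)
})

test_that("TPB behavioral intention is the three-term weighted sum", {
  beliefs <- belief_set_binary(p_s1_a1 = 0.8, se_i1 = 0.9)
  u <- utility_table(u_self_s = c(1, 0),
                     referents = data.frame(u_a1 = 0.5, m = 1))
  p <- decision_params(tpb_weights = c(1, 1, 1))
  expect_equal(tpb_behavioral_intention(beliefs, u, p), 0.8 + 0.5 + 0.9)
  expect_equal(tpb_behavioral_intention(beliefs, u,
               decision_params(tpb_weights = c(0, 0, 0))), 0)
  # the additivity that the jar-lid case exploits: zero self-efficacy
  # still leaves the attitude term standing
  b0 <- belief_set_binary(p_s1_a1 = 0.8, se_i1 = 0)
  expect_equal(tpb_behavioral_intention(b0, u,
               decision_params(tpb_weights = c(1, 0, 1))), 0.8)
})

test_that("TPB intention and behavior probabilities follow the logistic and product rules", {
  p <- decision_params(beta1 = 1, beta0 = 0)
  expect_equal(tpb_intention_probability(0, p), 0.5)
  expect_equal(round(tpb_intention_probability(2.2, p), 4), SIG_2.2)
  expect_equal(tpb_intention_probability(99, decision_params(beta1 = 0, beta0 = 0.3)),
               sigmoid(0.3))
  b <- belief_set_binary(0.8, se_i1 = 0.9)
  expect_equal(tpb_behavior_probability(0.65, b), 0.585)
  b1 <- belief_set_binary(0.8, se_i1 = 1)
  expect_equal(tpb_behavior_probability(0.42, b1), 0.42)
  b0 <- belief_set_binary(0.8, se_i1 = 0)
  expect_equal(tpb_behavior_probability(0.42, b0), 0)
})

test_that("DTM expected utilities match an explicit double-summation oracle", {
  fx <- exercise_fixture()
  # independent oracle: literal double sum over j and n
  oracle <- function(beliefs, utilities, h) {
    tot <- 0
    for (j in 1:2) {
      for (n in seq_len(nrow(beliefs$p_state_given_action))) {
        u <- utilities$u_self_as[j, n] +
          utilities$w_social * utilities$u_others_as[j, n]
        tot <- tot + beliefs$p_act_given_intent[j, h] *
          beliefs$p_state_given_action[n, j] * u
      }
    }
    tot
  }
  expect_equal(dtm_expected_utility(fx$beliefs, fx$utilities, 1), 0.74)
  expect_equal(dtm_expected_utility(fx$beliefs, fx$utilities, 2), 0.26)
  set.seed(11)
  for (i in 1:25) {
    ps <- random_param_set()
    for (h in 1:2) {
      expect_equal(dtm_expected_utility(ps$beliefs, ps$utilities, h),
                   oracle(ps$beliefs, ps$utilities, h), tolerance = 1e-12)
    }
  }
})

test_that("DTM intention probability responds only to the expected-utility difference", {
  fx <- exercise_fixture()
  expect_equal(round(dtm_intention_probability(fx$beliefs, fx$utilities, fx$params), 4),
               SIG_0.48)
  # indistinguishable intentions: identical link columns give 0.5
  bsame <- belief_set_binary(0.8, 0.2, se_i1 = 0.7, se_i2 = 0.7)
  expect_equal(dtm_intention_probability(bsame, fx$utilities, fx$params), 0.5)
  # shifting every utility cell by a constant shifts both expected
  # utilities equally and leaves the intention probability unchanged
  set.seed(12)
  for (i in 1:20) {
    ps <- random_param_set()
    shifted <- ps$utilities
    shifted$u_self_as <- shifted$u_self_as + 1.7
    expect_equal(
      dtm_intention_probability(ps$beliefs, ps$utilities, ps$params),
      dtm_intention_probability(ps$beliefs, shifted, ps$params),
      tolerance = 1e-12)
  }
})

test_that("DTM behavior probability is the two-intention mixture", {
  b <- belief_set_binary(0.8, 0.2, se_i1 = 0.9, se_i2 = 0.1)
  expect_equal(dtm_behavior_probability(0.7, b), 0.9 * 0.7 + 0.1 * 0.3)
  # with P(a1|i2)=0 the mixture collapses to the TPB product
  b0 <- belief_set_binary(0.8, 0.2, se_i1 = 0.9, se_i2 = 0)
  expect_equal(dtm_behavior_probability(0.65, b0),
               tpb_behavior_probability(0.65, b0))
  bzero <- belief_set_binary(0.8, 0.2, se_i1 = 0, se_i2 = 0)
  for (p in c(0, 0.3, 1)) expect_equal(dtm_behavior_probability(p, bzero), 0)
})

test_that("regrouped and weighted-sum TPB intention forms agree", {
  set.seed(21)
  for (i in 1:200) {
    ps <- random_param_set()
    expect_equal(
      tpb_behavioral_intention(ps$beliefs, ps$utilities, ps$params, "weighted_sum"),
      tpb_behavioral_intention(ps$beliefs, ps$utilities, ps$params, "regrouped"),
      tolerance = 1e-9)
  }
})

test_that("nested and expanded DTM expected-utility forms agree", {
  set.seed(22)
  for (i in 1:200) {
    ps <- random_param_set()
    for (h in 1:2) {
      expect_equal(dtm_expected_utility(ps$beliefs, ps$utilities, h, "nested"),
                   dtm_expected_utility(ps$beliefs, ps$utilities, h, "expanded"),
                   tolerance = 1e-9)
    }
  }
})

test_that("DTM reduces exactly to EUT under deterministic links and action-independent utilities", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    p1 <- runif(n); p1 <- p1 / sum(p1)
    p2 <- runif(n); p2 <- p2 / sum(p2)
    beliefs <- belief_set(cbind(p1, p2), cbind(c(1, 0), c(0, 1)))
    us <- runif(n, -1, 1)
    u <- utility_table(u_self_s = us, u_self_as = rbind(us, us), w_social = 0)
    params <- decision_params(beta1 = runif(1, 0, 3), beta0 = runif(1, -1, 1))
    expect_identical(dtm_intention_probability(beliefs, u, params),
                     eut_action_probability(beliefs, u, params))
  }
})

test_that("DTM intention probability increases with a reachable good outcome's utility", {
  set.seed(24)
  for (i in 1:30) {
    ps <- random_param_set()
    if (ps$params$beta1 == 0) next
    b <- ps$beliefs
    # force P(a1|i1) > P(a1|i2)
    b$p_act_given_intent <- cbind(i1 = c(0.9, 0.1), i2 = c(0.2, 0.8))
    dimnames(b$p_act_given_intent) <- list(c("a1", "a2"), c("i1", "i2"))
    n <- which(b$p_state_given_action[, 1] > 0)[1]
    bumped <- ps$utilities
    bumped$u_self_as[1, n] <- bumped$u_self_as[1, n] + 0.5
    expect_gt(dtm_intention_probability(b, bumped, ps$params),
              dtm_intention_probability(b, ps$utilities, ps$params))
  }
})

test_that("lifting a TPB parameterization to DTM preserves the intention-1 correspondence", {
  set.seed(25)
  for (i in 1:30) {
    ps <- random_param_set()
    lifted <- tpb_to_dtm_utilities(ps$utilities, w_social = 1)
    # with a deterministic i1 -> a1 link, E[U_total|i1] equals
    # attitude + subjective norm (the regrouped TPB content terms at unit weights)
    b <- ps$beliefs
    b$p_act_given_intent <- cbind(c(1, 0), c(0, 1))
    dimnames(b$p_act_given_intent) <- list(c("a1", "a2"), c("i1", "i2"))
    expect_equal(dtm_expected_utility(b, lifted, 1),
                 tpb_attitude(b, ps$utilities) + tpb_subjective_norm(ps$utilities),
                 tolerance = 1e-12)
  }
})
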