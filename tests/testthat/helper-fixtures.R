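# Shared fixture builders. Everything is generated in code; no files.

# The canonical exercise-after-surgery parameterization: two states
# (recovery / no recovery), beliefs 0.8 / 0.2, state utilities (1, 0),
# with the DTM self-efficacy extension 0.9 / 0.1.
exercise_fixture <- function(se_i1 = 0.9, se_i2 = 0.1) {
  list(
    beliefs = belief_set_binary(p_s1_a1 = 0.8, p_s1_a2 = 0.2,
                                se_i1 = se_i1, se_i2 = se_i2),
    utilities = utility_table(u_self_s = c(1, 0),
                              u_self_as = rbind(c(1, 0), c(1, 0)),
                              w_social = 0),
    params = decision_params(beta1 = 1, beta0 = 0)
  )
}

# One random, valid parameter set (beliefs + utilities + params) with a
# random number of states and referents. Assumes the RNG is seeded by
# the caller.
random_param_set <- function(n_states = sample(2:5, 1)) {
  p1 <- stats::runif(n_states); p1 <- p1 / sum(p1)
  p2 <- stats::runif(n_states); p2 <- p2 / sum(p2)
  se <- stats::runif(2)
  beliefs <- belief_set(cbind(p1, p2),
                        cbind(c(se[1], 1 - se[1]), c(se[2], 1 - se[2])))
  k <- sample(0:3, 1)
  refs <- if (k > 0) {
    data.frame(u_a1 = stats::runif(k, -1, 1), m = stats::runif(k))
  } else NULL
  utilities <- utility_table(
    u_self_s = stats::runif(n_states, -1, 1),
    u_self_as = matrix(stats::runif(2 * n_states, -1, 1), 2),
    u_others_as = matrix(stats::runif(2 * n_states, -1, 1), 2),
    w_social = stats::runif(1),
    referents = refs
  )
  params <- decision_params(beta1 = stats::runif(1, 0, 3),
                            beta0 = stats::runif(1, -1, 1),
                            tpb_weights = stats::runif(3, -1, 1))
  list(beliefs = beliefs, utilities = utilities, params = params)
}

# A complete DTM questionnaire record with every item rated `rating`.
uniform_record <- function(rating = 3, schemas = dtm_item_schemas()) {
  rec <- lapply(schemas, function(s) {
    if (s$item_id == "behavior") min(rating, s$scale_max) else rating
  })
  names(rec) <- names(schemas)
  c(list(respondent_id = "r1"), rec)
}

# Response table of n random-but-valid DTM records.
random_responses <- function(n, schemas = dtm_item_schemas()) {
  rows <- lapply(seq_len(n), function(i) {
    rec <- lapply(schemas, function(s) sample(s$scale_min:s$scale_max, 1))
    names(rec) <- names(schemas)
    as.data.frame(c(list(respondent_id = paste0("r", i)), rec))
  })
  do.call(rbind, rows)
}
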