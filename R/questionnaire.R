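CONSTRUCTS <- c("behavioral_belief", "outcome_evaluation", "normative_belief",
                "motivation_to_comply", "perceived_self_efficacy",
                "behavioral_intention", "behavior")

#' Describe one questionnaire item
#'
#' An item schema says which model quantity an item measures and how its
#' Likert scale is anchored. Most instruments in this literature anchor
#' the positive pole at 1 ("likely:1 ... 5:unlikely"), which is what
#' `positive_pole_at_min` records; reverse-anchored items just flip it.
#'
#' @param item_id Column name of the item in a response table.
#' @param construct One of the instrument constructs: behavioral_belief,
#'   outcome_evaluation, normative_belief, motivation_to_comply,
#'   perceived_self_efficacy, behavioral_intention, behavior.
#' @param maps_to Model symbol the item scores to, e.g. `"P(s1|a1)"` or
#'   `"U_self(a1,s1)"`.
#' @param scale_min,scale_max Integer endpoints of the rating scale.
#' @param positive_pole_at_min TRUE when rating `scale_min` is the
#'   positive anchor.
#' @return An object of class `item_schema`.
#' @export
item_schema <- function(item_id, construct, maps_to,
                        scale_min = 1L, scale_max = 5L,
                        positive_pole_at_min = TRUE) {
  construct <- match.arg(construct, CONSTRUCTS)
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  if (scale_min >= scale_max) stop_config("scale_min must be < scale_max")
  structure(
    list(item_id = as.character(item_id), construct = construct,
         maps_to = as.character(maps_to), scale_min = scale_min,
         scale_max = scale_max,
         positive_pole_at_min = isTRUE(positive_pole_at_min)),
    class = "item_schema"
  )
}

#' Default item schemas for the TPB instrument
#'
#' One item per construct: behavioral belief P(s1|a1), outcome evaluation
#' U_self(s1), normative belief U_1(a1) with motivation to comply m_1 for
#' a single referent, perceived self-efficacy P(a1|i1), the behavioral
#' intention item, and the follow-up binary behavior item (true/false,
#' answered after the fact).
#'
#' @return Named list of [item_schema()] objects keyed by item id.
#' @export
tpb_item_schemas <- function() {
  s <- list(
    item_schema("bb_s1_a1", "behavioral_belief", "P(s1|a1)"),
    item_schema("ev_s1", "outcome_evaluation", "U_self(s1)"),
    item_schema("nb_1", "normative_belief", "U_1(a1)"),
    item_schema("mc_1", "motivation_to_comply", "m_1"),
    item_schema("se_i1", "perceived_self_efficacy", "P(a1|i1)"),
    item_schema("bi", "behavioral_intention", "BI(i1)"),
    item_schema("behavior", "behavior", "P(a1)", scale_min = 1L,
                scale_max = 2L)
  )
  stats::setNames(s, vapply(s, `[[`, "", "item_id"))
}

#' Default item schemas for the DTM instrument
#'
#' The DTM instrument extends the TPB one with the items its
#' intention-action-state chain needs: the belief about the outcome under
#' NOT performing the behavior P(s1|a2), self-efficacy without the
#' intention P(a1|i2) ("even if I DO NOT want to"), and the four
#' action-by-state cells of both U_self and U_others.
#'
#' @return Named list of [item_schema()] objects keyed by item id.
#' @export
dtm_item_schemas <- function() {
  extra <- list(
    item_schema("bb_s1_a2", "behavioral_belief", "P(s1|a2)"),
    item_schema("se_i2", "perceived_self_efficacy", "P(a1|i2)"),
    item_schema("ev_a1_s1", "outcome_evaluation", "U_self(a1,s1)"),
    item_schema("ev_a1_s2", "outcome_evaluation", "U_self(a1,s2)"),
    item_schema("ev_a2_s1", "outcome_evaluation", "U_self(a2,s1)"),
    item_schema("ev_a2_s2", "outcome_evaluation", "U_self(a2,s2)"),
    item_schema("nb_a1_s1", "normative_belief", "U_others(a1,s1)"),
    item_schema("nb_a1_s2", "normative_belief", "U_others(a1,s2)"),
    item_schema("nb_a2_s1", "normative_belief", "U_others(a2,s1)"),
    item_schema("nb_a2_s2", "normative_belief", "U_others(a2,s2)")
  )
  c(tpb_item_schemas(), stats::setNames(extra, vapply(extra, `[[`, "", "item_id")))
}

check_rating <- function(rating, schema) {
  if (!is.numeric(rating) || any(is.na(rating)) ||
      any(rating != round(rating)) ||
      any(rating < schema$scale_min | rating > schema$scale_max)) {
    stop(errorCondition(
      sprintf("item '%s': rating out of range [%d, %d]",
              schema$item_id, schema$scale_min, schema$scale_max),
      class = c("dtmbc_validation_error", "error")))
  }
  invisible(rating)
}

#' Map a Likert rating to a probability
#'
#' Linear map sending the positive anchor to 1 and the negative anchor
#' to 0; on the usual 1-5 scale with the positive pole at 1 this is
#' `(5 - rating) / 4`. The instruments give no calibration beyond the
#' anchors, so the map is linear by construction and configurable per
#' item through its schema.
#'
#' @param rating Integer rating(s) within the item's scale.
#' @param schema The item's [item_schema()].
#' @return Probability in [0, 1].
#' @export
likert_to_probability <- function(rating, schema) {
  check_rating(rating, schema)
  span <- schema$scale_max - schema$scale_min
  p <- (rating - schema$scale_min) / span
  if (schema$positive_pole_at_min) 1 - p else p
}

#' Map a Likert rating to a utility in [-1, 1]
#'
#' Linear map sending the positive anchor to +1, the scale midpoint to 0
#' and the negative anchor to -1.
#'
#' @inheritParams likert_to_probability
#' @return Utility in [-1, 1].
#' @export
likert_to_utility <- function(rating, schema) {
  2 * likert_to_probability(rating, schema) - 1
}

get_rating <- function(record, item_id, construct) {
  v <- record[[item_id]]
  if (is.null(v) || length(v) == 0 || is.na(v)) {
    stop(errorCondition(
      sprintf("missing construct '%s' (item '%s')", construct, item_id),
      class = c("dtmbc_scoring_error", "error")))
  }
  v
}

score_item <- function(record, schemas, item_id, as = c("probability", "utility")) {
  as <- match.arg(as)
  sch <- schemas[[item_id]]
  if (is.null(sch)) {
    stop(errorCondition(paste0("no schema for item '", item_id, "'"),
                        class = c("dtmbc_scoring_error", "error")))
  }
  r <- get_rating(record, item_id, sch$construct)
  if (as == "probability") likert_to_probability(r, sch) else likert_to_utility(r, sch)
}

#' Score one TPB questionnaire record into model parameters
#'
#' Maps a respondent's item ratings to the TPB parameterization:
#' behavioral belief to P(s1|a1) (complement filled), outcome evaluation
#' to U_self(s1) with U_self(s2) fixed at 0 (the instrument evaluates
#' only the named outcome; the complementary state is the reference
#' point), the referent pair to (U_1(a1), m_1) with m_1 on [0, 1], and
#' self-efficacy to P(a1|i1). P(a1|i2) is set to 0, the assumption under
#' which the TPB behavior formula is valid, and P(s1|a2), which TPB
#' never elicits or uses, is set to 0.5.
#'
#' @param record One respondent's ratings: a named list or one-row data
#'   frame with columns named by item id.
#' @param schemas Item schemas, as from [tpb_item_schemas()].
#' @return List with `beliefs` ([belief_set()]), `utilities`
#'   ([utility_table()]), and `bi_item` (the raw intention rating, NA if
#'   the item is absent).
#' @export
score_tpb <- function(record, schemas = tpb_item_schemas()) {
  p_s1_a1 <- score_item(record, schemas, "bb_s1_a1", "probability")
  u_s1 <- score_item(record, schemas, "ev_s1", "utility")
  u_ref <- score_item(record, schemas, "nb_1", "utility")
  m1 <- score_item(record, schemas, "mc_1", "probability")
  se1 <- score_item(record, schemas, "se_i1", "probability")
  bi_item <- if (!is.null(record[["bi"]])) record[["bi"]] else NA_integer_
  list(
    beliefs = belief_set_binary(p_s1_a1 = p_s1_a1, p_s1_a2 = 0.5,
                                se_i1 = se1, se_i2 = 0),
    utilities = utility_table(u_self_s = c(u_s1, 0),
                              referents = data.frame(u_a1 = u_ref, m = m1)),
    bi_item = bi_item
  )
}

#' Score one DTM questionnaire record into model parameters
#'
#' Scores the TPB items plus the DTM additions: P(s1|a2), P(a1|i2), and
#' the four cells each of U_self(a_j, s_n) and U_others(a_j, s_n). The
#' referent's per-cell ratings enter U_others directly; how strongly
#' they weigh on the agent is carried by the social weight w, which is a
#' decision parameter (typically fitted), so `w_social` is set to 1 here.
#'
#' @inheritParams score_tpb
#' @param schemas Item schemas, as from [dtm_item_schemas()].
#' @return List with `beliefs` and `utilities` (the utility table also
#'   carries the TPB state-only utilities and referent for side-by-side
#'   use of both models on the same respondent).
#' @export
score_dtm <- function(record, schemas = dtm_item_schemas()) {
  tpb <- score_tpb(record, schemas)
  p_s1_a1 <- score_item(record, schemas, "bb_s1_a1", "probability")
  p_s1_a2 <- score_item(record, schemas, "bb_s1_a2", "probability")
  se1 <- score_item(record, schemas, "se_i1", "probability")
  se2 <- score_item(record, schemas, "se_i2", "probability")
  u_self <- rbind(
    c(score_item(record, schemas, "ev_a1_s1", "utility"),
      score_item(record, schemas, "ev_a1_s2", "utility")),
    c(score_item(record, schemas, "ev_a2_s1", "utility"),
      score_item(record, schemas, "ev_a2_s2", "utility"))
  )
  u_others <- rbind(
    c(score_item(record, schemas, "nb_a1_s1", "utility"),
      score_item(record, schemas, "nb_a1_s2", "utility")),
    c(score_item(record, schemas, "nb_a2_s1", "utility"),
      score_item(record, schemas, "nb_a2_s2", "utility"))
  )
  list(
    beliefs = belief_set_binary(p_s1_a1 = p_s1_a1, p_s1_a2 = p_s1_a2,
                                se_i1 = se1, se_i2 = se2),
    utilities = utility_table(
      u_self_s = tpb$utilities$u_self_s,
      u_self_as = u_self, u_others_as = u_others, w_social = 1,
      referents = tpb$utilities$referents
    ),
    bi_item = tpb$bi_item
  )
}

#' Read a questionnaire response table from CSV
#'
#' Expects UTF-8, comma-separated, a header row of item ids, one
#' respondent per row, and a `respondent_id` column. Every rating is
#' validated against its item schema; out-of-range values are an error
#' naming the item.
#'
#' @param path CSV file path.
#' @param schemas Named list of [item_schema()]; columns without a schema
#'   (other than `respondent_id` and `behavior_observed`) are an error.
#' @return Data frame of responses.
#' @export
read_responses <- function(path, schemas = dtm_item_schemas()) {
  if (!file.exists(path)) stop_config("response file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"respondent_id" %in% names(df)) {
    stop(errorCondition("response table needs a respondent_id column",
                        class = c("dtmbc_validation_error", "error")))
  }
  extra <- setdiff(names(df), c("respondent_id", "behavior_observed",
                                names(schemas)))
  if (length(extra) > 0) {
    stop(errorCondition(
      paste0("unknown item columns: ", paste(extra, collapse = ", ")),
      class = c("dtmbc_validation_error", "error")))
  }
  for (id in intersect(names(df), names(schemas))) {
    check_rating(df[[id]], schemas[[id]])
  }
  if ("behavior_observed" %in% names(df) &&
      !all(df$behavior_observed %in% c(0, 1, NA))) {
    stop(errorCondition("behavior_observed must be 0/1",
                        class = c("dtmbc_validation_error", "error")))
  }
  df
}

#' Write a questionnaire response table to CSV
#'
#' @param responses Data frame of responses.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score a whole response table into a flat parameter table
#'
#' Applies [score_tpb()] or [score_dtm()] row-wise and flattens the
#' result into one numeric row per respondent, the covariate format the
#' estimation routines consume. TPB scoring yields the derived TPB
#' constructs (attitude, subjective norm, self-efficacy) alongside the
#' raw parameters; DTM scoring yields the full belief/utility cell set.
#'
#' @param responses Data frame as from [read_responses()].
#' @param model `"tpb"` or `"dtm"`.
#' @param schemas Item schemas matching the instrument.
#' @return Data frame, one row per respondent, carrying
#'   `behavior_observed` and the raw intention item through when present.
#' @export
score_responses <- function(responses, model = c("dtm", "tpb"),
                            schemas = NULL) {
  model <- match.arg(model)
  if (is.null(schemas)) {
    schemas <- if (model == "dtm") dtm_item_schemas() else tpb_item_schemas()
  }
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    rec <- as.list(responses[i, , drop = FALSE])
    if (model == "tpb") {
      sc <- score_tpb(rec, schemas)
      b <- sc$beliefs; u <- sc$utilities
      data.frame(
        respondent_id = rec$respondent_id,
        p_s1_a1 = b$p_state_given_action["s1", "a1"],
        u_self_s1 = u$u_self_s[1], u_self_s2 = u$u_self_s[2],
        ref_u_a1 = u$referents$u_a1[1], ref_m = u$referents$m[1],
        se_i1 = b$p_act_given_intent["a1", "i1"],
        attitude = tpb_attitude(b, u),
        norm = tpb_subjective_norm(u),
        bi_item = sc$bi_item
      )
    } else {
      sc <- score_dtm(rec, schemas)
      b <- sc$beliefs; u <- sc$utilities
      data.frame(
        respondent_id = rec$respondent_id,
        p_s1_a1 = b$p_state_given_action["s1", "a1"],
        p_s1_a2 = b$p_state_given_action["s1", "a2"],
        se_i1 = b$p_act_given_intent["a1", "i1"],
        se_i2 = b$p_act_given_intent["a1", "i2"],
        u_self_a1_s1 = u$u_self_as[1, 1], u_self_a1_s2 = u$u_self_as[1, 2],
        u_self_a2_s1 = u$u_self_as[2, 1], u_self_a2_s2 = u$u_self_as[2, 2],
        u_others_a1_s1 = u$u_others_as[1, 1], u_others_a1_s2 = u$u_others_as[1, 2],
        u_others_a2_s1 = u$u_others_as[2, 1], u_others_a2_s2 = u$u_others_as[2, 2],
        attitude = tpb_attitude(b, u),
        norm = tpb_subjective_norm(u),
        bi_item = sc$bi_item
      )
    }
  })
  out <- do.call(rbind, rows)
  if ("behavior_observed" %in% names(responses)) {
    out$behavior_observed <- responses$behavior_observed
  }
  rownames(out) <- NULL
  out
}
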