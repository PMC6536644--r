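# Model configurations serialize as plain named lists so the same schema
# works in YAML and JSON. Matrices travel row-major as lists of rows.

model_config_as_list <- function(spec = NULL, beliefs = NULL,
                                 utilities = NULL, params = NULL) {
  cfg <- list()
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "behavior_spec"))
    cfg$spec <- list(states = spec$states,
                     target_behavior = spec$target_behavior)
  }
  if (!is.null(beliefs)) {
    stopifnot(inherits(beliefs, "belief_set"))
    cfg$beliefs <- list(
      p_state_given_action = mat_to_rows(beliefs$p_state_given_action),
      p_act_given_intent = mat_to_rows(beliefs$p_act_given_intent)
    )
  }
  if (!is.null(utilities)) {
    stopifnot(inherits(utilities, "utility_table"))
    u <- list(w_social = utilities$w_social)
    if (!is.null(utilities$u_self_s)) u$u_self_s <- as.numeric(utilities$u_self_s)
    if (!is.null(utilities$u_self_as)) u$u_self_as <- mat_to_rows(utilities$u_self_as)
    if (!is.null(utilities$u_others_as)) u$u_others_as <- mat_to_rows(utilities$u_others_as)
    if (nrow(utilities$referents) > 0) {
      u$referents <- lapply(seq_len(nrow(utilities$referents)), function(k) {
        list(u_a1 = utilities$referents$u_a1[k], m = utilities$referents$m[k])
      })
    }
    cfg$utilities <- u
  }
  if (!is.null(params)) {
    stopifnot(inherits(params, "decision_params"))
    cfg$params <- list(beta1 = params$beta1, beta0 = params$beta0,
                       tpb_weights = params$tpb_weights)
  }
  cfg
}

mat_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))

model_config_from_list <- function(cfg) {
  out <- list(spec = NULL, beliefs = NULL, utilities = NULL, params = NULL)
  if (!is.null(cfg$spec)) {
    out$spec <- behavior_spec(cfg$spec$states, cfg$spec$target_behavior)
  }
  if (!is.null(cfg$beliefs)) {
    out$beliefs <- belief_set(
      rows_to_mat(cfg$beliefs$p_state_given_action),
      rows_to_mat(cfg$beliefs$p_act_given_intent)
    )
  }
  if (!is.null(cfg$utilities)) {
    u <- cfg$utilities
    refs <- NULL
    if (!is.null(u$referents)) {
      refs <- data.frame(
        u_a1 = vapply(u$referents, function(r) as.numeric(r$u_a1), numeric(1)),
        m = vapply(u$referents, function(r) as.numeric(r$m), numeric(1))
      )
    }
    out$utilities <- utility_table(
      u_self_s = if (is.null(u$u_self_s)) NULL else as.numeric(u$u_self_s),
      u_self_as = if (is.null(u$u_self_as)) NULL else rows_to_mat(u$u_self_as),
      u_others_as = if (is.null(u$u_others_as)) NULL else rows_to_mat(u$u_others_as),
      w_social = if (is.null(u$w_social)) 0 else as.numeric(u$w_social),
      referents = refs
    )
  }
  if (!is.null(cfg$params)) {
    out$params <- decision_params(cfg$params$beta1, cfg$params$beta0,
                                  as.numeric(cfg$params$tpb_weights))
  }
  out
}

#' Write a model configuration to YAML or JSON
#'
#' Serializes any subset of (behavior spec, beliefs, utilities, decision
#' parameters) to one config file; the format follows the file extension
#' (`.yaml`/`.yml` or `.json`). Numeric values are written at full double
#' precision so read/write round-trips are lossless well below 1e-12.
#'
#' @param path Output file path.
#' @param spec,beliefs,utilities,params Objects created by
#'   [behavior_spec()], [belief_set()], [utility_table()],
#'   [decision_params()]; any may be NULL.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(path, spec = NULL, beliefs = NULL,
                               utilities = NULL, params = NULL) {
  cfg <- model_config_as_list(spec, beliefs, utilities, params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(cfg, precision = 17), path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop_config("unsupported config extension: ", ext)
  }
  invisible(path)
}

#' Read a model configuration written by [write_model_config()]
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @return Named list with elements `spec`, `beliefs`, `utilities`,
#'   `params` (each NULL when absent from the file), validated through
#'   the same constructors as programmatic input.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop_config("unsupported config extension: ", ext)
  }
  model_config_from_list(cfg)
}
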