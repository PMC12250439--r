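#' @title Configuration file I/O
#' @description A model run is described declaratively in a YAML file with a
#'   `schema_version` key. [load_model_run()] parses and validates it into a
#'   [model_run()]; [write_model_run()] serialises a run back to YAML such
#'   that `load(write(run))` reproduces the run field-by-field.
#' @name config-io
NULL

config_schema_version <- 1L

config_error <- function(key, msg) {
  stop(sprintf("configuration error at '%s': %s", key, msg), call. = FALSE)
}

get_key <- function(node, key, where, required = TRUE, default = NULL) {
  if (is.null(node[[key]])) {
    if (required) config_error(paste(where, key, sep = "/"), "missing key")
    return(default)
  }
  node[[key]]
}

parse_subgroup <- function(node, where) {
  kind <- get_key(node, "kind", where)
  if (!kind %in% names(subgroup_kinds)) {
    config_error(paste0(where, "/kind"), "must be one of RWT, AMS, MA")
  }
  tl_node <- get_key(node, "timeline", where)
  twhere <- paste0(where, "/timeline")
  t_early <- get_key(tl_node, "t_early", twhere)
  t_death_early <- get_key(tl_node, "t_death_early", twhere)
  # scenario-specific defaults reduce boilerplate: the missed-surgery arm has
  # no delayed surgery, the lifesaving counterfactual dies at t_early
  t_death_cf <- get_key(tl_node, "t_death_counterfactual", twhere,
                        required = kind != "MA", default = t_early)
  t_delayed <- get_key(tl_node, "t_delayed", twhere, required = kind == "RWT",
                       default = if (kind == "AMS") t_death_cf else t_early)
  tl <- timeline(t_early, t_delayed, t_death_cf, t_death_early)

  u_node <- get_key(node, "utilities", where)
  u <- utility_profile(
    u_wait = get_key(u_node, "u_wait", paste0(where, "/utilities"),
                     required = kind == "RWT", default = NA_real_),
    u_post_early = get_key(u_node, "u_post_early",
                           paste0(where, "/utilities")),
    u_post_delayed = get_key(u_node, "u_post_delayed",
                             paste0(where, "/utilities"),
                             required = kind == "RWT", default = NA_real_),
    u_missed = get_key(u_node, "u_missed", paste0(where, "/utilities"),
                       required = kind == "AMS", default = NA_real_))

  c_node <- get_key(node, "costs", where, required = FALSE, default = list())
  cwhere <- paste0(where, "/costs")
  cs <- cost_set(
    direct_early = get_key(c_node, "direct_early", cwhere, FALSE, 0),
    direct_delayed = get_key(c_node, "direct_delayed", cwhere, FALSE, 0),
    indirect_patient_early =
      get_key(c_node, "indirect_patient_early", cwhere, FALSE, 0),
    indirect_patient_delayed =
      get_key(c_node, "indirect_patient_delayed", cwhere, FALSE, 0),
    indirect_caregiver_early =
      get_key(c_node, "indirect_caregiver_early", cwhere, FALSE, 0),
    indirect_caregiver_delayed =
      get_key(c_node, "indirect_caregiver_delayed", cwhere, FALSE, 0),
    incurrence_time_early =
      get_key(c_node, "incurrence_time_early", cwhere, FALSE, tl$t_early),
    incurrence_time_delayed =
      get_key(c_node, "incurrence_time_delayed", cwhere, FALSE, tl$t_delayed))

  subgroup_parameters(
    kind = kind,
    n_patients = get_key(node, "n_patients", where),
    utilities = u, timeline = tl, costs = cs,
    scenario = get_key(node, "scenario", where, required = FALSE))
}

#' Load and validate a model-run configuration file
#'
#' Parses the documented YAML schema, applies documented defaults (discount
#' rate 0.035 when omitted; scenario inferred from subgroup kind; cost
#' incurrence times defaulting to the surgery times; counterfactual event
#' times collapsing per scenario), and checks every structural invariant.
#'
#' @param path path to a YAML configuration file.
#' @return A validated [model_run()].
#' @seealso [write_model_run()], [validate_model_run()]
#' @export
load_model_run <- function(path) {
  if (!file.exists(path)) {
    config_error(path, "file does not exist")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    config_error(path, paste("YAML parse failure:", conditionMessage(e)))
  })
  model_run_from_list(doc)
}

#' Build a model run from an already-parsed configuration list
#'
#' @param doc a list with the same structure as the YAML schema.
#' @return A validated [model_run()].
#' @export
model_run_from_list <- function(doc) {
  if (!is.list(doc)) config_error("<root>", "top level must be a mapping")
  sv <- get_key(doc, "schema_version", "<root>", required = FALSE,
                default = config_schema_version)
  if (!identical(as.integer(sv), config_schema_version)) {
    config_error("schema_version",
                 sprintf("unsupported version %s (expected %d)",
                         sv, config_schema_version))
  }
  d_node <- get_key(doc, "discount", "<root>", required = FALSE,
                    default = list())
  disc <- discount_settings(
    annual_rate = get_key(d_node, "annual_rate", "discount", FALSE, 0.035))
  e_node <- get_key(doc, "economy", "<root>")
  econ <- economy_settings(
    gdp_per_capita = get_key(e_node, "gdp_per_capita", "economy"),
    wtp_threshold = get_key(e_node, "wtp_threshold", "economy"),
    currency_label = get_key(e_node, "currency_label", "economy",
                             FALSE, "EGP"))
  co_nodes <- get_key(doc, "cohorts", "<root>")
  if (!is.list(co_nodes) || length(co_nodes) == 0L) {
    config_error("cohorts", "must be a non-empty sequence")
  }
  cohorts <- lapply(seq_along(co_nodes), function(i) {
    node <- co_nodes[[i]]
    where <- sprintf("cohorts[%d]", i)
    name <- get_key(node, "name", where)
    sg_nodes <- get_key(node, "subgroups", where)
    if (!is.list(sg_nodes) || length(sg_nodes) == 0L) {
      config_error(paste0(where, "/subgroups"), "must be a non-empty sequence")
    }
    subgroups <- lapply(seq_along(sg_nodes), function(j) {
      parse_subgroup(sg_nodes[[j]], sprintf("%s/subgroups[%d]", where, j))
    })
    surgery_cohort(name, subgroups)
  })
  model_run(cohorts, disc, econ)
}

subgroup_to_list <- function(sg) {
  drop_na <- function(x) x[!vapply(x, function(v) is.na(v), logical(1))]
  list(kind = sg$kind, scenario = sg$scenario, n_patients = sg$n_patients,
       utilities = drop_na(unclass(sg$utilities)),
       timeline = unclass(sg$timeline),
       costs = unclass(sg$costs))
}

#' Convert a model run to its configuration-list form
#'
#' @param run a [model_run()].
#' @return A list mirroring the YAML schema.
#' @export
model_run_to_list <- function(run) {
  stopifnot(inherits(run, "model_run"))
  list(
    schema_version = config_schema_version,
    discount = unclass(run$discount),
    economy = unclass(run$economy),
    cohorts = lapply(unname(run$cohorts), function(co) {
      list(name = co$name,
           subgroups = lapply(unname(co$subgroups), subgroup_to_list))
    }))
}

#' Serialise a model run to a YAML configuration file
#'
#' The output is loadable by [load_model_run()] and reproduces the run
#' field-by-field (lossless round trip at 15 significant digits).
#'
#' @param run a [model_run()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_run <- function(run, path) {
  txt <- yaml::as.yaml(model_run_to_list(run), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}
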