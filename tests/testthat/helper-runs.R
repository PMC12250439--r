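# Small model runs built in code for unit tests.

make_rwt_subgroup <- function(n = 100,
                              u_wait = 0.5, u_post_early = 0.8,
                              u_post_delayed = 0.75,
                              t_early = 0, t_delayed = 1,
                              t_death_counterfactual = 20,
                              t_death_early = 22,
                              direct_early = 100000,
                              direct_delayed = 100000, ...) {
  subgroup_parameters(
    "RWT", n,
    utility_profile(u_wait = u_wait, u_post_early = u_post_early,
                    u_post_delayed = u_post_delayed),
    timeline(t_early, t_delayed, t_death_counterfactual, t_death_early),
    cost_set(direct_early = direct_early, direct_delayed = direct_delayed,
             incurrence_time_early = t_early,
             incurrence_time_delayed = t_delayed, ...))
}

tiny_run <- function(subgroups = list(make_rwt_subgroup()),
                     name = "surgery_a", rate = 0.035,
                     wtp = 56000, gdp = 56000) {
  model_run(list(surgery_cohort(name, subgroups)),
            discount_settings(rate),
            economy_settings(gdp, wtp))
}

minimal_config_yaml <- function(extra_timeline = NULL) {
  tl <- "t_early: 0.1\n          t_delayed: 1\n          t_death_counterfactual: 18\n          t_death_early: 20"
  if (!is.null(extra_timeline)) tl <- extra_timeline
  sprintf("
schema_version: 1
economy:
  gdp_per_capita: 56000
  wtp_threshold: 56000
cohorts:
  - name: demo_surgery
    subgroups:
      - kind: RWT
        n_patients: 100
        utilities:
          u_wait: 0.5
          u_post_early: 0.8
          u_post_delayed: 0.75
        timeline:
          %s
        costs:
          direct_early: 100000
          direct_delayed: 90000
", tl)
}

write_config <- function(text) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}
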