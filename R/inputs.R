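#' Default model inputs
#'
#' Assembles a ready-to-run input set from the packaged data files: the
#' published survival-model point estimates for the transition schedule, the
#' published incremental-cost point estimates (2009 EUR), and the synthetic
#' life table and hazard-ratio fixtures (clearly non-authoritative stand-ins
#' — substitute national data for real analyses).
#'
#' @param spec A [model_spec()] (defaults to the base-case specification).
#' @return List with `spec`, `models`, `schedule`, `lifetable`, `hrs`,
#'   `cost_points` and `cost_schedule`, the shape expected by
#'   [run_base_case()], [run_scenario()] and [run_psa()].
#' @export
default_inputs <- function(spec = model_spec()) {
  models <- transition_models_from_table()
  cost_points <- read.csv(bmicohort_example("incremental_cost_points.csv"),
                          stringsAsFactors = FALSE)
  list(spec = spec,
       models = models,
       schedule = build_schedule(models),
       lifetable = read_life_table(bmicohort_example("life_table_synthetic.csv")),
       hrs = read_hazard_ratios(bmicohort_example("hazard_ratios_synthetic.csv")),
       cost_points = cost_points,
       cost_schedule = extend_cost_schedule(cost_points))
}

#' Run the base-case cohort simulation
#'
#' Simulates both sexes from age 2 to 100 and derives prevalence among the
#' living, survival-adjusted incremental costs (discounted and undiscounted)
#' and life expectancy.
#'
#' @param inputs Model inputs (see [default_inputs()]).
#' @return A `base_case_result` list: per-sex `traces`, `costs`, `prevalence`
#'   matrices and a `summary` data frame.
#' @export
run_base_case <- function(inputs = default_inputs()) {
  spec <- inputs$spec
  traces <- list(); costs <- list(); prev <- list()
  rows <- list()
  for (s in c("female", "male")) {
    traces[[s]] <- run_cohort(spec, inputs$schedule, inputs$lifetable,
                              inputs$hrs, s)
    costs[[s]] <- expected_costs(traces[[s]], inputs$cost_schedule,
                                 spec$discount_rate)
    prev[[s]] <- prevalence_among_alive(traces[[s]])
    cs <- costs[[s]]$summary
    rows[[s]] <- data.frame(
      sex = s,
      life_expectancy = life_expectancy(traces[[s]], spec$half_cycle),
      cum_cost_pp = cs$cum_pp[cs$state == "total"],
      cum_cost_disc_pp = cs$cum_disc_pp[cs$state == "total"],
      cum_obesity_cost_pp = sum(cs$cum_pp[cs$state %in% c("OB1", "OB2")]))
  }
  structure(list(traces = traces, costs = costs, prevalence = prev,
                 summary = do.call(rbind, rows), spec = spec),
            class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("<base_case_result>\n")
  for (s in names(x$traces)) {
    p45 <- x$prevalence[[s]][, "45"]
    cat(sprintf(
      "  %-6s LE %.2f y | prevalence at 45: OW %.1f%%, OB1+OB2 %.1f%% | lifetime incremental cost/person: EUR %.0f (EUR %.0f discounted)\n",
      s, x$summary$life_expectancy[x$summary$sex == s],
      100 * p45[["OW"]], 100 * (p45[["OB1"]] + p45[["OB2"]]),
      x$summary$cum_cost_pp[x$summary$sex == s],
      x$summary$cum_cost_disc_pp[x$summary$sex == s]))
  }
  invisible(x)
}

#' Export a cohort trace as delimited text
#'
#' Long format `sex,age,state,persons`.
#'
#' @param trace A [run_cohort()] trace.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(sex = attr(trace, "sex"),
                   age = rep(as.integer(colnames(trace)), each = nrow(trace)),
                   state = rep(rownames(trace), times = ncol(trace)),
                   persons = as.vector(trace))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
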