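#' Model specification for the cohort simulation
#'
#' Defaults describe the base-case study conditions: a birth cohort of 55,120
#' two-year-olds (26,458 girls, 28,662 boys — 48%/52%), initially distributed
#' 89.83% NW, 8.98% OW, 0.86% OB1 and 0.33% OB2, simulated in one-year cycles
#' for 98 years (to age 100), with costs discounted at 4% per year.
#'
#' @param start_age First modelled age (years).
#' @param end_age Last modelled age (years).
#' @param cohort_female,cohort_male Starting cohort sizes per sex.
#' @param init Initial distribution over the four weight classes (NW, OW, OB1,
#'   OB2); must sum to 1. The NW mass enters NW1 (never previously heavier).
#' @param discount_rate Annual discount rate applied to costs.
#' @param half_cycle Apply a half-cycle (trapezoid) correction in
#'   [life_expectancy()] (off by default).
#' @return A `model_spec` list.
#' @export
model_spec <- function(start_age = 2, end_age = 100,
                       cohort_female = 26458, cohort_male = 28662,
                       init = c(NW = 0.8983, OW = 0.0898, OB1 = 0.0086,
                                OB2 = 0.0033),
                       discount_rate = 0.04, half_cycle = FALSE) {
  if (abs(sum(init) - 1) > 1e-9) stop("initial distribution must sum to 1",
                                      call. = FALSE)
  if (!all(names(init) == c("NW", "OW", "OB1", "OB2"))) {
    stop("init must be named NW, OW, OB1, OB2", call. = FALSE)
  }
  structure(list(start_age = start_age, end_age = end_age,
                 cohort = c(female = cohort_female, male = cohort_male),
                 init = init, discount_rate = discount_rate,
                 half_cycle = half_cycle),
            class = "model_spec")
}

#' Assemble the one-cycle transition matrix at a given age
#'
#' Builds the row-stochastic 6x6 matrix over the states NW1, NW2, OW, OB1,
#' OB2, DEAD governing one annual cycle. Death is applied first: each live
#' state moves its death probability to DEAD, and the surviving mass is split
#' among the allowed weight-class moves (only one-class moves exist; OW
#' regresses to NW2, never NW1; NW1 and NW2 share all parameters), with the
#' stay probability absorbing the remainder so every row sums to 1 exactly.
#'
#' @param age Integer age at cycle start.
#' @param sex `"female"` or `"male"`.
#' @param schedule A [build_schedule()] result.
#' @param lifetable,hrs Mortality inputs (see [death_probability()]).
#' @return A 6x6 row-stochastic matrix.
#' @export
assemble_matrix <- function(age, sex, schedule, lifetable, hrs) {
  p <- schedule_at(schedule, sex, age)
  q <- vapply(STATES[1:5], function(s)
    death_probability(lifetable, hrs, sex, age, s), numeric(1))
  build_matrix(p, q, age, sex)
}

# core matrix builder from a transition-probability vector (named by
# TRANSITIONS) and a death-probability vector (named by live states)
build_matrix <- function(p, q, age = NA, sex = "") {
  moves <- list(  # state -> list(destination = schedule probability)
    NW1 = c(OW = p[["NW-OW"]]),
    NW2 = c(OW = p[["NW-OW"]]),
    OW  = c(OB1 = p[["OW-OB1"]], NW2 = p[["OW-NW"]]),
    OB1 = c(OB2 = p[["OB1-OB2"]], OW = p[["OB1-OW"]]),
    OB2 = c(OB1 = p[["OB2-OB1"]])
  )
  M <- matrix(0, 6, 6, dimnames = list(STATES, STATES))
  for (s in STATES[1:5]) {
    mv <- moves[[s]]
    if (sum(mv) > 1 + 1e-12) {
      stop(sprintf("transition probabilities out of state %s exceed 1 at age %s (%s)",
                   s, age, sex), call. = FALSE)
    }
    M[s, "DEAD"] <- q[[s]]
    M[s, names(mv)] <- (1 - q[[s]]) * mv
    M[s, s] <- (1 - q[[s]]) * (1 - sum(mv))
  }
  M["DEAD", "DEAD"] <- 1
  M
}

# death probabilities for all live states over an age vector: [5 x ages]
death_probability_matrix <- function(lifetable, hrs, sex, ages) {
  m <- vapply(STATES[1:5], function(s)
    death_probability(lifetable, hrs, sex, ages, s), numeric(length(ages)))
  matrix(t(m), nrow = 5, dimnames = list(STATES[1:5], ages))
}

#' Run the cohort simulation for one sex
#'
#' Propagates the starting occupancy through [assemble_matrix()] for every
#' annual cycle from `start_age` to `end_age`. Anyone still alive at the end
#' of the horizon is retained (no forced death), so life expectancy is
#' horizon-truncated.
#'
#' @param spec A [model_spec()].
#' @param schedule,lifetable,hrs Model inputs.
#' @param sex `"female"` or `"male"`.
#' @param init Optional occupancy vector over the six states at `start_age`
#'   (persons); defaults to the spec's initial distribution times the sex's
#'   cohort size, with the NW mass in NW1.
#' @param start_age Optional override of the spec's start age (used by the
#'   conditional-start scenarios).
#' @return A `cohort_trace`: persons per state (rows) per age (columns),
#'   with attributes `sex` and `cohort_size`.
#' @export
run_cohort <- function(spec, schedule, lifetable, hrs, sex,
                       init = NULL, start_age = spec$start_age) {
  ages <- start_age:spec$end_age
  if (is.null(init)) {
    size <- spec$cohort[[sex]]
    init <- setNames(numeric(6), STATES)
    init["NW1"] <- spec$init[["NW"]] * size
    init["OW"] <- spec$init[["OW"]] * size
    init["OB1"] <- spec$init[["OB1"]] * size
    init["OB2"] <- spec$init[["OB2"]] * size
  }
  stopifnot(length(init) == 6)
  trace <- matrix(0, nrow = 6, ncol = length(ages),
                  dimnames = list(STATES, ages))
  trace[, 1] <- init
  cycle_ages <- ages[-length(ages)]
  qmat <- death_probability_matrix(lifetable, hrs, sex, cycle_ages)
  tpm <- schedule$tp[[sex]][, match(cycle_ages, schedule$ages), drop = FALSE]
  if (anyNA(tpm)) stop("schedule does not cover ages ", min(cycle_ages), "-",
                       max(cycle_ages), call. = FALSE)
  for (i in seq_along(cycle_ages)) {
    M <- build_matrix(tpm[, i], qmat[, i], cycle_ages[i], sex)
    trace[, i + 1] <- drop(crossprod(M, trace[, i]))
  }
  structure(trace, sex = sex, cohort_size = sum(init), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  ages <- as.integer(colnames(x))
  cat(sprintf("<cohort_trace> %s, %s persons, ages %d-%d (alive at end: %.0f)\n",
              attr(x, "sex"), format(attr(x, "cohort_size"), big.mark = ","),
              min(ages), max(ages), sum(x[1:5, ncol(x)])))
  invisible(x)
}

alive_at <- function(trace) colSums(trace[STATES[1:5], , drop = FALSE])

#' Weight-class prevalence among the living
#'
#' Proportions of the cohort still alive at each age who are NW (NW1 + NW2),
#' OW, OB1 or OB2; fractions sum to 1 at every age.
#'
#' @param trace A [run_cohort()] trace.
#' @param age Optional integer age(s); default all ages in the trace.
#' @return Matrix with rows NW, OW, OB1, OB2 and one column per age.
#' @export
prevalence_among_alive <- function(trace, age = NULL) {
  ages <- as.integer(colnames(trace))
  j <- if (is.null(age)) seq_along(ages) else match(age, ages)
  if (anyNA(j)) stop("age outside the trace range", call. = FALSE)
  alive <- alive_at(trace)[j]
  if (any(alive <= 0)) stop("prevalence undefined: nobody alive", call. = FALSE)
  m <- rbind(NW = trace["NW1", j] + trace["NW2", j],
             OW = trace["OW", j], OB1 = trace["OB1", j], OB2 = trace["OB2", j])
  sweep(m, 2, alive, "/")
}

#' Life expectancy from a cohort trace
#'
#' Expected age at death under the end-of-cycle death convention:
#' `start_age + sum over later ages of the alive fraction`. With
#' `half_cycle = TRUE` a trapezoid correction credits half a year for the
#' cycle in which death occurs. The horizon truncates at the trace's last age:
#' survivors at the end contribute no further years.
#'
#' @param trace A [run_cohort()] trace.
#' @param half_cycle Apply the trapezoid (half-cycle) correction.
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(trace, half_cycle = FALSE) {
  ages <- as.integer(colnames(trace))
  af <- alive_at(trace) / attr(trace, "cohort_size")
  le <- ages[1] + sum(af[-1])
  if (half_cycle) le <- le + 0.5 * (af[1] - af[length(af)])
  unname(le)
}

#' Compare modelled prevalence with an observed reference
#'
#' External-validity helper: contrasts the model's prevalence among the
#' living with observed prevalence by age band, and flags whether each
#' modelled value lies inside supplied confidence bounds.
#'
#' @param trace A [run_cohort()] trace.
#' @param reference Data frame with columns `age_lo`, `age_hi` (band,
#'   inclusive), `class` (NW/OW/OB1/OB2), `observed` (fraction), and
#'   optionally `lo`, `hi` (bounds on the observed fraction).
#' @return The reference with added columns `modelled` (alive-weighted mean
#'   over the band's ages), `difference` (modelled minus observed) and, when
#'   bounds are present, `within_bounds`.
#' @export
compare_prevalence <- function(trace, reference) {
  need <- c("age_lo", "age_hi", "class", "observed")
  if (!all(need %in% names(reference))) {
    stop("reference needs columns ", paste(need, collapse = ","), call. = FALSE)
  }
  ages <- as.integer(colnames(trace))
  prev <- prevalence_among_alive(trace)
  alive <- alive_at(trace)
  reference$modelled <- vapply(seq_len(nrow(reference)), function(i) {
    j <- which(ages >= reference$age_lo[i] & ages <= reference$age_hi[i])
    if (length(j) == 0) stop("reference band outside the trace range", call. = FALSE)
    sum(prev[reference$class[i], j] * alive[j]) / sum(alive[j])
  }, numeric(1))
  reference$difference <- reference$modelled - reference$observed
  if (all(c("lo", "hi") %in% names(reference))) {
    reference$within_bounds <- reference$modelled >= reference$lo &
      reference$modelled <= reference$hi
  }
  reference
}
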