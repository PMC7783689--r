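#' Fit a two-part health-care cost model
#'
#' Annual health-care costs are semicontinuous: many zeros (non-users) and a
#' right-skewed positive part. The two-part model combines a logistic
#' regression for any use, P(cost > 0), with a log-link gamma GLM for the
#' positive costs; expected cost is the product of the two parts. Covariates
#' are weight class, age (continuous), smoking status and marital status;
#' models are fitted separately per sex.
#'
#' @param records Data frame with columns `sex`, `age`, `weight_class`
#'   (NW/OW/OB1/OB2), `smoking`, `marital`, `annual_cost` (EUR, >= 0).
#' @param sex `"female"` or `"male"` — the stratum to fit.
#' @return A `two_part_model`: list with `part1` (binomial GLM), `part2`
#'   (Gamma GLM on positives) and the estimation sample.
#' @export
fit_two_part <- function(records, sex) {
  d <- records[records$sex == sex, ]
  if (nrow(d) == 0) stop("no records for sex '", sex, "'", call. = FALSE)
  if (any(d$annual_cost < 0)) stop("costs must be non-negative", call. = FALSE)
  d$weight_class <- factor(d$weight_class, levels = CLASSES)
  d$any_cost <- d$annual_cost > 0
  if (all(d$any_cost) || !any(d$any_cost)) {
    stop("two-part model needs both zero and positive costs", call. = FALSE)
  }
  # drop constant factors (e.g. single-level smoking in synthetic data)
  rhs <- c("weight_class", "age",
           if (length(unique(d$smoking)) > 1) "smoking",
           if (length(unique(d$marital)) > 1) "marital")
  form1 <- stats::reformulate(rhs, response = "any_cost")
  form2 <- stats::reformulate(rhs, response = "annual_cost")
  part1 <- glm(form1, family = binomial(), data = d)
  part2 <- glm(form2, family = Gamma(link = "log"), data = d,
               subset = d$any_cost)
  if (!part1$converged || !part2$converged) {
    stop("two-part model did not converge (possible separation)", call. = FALSE)
  }
  structure(list(part1 = part1, part2 = part2, data = d, sex = sex),
            class = "two_part_model")
}

#' Predicted expected cost from a two-part model
#'
#' @param model A [fit_two_part()] model.
#' @param newdata Data frame of covariates.
#' @return Expected annual cost: P(cost > 0) x E\[cost | cost > 0\].
#' @export
predict_two_part <- function(model, newdata) {
  p <- predict(model$part1, newdata = newdata, type = "response")
  mu <- predict(model$part2, newdata = newdata, type = "response")
  p * mu
}

#' Average marginal incremental cost of a weight class
#'
#' The average marginal effect at a given age: the estimation sample is
#' duplicated with everyone assigned the target class and everyone assigned
#' NW, `age` set to the requested value, and the mean difference of the
#' two-part predictions is returned (observed-sample averaging over the other
#' covariates). NW returns 0 by construction.
#'
#' @param model A [fit_two_part()] model.
#' @param age Age in years, within the 20–80 estimation range.
#' @param state Weight class (`"NW"`, `"OW"`, `"OB1"`, `"OB2"`).
#' @return Incremental annual cost vs NW in EUR.
#' @export
marginal_incremental_cost <- function(model, age, state) {
  state <- match.arg(state, CLASSES)
  if (age < 20 || age > 80) {
    stop("age must be in 20-80; use extend_cost_schedule() for other ages",
         call. = FALSE)
  }
  if (state == "NW") return(0)
  d <- model$data
  d$age <- age
  d_state <- d; d_state$weight_class <- factor(state, levels = CLASSES)
  d_nw <- d; d_nw$weight_class <- factor("NW", levels = CLASSES)
  mean(predict_two_part(model, d_state)) - mean(predict_two_part(model, d_nw))
}

#' Extend incremental costs to the full age range
#'
#' Builds a complete incremental cost schedule over ages 2–100 from values
#' available for ages 20–80. Ages above 80 are held constant at the age-80
#' value; ages below 20 follow `under20_rule` (`"zero"` — no incremental
#' cost, the default — or `"constant_at_20"`). The NW column is identically 0
#' (incremental accounting, NW as the EUR 0 reference).
#'
#' @param x Either a data frame `sex,state,age,cost` covering ages 20–80, a
#'   data frame `sex,state,cost` of age-constant increments, or a
#'   [fit_two_part()] model (evaluated via [marginal_incremental_cost()]).
#' @param under20_rule Rule for ages 2–19.
#' @param sex Required when `x` is a fitted model.
#' @return A `cost_schedule` data frame `sex,state,age,cost` covering ages
#'   2–100 for the supplied sexes.
#' @export
extend_cost_schedule <- function(x, under20_rule = c("zero", "constant_at_20"),
                                 sex = NULL) {
  under20_rule <- match.arg(under20_rule)
  if (inherits(x, "two_part_model")) {
    sex <- x$sex
    x <- do.call(rbind, lapply(CLASSES, function(cl)
      data.frame(sex = sex, state = cl, age = 20:80,
                 cost = vapply(20:80, function(a)
                   marginal_incremental_cost(x, a, cl), numeric(1)))))
  }
  if (!"age" %in% names(x)) {  # age-constant increments
    x <- do.call(rbind, lapply(seq_len(nrow(x)), function(i)
      data.frame(sex = x$sex[i], state = x$state[i], age = 20:80,
                 cost = x$cost[i])))
  }
  out <- list()
  for (s in unique(x$sex)) for (cl in CLASSES) {
    d <- x[x$sex == s & x$state == cl, ]
    if (cl != "NW" && nrow(d) > 0 && !all(20:80 %in% d$age)) {
      stop("cost values must cover every age 20-80 for ", s, "/", cl,
           call. = FALSE)
    }
    # NW is the reference (always 0); classes without rows have no increment
    core <- if (cl == "NW" || nrow(d) == 0) rep(0, 61) else
      d$cost[match(20:80, d$age)]
    young <- switch(under20_rule, zero = rep(0, 18),
                    constant_at_20 = rep(core[1], 18))
    old <- rep(core[length(core)], 20)  # ages 81-100 flat at the age-80 value
    out[[length(out) + 1L]] <- data.frame(sex = s, state = cl, age = 2:100,
                                          cost = c(young, core, old))
  }
  res <- do.call(rbind, out)
  class(res) <- c("cost_schedule", "data.frame")
  res
}

cost_increment_matrix <- function(schedule, sex, ages) {
  d <- schedule[schedule$sex == sex, ]
  m <- matrix(0, nrow = length(CLASSES), ncol = length(ages),
              dimnames = list(CLASSES, ages))
  idx <- cbind(match(d$state, CLASSES), match(d$age, ages))
  ok <- complete.cases(idx)
  m[idx[ok, , drop = FALSE]] <- d$cost[ok]
  if (!all(ages %in% d$age)) stop("cost schedule does not cover all trace ages",
                                  call. = FALSE)
  m
}

#' Survival-adjusted incremental costs of a simulated cohort
#'
#' Multiplies the number of persons occupying each weight class at each age by
#' that class's incremental annual cost, yielding survival-adjusted
#' incremental costs: only the living accrue costs. Discounted values divide
#' by `(1 + r)^(age - start_age)`; per-person values divide by the starting
#' cohort size.
#'
#' @param trace A [run_cohort()] trace.
#' @param schedule A [extend_cost_schedule()] cost schedule.
#' @param discount_rate Annual discount rate (default 0.04).
#' @return List with `by_age` (data frame: age, per-class and total annual
#'   costs, discounted and per-person variants, cumulative totals) and
#'   `summary` (cumulative per-person and whole-cohort costs by class,
#'   discounted and undiscounted).
#' @export
expected_costs <- function(trace, schedule, discount_rate = 0.04) {
  ages <- as.integer(colnames(trace))
  sex <- attr(trace, "sex")
  size <- attr(trace, "cohort_size")
  inc <- cost_increment_matrix(schedule, sex, ages)
  occ <- rbind(NW = trace["NW1", ] + trace["NW2", ], OW = trace["OW", ],
               OB1 = trace["OB1", ], OB2 = trace["OB2", ])
  annual_by_class <- occ * inc                      # whole-cohort EUR per age
  annual <- colSums(annual_by_class)
  disc <- (1 + discount_rate)^(ages - ages[1])
  by_age <- data.frame(age = ages, t(annual_by_class),
                       annual = annual, annual_pp = annual / size,
                       annual_disc = annual / disc,
                       cumulative = cumsum(annual),
                       cumulative_disc = cumsum(annual / disc))
  summary <- data.frame(
    state = rownames(annual_by_class),
    cum = rowSums(annual_by_class),
    cum_disc = as.vector(annual_by_class %*% (1 / disc)))
  summary$cum_pp <- summary$cum / size
  summary$cum_disc_pp <- summary$cum_disc / size
  total <- data.frame(state = "total", cum = sum(summary$cum),
                      cum_disc = sum(summary$cum_disc),
                      cum_pp = sum(summary$cum_pp),
                      cum_disc_pp = sum(summary$cum_disc_pp))
  list(by_age = by_age, summary = rbind(summary, total))
}
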