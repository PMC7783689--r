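#' Specification for the synthetic longitudinal cohort generator
#'
#' Describes a synthetic data-generating process that emulates the structure
#' of linked growth-survey data: a latent annual weight-class path per person
#' driven by known parametric transition hazards, observed only at sparse
#' visit ages. Visits are drawn independently at each candidate age with a
#' probability set so that the expected number of observations per person
#' matches `mean_visits` (default 2.84, the observation density of the linked
#' Norwegian surveys); persons ending up with fewer than two visits are kept
#' in the output so downstream exclusion rules are exercised.
#'
#' @param n_persons Number of persons.
#' @param female_share Probability a person is female (default 0.48).
#' @param ages Integer ages of the latent annual path (default 2:12, the
#'   childhood window; widen for adolescent/adult studies).
#' @param visit_ages Candidate observation ages (default `ages`).
#' @param mean_visits Expected observations per person (default 2.84).
#' @param models Nested list of true transition hazards per
#'   sex/transition/band (see [build_schedule()]); default: the packaged
#'   parameter table.
#' @param init Initial weight-class distribution at the first age.
#' @param dropout Annual probability of permanent dropout after the first
#'   visit (non-informative; default 0).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_persons = 2000, female_share = 0.48,
                           ages = 2:12, visit_ages = ages,
                           mean_visits = 2.84,
                           models = transition_models_from_table(),
                           init = c(NW = 0.8983, OW = 0.0898, OB1 = 0.0086,
                                    OB2 = 0.0033),
                           dropout = 0) {
  stopifnot(n_persons > 0, abs(sum(init) - 1) < 1e-9)
  structure(list(n_persons = n_persons, female_share = female_share,
                 ages = as.integer(ages), visit_ages = as.integer(visit_ages),
                 mean_visits = mean_visits, models = models, init = init,
                 dropout = dropout),
            class = "generator_spec")
}

# yearly move probabilities (up, down) for a class at an age under the truth
latent_move_probs <- function(models, sex, cls, age) {
  bands <- estimation_bands()
  b <- band_for_age(age)
  entry <- bands$entry[bands$band == b]
  up <- switch(cls, NW = "NW-OW", OW = "OW-OB1", OB1 = "OB1-OB2", OB2 = NULL)
  down <- switch(cls, NW = NULL, OW = "OW-NW", OB1 = "OB1-OW", OB2 = "OB2-OB1")
  get <- function(tr) {
    if (is.null(tr)) return(0)
    m <- models[[sex]][[tr]][[b]]
    if (is.null(m)) 0 else yearly_tp(m, entry, age)
  }
  c(up = get(up), down = get(down))
}

# precomputed (class x age) move-probability tables for one sex
latent_move_tables <- function(models, sex, ages) {
  up <- down <- matrix(0, nrow = 4, ncol = length(ages),
                       dimnames = list(CLASSES, ages))
  for (cls in CLASSES) for (j in seq_along(ages)) {
    p <- latent_move_probs(models, sex, cls, ages[j])
    up[cls, j] <- p[["up"]]
    down[cls, j] <- p[["down"]]
  }
  list(up = up, down = down)
}

# latent annual class paths, all persons advanced one age step at a time
# (one-class moves only)
simulate_class_paths <- function(models, sexes, cls0, ages) {
  n <- length(sexes)
  tabs <- list(female = latent_move_tables(models, "female", ages),
               male = latent_move_tables(models, "male", ages))
  rank <- matrix(NA_integer_, nrow = n, ncol = length(ages))
  rank[, 1] <- class_rank(cls0)
  for (j in seq_len(length(ages) - 1)) {
    u <- runif(n)
    for (s in c("female", "male")) {
      i <- sexes == s
      if (!any(i)) next
      pu <- tabs[[s]]$up[cbind(rank[i, j], j)]
      pd <- tabs[[s]]$down[cbind(rank[i, j], j)]
      rank[i, j + 1] <- rank[i, j] + (u[i] < pu) - (u[i] >= pu & u[i] < pu + pd)
    }
  }
  matrix(CLASSES[rank], nrow = n)
}

# BMI band [lo, hi) for a class at an age/sex; bands outside the tabulated
# thresholds get a fixed plausible width
class_bmi_bounds <- function(cls, age, sex, cutoffs) {
  if (age >= 18) {
    th <- c(ow = 25, ob1 = 30, ob2 = 35)
  } else {
    row <- cutoffs[cutoffs$sex == sex & cutoffs$age == floor(age), ]
    th <- c(ow = row$ow, ob1 = row$ob1, ob2 = row$ob2)
  }
  switch(cls,
    NW  = c(th[["ow"]] - 4, th[["ow"]]),
    OW  = c(th[["ow"]], th[["ob1"]]),
    OB1 = c(th[["ob1"]], th[["ob2"]]),
    OB2 = c(th[["ob2"]], th[["ob2"]] + 6))
}

# deterministic growth curve: linear gain to the adult height at 18
synthetic_height <- function(age, sex) {
  adult <- ifelse(sex == "female", 1.68, 1.80)
  frac <- pmin(pmax((age - 2) / 16, 0), 1)
  0.87 + (adult - 0.87) * frac
}

#' Simulate a sparse longitudinal anthropometric cohort
#'
#' Generates person-level height/weight records from the process described in
#' [generator_spec()]: the latent annual weight-class path follows the true
#' hazards (one-class moves only), and at each attended visit a BMI is drawn
#' uniformly inside the class's BMI band for the person's age and sex, then
#' converted to weight via a deterministic growth-curve height.
#'
#' @param spec A [generator_spec()].
#' @param cutoffs Child cutoff table (used for the BMI class bands).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Data frame of anthropometric records `person_id`, `sex`, `age`,
#'   `height`, `weight`, plus a `latent` attribute holding the true annual
#'   class paths (for validation).
#' @export
simulate_longitudinal_cohort <- function(spec, cutoffs, seed) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  n <- spec$n_persons
  p_visit <- min(1, spec$mean_visits / length(spec$visit_ages))
  sexes <- ifelse(runif(n) < spec$female_share, "female", "male")
  cls0 <- sample(CLASSES, n, replace = TRUE, prob = spec$init)
  paths <- simulate_class_paths(spec$models, sexes, cls0, spec$ages)
  latent <- data.frame(person_id = rep(seq_len(n), each = length(spec$ages)),
                       sex = rep(sexes, each = length(spec$ages)),
                       age = rep(spec$ages, times = n),
                       class = as.vector(t(paths)), stringsAsFactors = FALSE)
  attend <- matrix(runif(n * length(spec$visit_ages)) < p_visit, nrow = n)
  if (spec$dropout > 0) {
    for (i in seq_len(n)) {
      at <- which(attend[i, ])
      if (length(at) > 1) {
        gone <- which(runif(length(at) - 1) < spec$dropout)
        if (length(gone)) attend[i, at[-seq_len(min(gone))]] <- FALSE
      }
    }
  }
  idx <- which(attend, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pid <- idx[, 1]
  age <- spec$visit_ages[idx[, 2]]
  sex <- sexes[pid]
  cls <- paths[cbind(pid, match(age, spec$ages))]
  # thresholds by (sex, floored age): child rows from the cutoff table, 18+
  # the adult WHO values
  key <- paste(cutoffs$sex, cutoffs$age)
  row <- match(paste(sex, pmin(floor(age), 18)), c(key, "female 18", "male 18"))
  adult <- row > nrow(cutoffs)
  th_ow <- ifelse(adult, 25, cutoffs$ow[row])
  th_ob1 <- ifelse(adult, 30, cutoffs$ob1[row])
  th_ob2 <- ifelse(adult, 35, cutoffs$ob2[row])
  lo <- cbind(th_ow - 4, th_ow, th_ob1, th_ob2)[cbind(seq_along(cls),
                                                      class_rank(cls))]
  hi <- cbind(th_ow, th_ob1, th_ob2, th_ob2 + 6)[cbind(seq_along(cls),
                                                       class_rank(cls))]
  bmi <- lo + runif(length(cls)) * (hi - lo)
  h <- synthetic_height(age, sex)
  out <- data.frame(person_id = pid, sex = sex, age = age, height = h,
                    weight = bmi * h^2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "latent") <- latent
  out
}

#' Simulate a Gompertz–Makeham life table
#'
#' Annual mortality rates \eqn{m(age) = c + \lambda e^{\gamma \cdot age}} for
#' ages 0–100 and both sexes. The packaged default parameters were tuned (by
#' bisection on \eqn{\lambda} against the cohort engine) so the life-table
#' life expectancy at age 2 is about 83.5 years for women and 80.5 for men.
#'
#' @param makeham Age-independent background rate \eqn{c}.
#' @param lambda Named vector of Gompertz rate parameters per sex.
#' @param gamma Gompertz shape (log increase in mortality per year of age).
#' @return A life table data frame `sex,age,rate`.
#' @export
simulate_life_table <- function(makeham = 2e-4,
                                lambda = c(female = 1.68706e-5, male = 2.29822e-5),
                                gamma = 0.0955) {
  stopifnot(makeham >= 0, all(lambda >= 0), gamma >= 0)
  do.call(rbind, lapply(c("female", "male"), function(s)
    data.frame(sex = s, age = 0:100,
               rate = makeham + lambda[[s]] * exp(gamma * (0:100)))))
}

#' Simulate individual-level cost records from a two-part process
#'
#' Costs are Bernoulli(participation) x Gamma(mean, shape): a logistic
#' participation part and a log-linear gamma positive part, both with
#' weight-class and age effects, mirroring the two-part estimator they are
#' meant to exercise.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param participation Baseline participation probability for NW at age 50.
#' @param part_class_logit Named logit offsets per class (NW must be 0).
#' @param mean_cost Baseline mean positive cost (EUR) for NW at age 50.
#' @param cost_class_log Named log-scale offsets per class (NW must be 0).
#' @param age_slope_logit,age_slope_log Age effects per year (centred at 50).
#' @param shape Gamma shape of the positive part.
#' @param female_share Probability a record is female.
#' @return Data frame of cost records (`person_id`, `sex`, `age`,
#'   `weight_class`, `smoking`, `marital`, `annual_cost`).
#' @export
simulate_cost_records <- function(n, seed, participation = 0.7,
                                  part_class_logit = c(NW = 0, OW = 0.1,
                                                       OB1 = 0.3, OB2 = 0.4),
                                  mean_cost = 1500,
                                  cost_class_log = c(NW = 0, OW = 0.1,
                                                     OB1 = 0.35, OB2 = 0.4),
                                  age_slope_logit = 0.01, age_slope_log = 0.01,
                                  shape = 1.2, female_share = 0.5) {
  set.seed(seed)
  sex <- ifelse(runif(n) < female_share, "female", "male")
  age <- runif(n, 20, 80)
  cls <- sample(CLASSES, n, replace = TRUE, prob = c(0.45, 0.35, 0.13, 0.07))
  smoking <- sample(c("never", "previous", "daily", "occasional"), n,
                    replace = TRUE, prob = c(0.45, 0.3, 0.2, 0.05))
  marital <- sample(c("married/partner", "never married", "widowed",
                      "divorced/separated"), n, replace = TRUE,
                    prob = c(0.55, 0.25, 0.08, 0.12))
  eta1 <- qlogis(participation) + part_class_logit[cls] +
    age_slope_logit * (age - 50)
  use <- rbinom(n, 1, plogis(eta1))
  mu <- mean_cost * exp(cost_class_log[cls] + age_slope_log * (age - 50))
  cost <- use * rgamma(n, shape = shape, rate = shape / mu)
  data.frame(person_id = seq_len(n), sex = sex, age = age, weight_class = cls,
             smoking = smoking, marital = marital, annual_cost = cost,
             stringsAsFactors = FALSE)
}
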