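#' Read a life table
#'
#' Delimited text with header `sex,age,rate`: annual all-cause mortality rates
#' by sex and single year of age. Must cover ages 2–100 for both sexes with
#' non-negative rates. The packaged `life_table_synthetic.csv` is a synthetic
#' Gompertz–Makeham table for testing — substitute a national life table for
#' real analyses.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_life_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df)
}

validate_life_table <- function(df) {
  if (!all(c("sex", "age", "rate") %in% names(df))) {
    stop("life table needs columns sex,age,rate", call. = FALSE)
  }
  if (any(df$rate < 0)) stop("mortality rates must be non-negative", call. = FALSE)
  covered <- expand.grid(sex = c("female", "male"), age = 2:100)
  miss <- !paste(covered$sex, covered$age) %in% paste(df$sex, df$age)
  if (any(miss)) stop("life table must cover ages 2-100 for both sexes", call. = FALSE)
  df
}

#' Read a hazard-ratio table
#'
#' Delimited text with header `state,age_lo,age_hi,hr` (optional `hr_lo`,
#' `hr_hi` 95% CI bounds): mortality hazard ratios relative to normal weight,
#' by weight class and age band \[age_lo, age_hi). NW rows must carry HR 1 and
#' the bands must partition ages 2–100 without overlap for every class. The
#' packaged `hazard_ratios_synthetic.csv` is a plausible synthetic fixture,
#' not an authoritative estimate.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_hazard_ratios <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_hazard_ratios(df)
}

validate_hazard_ratios <- function(df) {
  if (!all(c("state", "age_lo", "age_hi", "hr") %in% names(df))) {
    stop("hazard-ratio table needs columns state,age_lo,age_hi,hr", call. = FALSE)
  }
  if (any(df$hr < 0)) stop("hazard ratios must be non-negative", call. = FALSE)
  if (any(df$hr[df$state == "NW"] != 1)) {
    stop("NW hazard ratios must equal 1 (reference class)", call. = FALSE)
  }
  for (cls in CLASSES) {
    d <- df[df$state == cls, ]
    d <- d[order(d$age_lo), ]
    if (nrow(d) == 0 || d$age_lo[1] > 2 || d$age_hi[nrow(d)] < 101 ||
        (nrow(d) > 1 && any(d$age_lo[-1] != d$age_hi[-nrow(d)]))) {
      stop("hazard-ratio bands for ", cls, " must partition ages 2-100",
           call. = FALSE)
    }
  }
  df
}

lookup_hr <- function(hrs, state, age) {
  cls <- if (state %in% c("NW1", "NW2")) "NW" else state
  d <- hrs[hrs$state == cls, ]
  i <- findInterval(age, d$age_lo)
  if (any(i == 0) || any(age >= d$age_hi[i])) {
    stop("no hazard-ratio band for ", cls, " at age ", age[1], call. = FALSE)
  }
  d$hr[i]
}

lookup_rate <- function(lifetable, sex, age) {
  i <- match(paste(sex, age), paste(lifetable$sex, lifetable$age))
  if (anyNA(i)) stop("life table missing sex '", sex, "' age ", age[is.na(i)][1],
                     call. = FALSE)
  lifetable$rate[i]
}

#' Annual death probability by state
#'
#' Converts the life-table mortality rate into a per-state annual death
#' probability by scaling the rate with the state's hazard ratio and applying
#' the rate-to-probability identity: \eqn{q = 1 - \exp(-m \cdot HR)}. Hazard
#' ratios act on rates, so scaling happens on the rate scale (never on the
#' probability scale, which could exceed 1). NW1 and NW2 share the NW hazard
#' ratio.
#'
#' @param lifetable Life table (see [read_life_table()]).
#' @param hrs Hazard-ratio table (see [read_hazard_ratios()]).
#' @param sex `"female"` or `"male"`.
#' @param age Age in years (vectorised).
#' @param state A live health state (`"NW1"`, `"NW2"`, `"OW"`, `"OB1"`, `"OB2"`).
#' @return Annual death probability in \[0, 1).
#' @export
death_probability <- function(lifetable, hrs, sex, age, state) {
  if (any(state == "DEAD")) stop("death probability undefined for DEAD", call. = FALSE)
  m <- lookup_rate(lifetable, sex, age)
  hr <- lookup_hr(hrs, state, age)
  1 - exp(-m * hr)
}
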