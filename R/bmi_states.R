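#' Compute body mass index
#'
#' @param height Height in metres (strictly positive).
#' @param weight Weight in kilograms (strictly positive).
#' @return BMI in kg/m^2. Vectorised.
#' @examples
#' compute_bmi(1.60, 51.2) # 20
#' @export
compute_bmi <- function(height, weight) {
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be finite and strictly positive", call. = FALSE)
  }
  weight / height^2
}

#' Classify an adult BMI into a weight class
#'
#' Adult WHO cutoffs: NW below 25, OW in \[25, 30), OB1 in \[30, 35), OB2 at 35
#' and above. Boundaries are lower-inclusive so that "35+" is OB2. The model
#' has no underweight state, so any BMI below 18 is NW.
#'
#' @param bmi BMI in kg/m^2 (strictly positive). Vectorised.
#' @return Character vector of weight-class labels (`"NW"`, `"OW"`, `"OB1"`, `"OB2"`).
#' @export
classify_adult <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and strictly positive", call. = FALSE)
  }
  classify_with_thresholds(bmi, ow = 25, ob1 = 30, ob2 = 35)
}

classify_with_thresholds <- function(bmi, ow, ob1, ob2) {
  CLASSES[1L + (bmi >= ow) + (bmi >= ob1) + (bmi >= ob2)]
}

#' Classify a child BMI into a weight class
#'
#' Children (ages 2–17) use age- and sex-specific BMI cutoffs in place of the
#' adult thresholds; for example a 2-year-old girl is OW from a BMI of 18.09
#' and OB2 from 21.13. Non-tabulated (fractional) ages use the row of the
#' floored tabulated age. Boundaries are lower-inclusive as in
#' [classify_adult()].
#'
#' @param bmi BMI in kg/m^2. Vectorised together with `age` and `sex`.
#' @param age Age in years, in \[2, 17\] (fractions allowed; floored to the
#'   tabulated age). Callers must route ages 18+ to [classify_adult()].
#' @param sex `"female"` or `"male"`.
#' @param cutoffs Cutoff table from [read_cutoff_table()] (columns
#'   `sex`, `age`, `ow`, `ob1`, `ob2`).
#' @return Character vector of weight-class labels.
#' @export
classify_child <- function(bmi, age, sex, cutoffs) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and strictly positive", call. = FALSE)
  }
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(age < 2 | age > 18)) {
    stop("classify_child applies to ages 2-17 (18 only via an adult-equivalent row)",
         call. = FALSE)
  }
  key <- paste(cutoffs$sex, cutoffs$age)
  idx <- match(paste(sex, floor(age)), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    stop(sprintf("no cutoff row for sex '%s' at age %d", sex[miss],
                 as.integer(floor(age[miss]))), call. = FALSE)
  }
  classify_with_thresholds(bmi, cutoffs$ow[idx], cutoffs$ob1[idx], cutoffs$ob2[idx])
}

#' Classify BMI using the age-appropriate rule
#'
#' Dispatches to [classify_child()] for ages below 18 and [classify_adult()]
#' otherwise.
#'
#' @inheritParams classify_child
#' @return Character vector of weight-class labels.
#' @export
classify_bmi <- function(bmi, age, sex, cutoffs) {
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  out <- character(n)
  child <- age < 18
  if (any(child)) out[child] <- classify_child(bmi[child], age[child], sex[child], cutoffs)
  if (any(!child)) out[!child] <- classify_adult(bmi[!child])
  out
}

#' Read a child BMI cutoff table
#'
#' Delimited text with header `sex,age,ow,ob1,ob2`; thresholds in kg/m^2. The
#' table must cover every integer age 2–17 for both sexes, with strictly
#' ordered thresholds `ow < ob1 < ob2` in every row.
#'
#' A synthetic reference table ships with the package (see
#' [bmicohort_example()]); users with access to the full published
#' international child cutoff table should substitute it — the values are
#' configuration, not code.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_cutoff_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cutoff_table(df)
}

validate_cutoff_table <- function(df) {
  need <- c("sex", "age", "ow", "ob1", "ob2")
  if (!all(need %in% names(df))) {
    stop("cutoff table must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  if (!all(df$sex %in% c("female", "male"))) {
    stop("cutoff table sex must be 'female' or 'male'", call. = FALSE)
  }
  if (any(df$ow <= 0) || any(df$ow >= df$ob1) || any(df$ob1 >= df$ob2)) {
    stop("cutoff thresholds must be positive and strictly ordered ow < ob1 < ob2",
         call. = FALSE)
  }
  covered <- expand.grid(sex = c("female", "male"), age = 2:17)
  miss <- !paste(covered$sex, covered$age) %in% paste(df$sex, df$age)
  if (any(miss)) {
    stop("cutoff table missing rows for: ",
         paste(paste(covered$sex, covered$age)[miss], collapse = "; "), call. = FALSE)
  }
  df
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
bmicohort_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "bmicohort"))
  } else {
    path <- system.file("extdata", file, package = "bmicohort")
    if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
    path
  }
}
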