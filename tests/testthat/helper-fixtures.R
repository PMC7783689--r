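# shared fixtures, built in code

pkg_cutoffs <- function() {
  read_cutoff_table(bmicohort_example("child_bmi_cutoffs_synthetic.csv"))
}

# a transition schedule with constant probabilities (named by transition;
# unnamed transitions default to 0)
flat_schedule <- function(..., ages = 2:99) {
  p <- list(...)
  tp <- lapply(c(female = "female", male = "male"), function(s) {
    m <- matrix(0, nrow = length(bmicohort:::TRANSITIONS), ncol = length(ages),
                dimnames = list(bmicohort:::TRANSITIONS, ages))
    for (tr in names(p)) m[tr, ] <- p[[tr]]
    m
  })
  structure(list(tp = tp, ages = ages, provenance = NULL),
            class = "transition_schedule")
}

# a life table with one flat annual rate for both sexes
flat_lifetable <- function(rate) {
  do.call(rbind, lapply(c("female", "male"), function(s)
    data.frame(sex = s, age = 0:100, rate = rate)))
}

# hazard-ratio table with one band 2-100 per class
flat_hrs <- function(ow = 1, ob1 = 1, ob2 = 1) {
  data.frame(state = c("NW", "OW", "OB1", "OB2"), age_lo = 2, age_hi = 101,
             hr = c(1, ow, ob1, ob2))
}

# hand-made cohort trace (rows = six states, cols = ages)
make_trace <- function(mat, ages, sex = "female", cohort_size = sum(mat[, 1])) {
  dimnames(mat) <- list(bmicohort:::STATES, ages)
  structure(mat, sex = sex, cohort_size = cohort_size, class = "cohort_trace")
}

# anthropometric record helper
rec <- function(id, sex, age, height, weight) {
  data.frame(person_id = id, sex = sex, age = age, height = height,
             weight = weight, stringsAsFactors = FALSE)
}

# annual state series helper
series <- function(id, sex, ages, classes) {
  data.frame(person_id = id, sex = sex, age = ages, class = classes,
             stringsAsFactors = FALSE)
}
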