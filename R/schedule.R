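#' Build an annual transition-probability schedule
#'
#' Splices fitted survival models from the three estimation bands into one
#' annual transition-probability schedule per sex and transition, covering
#' ages 2–99 (the transition out of age *a* governs the cycle from *a* to
#' *a + 1*). Ages 2–12 use the child fit, 13–19 the adolescent fit and 20+
#' the adult fit; within each band the survival clock starts at the band entry
#' age (2, 13, 20). Probabilities are clipped to \[0, 1\]; transitions without
#' a direct arrow in the model structure are structural zeros handled by the
#' Markov engine, not by the schedule.
#'
#' @param models Nested list `models[[sex]][[transition]][[band]]` of
#'   [parametric_model()] objects; sexes `female`/`male`, transitions as in
#'   `TRANSITIONS` (`"NW-OW"`, `"OW-OB1"`, `"OB1-OB2"`, `"OB2-OB1"`,
#'   `"OB1-OW"`, `"OW-NW"`), bands `child`/`adolescent`/`adult`.
#' @param ages Integer ages the schedule covers (default 2:99).
#' @param bands Band definition table (see [estimation_bands()]); override the
#'   `entry` column to use a different survival-clock convention (e.g. a
#'   common origin at age 2 for all bands).
#' @return A `transition_schedule`: list with per-sex probability matrices
#'   (`tp`, rows = transitions, columns = ages) and a provenance table.
#' @export
build_schedule <- function(models, ages = 2:99, bands = estimation_bands()) {
  tp <- list()
  prov <- list()
  for (s in c("female", "male")) {
    mat <- matrix(NA_real_, nrow = length(TRANSITIONS), ncol = length(ages),
                  dimnames = list(TRANSITIONS, ages))
    for (tr in TRANSITIONS) {
      for (i in seq_len(nrow(bands))) {
        b <- bands$band[i]
        in_band <- ages >= bands$lo[i] & ages <= bands$hi[i]
        if (!any(in_band)) next
        m <- models[[s]][[tr]][[b]]
        if (is.null(m)) {
          stop(sprintf("missing model for sex '%s', transition '%s', band '%s'",
                       s, tr, b), call. = FALSE)
        }
        mat[tr, in_band] <- yearly_tp(m, bands$entry[i], ages[in_band])
        prov[[length(prov) + 1L]] <- data.frame(
          sex = s, transition = tr, band = b, family = m$family,
          params = paste(signif(m$params, 6), collapse = ";"),
          age_lo = min(ages[in_band]), age_hi = max(ages[in_band]))
      }
    }
    if (anyNA(mat)) stop("schedule has uncovered ages", call. = FALSE)
    tp[[s]] <- mat
  }
  structure(list(tp = tp, ages = ages, provenance = do.call(rbind, prov)),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("<transition_schedule> %d transitions x ages %d-%d, sexes: %s\n",
              nrow(x$tp[[1]]), min(x$ages), max(x$ages),
              paste(names(x$tp), collapse = ", ")))
  invisible(x)
}

#' Look up annual transition probabilities
#'
#' @param schedule A [build_schedule()] result.
#' @param sex `"female"` or `"male"`.
#' @param age Integer age (scalar) within the schedule's range.
#' @return Named numeric vector of the six transition probabilities at `age`.
#' @export
schedule_at <- function(schedule, sex, age) {
  j <- match(age, schedule$ages)
  if (is.na(j)) stop("age ", age, " not covered by schedule", call. = FALSE)
  schedule$tp[[sex]][, j]
}

#' Export / import a transition schedule as delimited text
#'
#' Long format with header `sex,transition,age,probability`.
#'
#' @param schedule A `transition_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   a `transition_schedule` (without provenance).
#' @export
write_schedule <- function(schedule, path) {
  rows <- do.call(rbind, lapply(names(schedule$tp), function(s) {
    m <- schedule$tp[[s]]
    data.frame(sex = s,
               transition = rep(rownames(m), times = ncol(m)),
               age = rep(schedule$ages, each = nrow(m)),
               probability = as.vector(m))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ages <- sort(unique(df$age))
  tp <- lapply(split(df, df$sex), function(d) {
    m <- matrix(NA_real_, nrow = length(TRANSITIONS), ncol = length(ages),
                dimnames = list(TRANSITIONS, ages))
    m[cbind(match(d$transition, TRANSITIONS), match(d$age, ages))] <- d$probability
    if (anyNA(m)) stop("incomplete schedule file", call. = FALSE)
    m
  })
  structure(list(tp = tp, ages = ages, provenance = NULL),
            class = "transition_schedule")
}

#' Build transition models from a parameter table
#'
#' Reads a delimited parameter table (columns `sex`, `transition`, `band`,
#' `family`, `p1`, `p2`, `p3`; `p3` empty except for the generalized gamma)
#' into the nested model list consumed by [build_schedule()]. The packaged
#' default table carries the published point estimates of the fitted survival
#' models per sex, transition and estimation band.
#'
#' @param path Path to the CSV (default: the packaged table).
#' @return Nested list `models[[sex]][[transition]][[band]]`.
#' @export
transition_models_from_table <- function(path = bmicohort_example("transition_model_parameters.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "transition", "band", "family", "p1", "p2")
  if (!all(need %in% names(df))) {
    stop("parameter table needs columns ", paste(need, collapse = ","), call. = FALSE)
  }
  models <- list(female = list(), male = list())
  for (i in seq_len(nrow(df))) {
    p <- c(df$p1[i], df$p2[i], if ("p3" %in% names(df)) df$p3[i] else NA)
    p <- p[!is.na(p)][seq_len(n_params(df$family[i]))]
    models[[df$sex[i]]][[df$transition[i]]][[df$band[i]]] <-
      parametric_model(df$family[i], p)
  }
  models
}

#' Serialize fitted models to structured text
#'
#' One row per (sex, transition, band): family, parameters, and the
#' flattened covariance (if present).
#'
#' @param models Nested model list (see [build_schedule()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  rows <- list()
  for (s in names(models)) for (tr in names(models[[s]]))
    for (b in names(models[[s]][[tr]])) {
      m <- models[[s]][[tr]][[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, transition = tr, band = b, family = m$family,
        params = paste(signif(m$params, 10), collapse = ";"),
        vcov = if (is.null(m$vcov)) "" else
          paste(signif(as.vector(m$vcov), 10), collapse = ";"))
    }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
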