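#' Interpolate sparse anthropometric records to an annual grid
#'
#' Survey records arrive with large, irregular gaps (roughly annual in
#' childhood, 4–11 years in adolescence and adulthood). Weight is interpolated
#' linearly between adjacent measurements at every integer age between a
#' person's first and last observation. Height is interpolated linearly while
#' below the plateau age (default 18); when a measurement pair straddles the
#' plateau age, height rises linearly to the later measured height at exactly
#' the plateau age and is constant thereafter. Persons with fewer than two
#' records are excluded; the count is reported via a message and the
#' `n_excluded` attribute.
#'
#' @param records Data frame with columns `person_id`, `sex`, `age`, `height`
#'   (metres), `weight` (kilograms).
#' @param height_plateau_age Age at which height growth stops (years).
#' @return Data frame of annual records (`person_id`, `sex`, `age`, `height`,
#'   `weight`) with one row per integer age per person.
#' @export
interpolate_series <- function(records, height_plateau_age = 18) {
  need <- c("person_id", "sex", "age", "height", "weight")
  if (!all(need %in% names(records))) {
    stop("records need columns ", paste(need, collapse = ","), call. = FALSE)
  }
  if (any(records$height <= 0) || any(records$weight <= 0) || any(records$age < 0)) {
    stop("height/weight must be positive and age non-negative", call. = FALSE)
  }
  split_rec <- split(records, records$person_id)
  n_obs <- vapply(split_rec, nrow, integer(1))
  n_excluded <- sum(n_obs < 2)
  if (n_excluded > 0) {
    message(n_excluded, " person(s) with a single observation excluded")
  }
  out <- lapply(split_rec[n_obs >= 2], function(d) {
    d <- d[order(d$age), ]
    d <- d[!duplicated(d$age), ]
    if (nrow(d) < 2) return(NULL)
    ages <- seq(ceiling(min(d$age)), floor(max(d$age)))
    if (length(ages) == 0) return(NULL)
    w <- approx(d$age, d$weight, xout = ages, rule = 2)$y
    # height: measurement ages clamped to the plateau age, first value kept on
    # ties, constant beyond the plateau
    ma <- pmin(d$age, height_plateau_age)
    keep <- !duplicated(ma)
    h <- if (sum(keep) == 1) rep(d$height[keep][1], length(ages)) else
      approx(ma[keep], d$height[keep], xout = pmin(ages, height_plateau_age),
             rule = 2)$y
    data.frame(person_id = d$person_id[1], sex = d$sex[1], age = ages,
               height = h, weight = w, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Classify annual records into weight classes
#'
#' Maps every interpolated annual record through [compute_bmi()] and the
#' age-appropriate classification rule (child cutoffs through age 17, adult
#' WHO cutoffs from 18).
#'
#' @param annual Annual records from [interpolate_series()].
#' @param cutoffs Child cutoff table (see [read_cutoff_table()]).
#' @return Data frame `person_id`, `sex`, `age`, `bmi`, `class` — an annual
#'   weight-class series per person with consecutive ages.
#' @export
annualize_states <- function(annual, cutoffs) {
  bmi <- compute_bmi(annual$height, annual$weight)
  cls <- tryCatch(classify_bmi(bmi, annual$age, annual$sex, cutoffs),
                  error = function(e) {
                    stop("classification failed (", conditionMessage(e), ")",
                         call. = FALSE)
                  })
  data.frame(person_id = annual$person_id, sex = annual$sex, age = annual$age,
             bmi = bmi, class = cls, stringsAsFactors = FALSE)
}

# ordinal coding of weight classes for jump decomposition
class_rank <- function(cls) match(cls, CLASSES)

#' Restructure an annual state series into survival spells
#'
#' For one of the six transition analyses, opens a spell at the first age a
#' person is observed in the origin class (delayed entry on the common age
#' clock), and closes it with an event at the first subsequent age in the
#' destination class, or with censoring at the last observed age or when the
#' person exits to a non-destination class (cause-specific censoring).
#' Re-entry into the origin class opens a new spell. A jump of two or more
#' classes between consecutive ages is decomposed into one-class moves: it
#' counts as an event if it passes through the destination, and the number of
#' such jumps is reported in the `n_two_class_jumps` attribute. Spells are
#' split at the estimation-band boundaries (ages 13 and 20); the earlier part
#' is censored at the boundary and the later part re-enters the next band with
#' delayed entry — a likelihood-neutral decomposition.
#'
#' @param series Annual state series (`person_id`, `sex`, `age`, `class`)
#'   from [annualize_states()].
#' @param analysis_id Analysis number 1–6 (1 NW→OW, 2 OW→OB1, 3 OB1→OB2,
#'   4 OB2→OB1, 5 OB1→OW, 6 OW→NW).
#' @param split_bands Split spells at the band boundaries (default TRUE).
#' @return Data frame `person_id`, `sex`, `analysis`, `band`, `entry`, `exit`,
#'   `event` (logical). Empty output (zero rows) is valid.
#' @export
build_survival_records <- function(series, analysis_id, split_bands = TRUE) {
  stopifnot(analysis_id %in% 1:6)
  origin <- transition_origin(analysis_id)
  dest <- transition_destination(analysis_id)
  progression <- class_rank(dest) > class_rank(origin)
  jumps <- 0L
  spells <- list()
  for (d in split(series, series$person_id)) {
    d <- d[order(d$age), ]
    r <- class_rank(d$class)
    o <- class_rank(origin)
    i <- 1L
    n <- nrow(d)
    while (i <= n) {
      # find spell opening
      while (i <= n && r[i] != o) i <- i + 1L
      if (i > n) break
      entry <- d$age[i]
      j <- i + 1L
      status <- NA  # NA = still open
      while (j <= n) {
        if (r[j] == o) { j <- j + 1L; next }
        if (abs(r[j] - o) >= 2) jumps <- jumps + 1L
        status <- if (progression) r[j] > o else r[j] < o
        break
      }
      if (j > n) { exit <- d$age[n]; status <- FALSE } else exit <- d$age[j]
      if (exit > entry) {
        spells[[length(spells) + 1L]] <- data.frame(
          person_id = d$person_id[1], sex = d$sex[1], analysis = analysis_id,
          entry = entry, exit = exit, event = isTRUE(status),
          stringsAsFactors = FALSE)
      }
      i <- j  # resume scan at the closing age (re-entry needs a later O age)
    }
  }
  out <- if (length(spells)) do.call(rbind, spells) else
    data.frame(person_id = character(), sex = character(), analysis = integer(),
               entry = numeric(), exit = numeric(), event = logical())
  if (split_bands && nrow(out)) out <- split_spells_at_bands(out)
  out$band <- band_for_age(out$entry)
  rownames(out) <- NULL
  attr(out, "n_two_class_jumps") <- jumps
  out
}

# split spells at the estimation-band boundaries; earlier parts censored at the
# boundary, later parts delayed-entry into the next band
split_spells_at_bands <- function(spells) {
  boundaries <- estimation_bands()$entry[-1]  # 13, 20
  rows <- lapply(seq_len(nrow(spells)), function(i) {
    sp <- spells[i, ]
    cuts <- boundaries[boundaries > sp$entry & boundaries < sp$exit]
    if (length(cuts) == 0) return(sp)
    lo <- c(sp$entry, cuts)
    hi <- c(cuts, sp$exit)
    part <- sp[rep(1, length(lo)), ]
    part$entry <- lo
    part$exit <- hi
    part$event <- c(rep(FALSE, length(lo) - 1), sp$event)
    part
  })
  do.call(rbind, rows)
}

#' Full record-preparation pipeline
#'
#' Interpolates raw anthropometric records, classifies them annually, and
#' builds survival records for all six transition analyses.
#'
#' @inheritParams interpolate_series
#' @param cutoffs Child cutoff table.
#' @param analyses Analysis ids to build (default all six).
#' @return Data frame of survival records across analyses (columns
#'   `person_id`, `sex`, `analysis`, `band`, `entry`, `exit`, `event`).
#' @export
prepare_survival_records <- function(records, cutoffs, analyses = 1:6,
                                     height_plateau_age = 18) {
  annual <- interpolate_series(records, height_plateau_age)
  series <- annualize_states(annual, cutoffs)
  out <- do.call(rbind, lapply(analyses, function(a)
    build_survival_records(series, a)))
  rownames(out) <- NULL
  out
}
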