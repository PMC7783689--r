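#' Left-truncated survival log-likelihood
#'
#' Log-likelihood of left-truncated, right-censored time-to-event records under
#' a parametric model. Records carry entry and exit on the common age clock;
#' both are shifted to the analysis clock (`t = age - band_entry_age`). Each
#' record contributes `log f(t_exit)` if it ends in an event and
#' `log S(t_exit)` if censored, minus `log S(t_entry)` — the delayed-entry
#' (left-truncation) correction: individuals enter the risk set only when the
#' model reaches their age.
#'
#' With `interval = TRUE` an event observed at exit age *a* is treated as
#' having occurred somewhere in the preceding one-year cycle `(a - 1, a]` and
#' contributes `log(S(t - 1) - S(t))` instead of the density. This is the
#' appropriate form for series observed (or interpolated) on an annual grid,
#' where exact event times are unknown; the density form is exact for
#' continuously observed times.
#'
#' @param model A [parametric_model()].
#' @param records Data frame with columns `entry`, `exit` (ages, years) and
#'   `event` (logical, or 0/1).
#' @param band_entry_age Clock origin age of the estimation band.
#' @param interval Use the interval-censored event contribution (see above).
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(model, records, band_entry_age, interval = FALSE) {
  rec <- validate_survival_records(records)
  t_entry <- rec$entry - band_entry_age
  t_exit <- rec$exit - band_entry_age
  if (any(t_entry < 0)) stop("entry before band entry age", call. = FALSE)
  tiny <- .Machine$double.xmin
  ll <- if (interval) {
    s_exit <- survival_function(model, t_exit)
    s_prev <- survival_function(model, pmax(t_exit - 1, 0))
    ifelse(rec$event, log(pmax(s_prev - s_exit, tiny)), log(pmax(s_exit, tiny)))
  } else {
    ifelse(rec$event, log_density(model, t_exit),
           log(pmax(survival_function(model, t_exit), tiny)))
  }
  trunc <- log(pmax(survival_function(model, t_entry), tiny))
  sum(ll) - sum(trunc)
}

validate_survival_records <- function(records) {
  need <- c("entry", "exit", "event")
  if (!all(need %in% names(records))) {
    stop("records need columns entry, exit, event", call. = FALSE)
  }
  ev <- records$event
  if (is.character(ev)) ev <- ev == "event"
  ev <- as.logical(ev)
  if (anyNA(ev)) stop("event must be logical, 0/1 or 'event'/'censored'", call. = FALSE)
  if (any(records$exit <= records$entry)) {
    stop("every record must have exit > entry", call. = FALSE)
  }
  data.frame(entry = as.numeric(records$entry), exit = as.numeric(records$exit),
             event = ev)
}

# unconstrained <-> natural parameter transforms used by the optimizer
to_natural <- function(family, theta) {
  switch(family,
    exponential = exp(theta[1]),
    weibull     = c(theta[1], exp(theta[2])),
    lognormal   = c(theta[1], exp(theta[2])),
    loglogistic = c(theta[1], exp(theta[2])),
    gompertz    = c(theta[1], exp(theta[2])),
    gengamma    = c(theta[1], exp(theta[2]), theta[3]))
}

to_unconstrained <- function(family, p) {
  switch(family,
    exponential = log(p[1]),
    weibull     = c(p[1], log(p[2])),
    lognormal   = c(p[1], log(p[2])),
    loglogistic = c(p[1], log(p[2])),
    gompertz    = c(p[1], log(p[2])),
    gengamma    = c(p[1], log(p[2]), p[3]))
}

# jacobian d(natural)/d(unconstrained), evaluated at theta — diagonal for all
# families used here
natural_jacobian <- function(family, theta) {
  p <- to_natural(family, theta)
  d <- switch(family,
    exponential = p[1],
    weibull     = c(1, p[2]),
    lognormal   = c(1, p[2]),
    loglogistic = c(1, p[2]),
    gompertz    = c(1, p[2]),
    gengamma    = c(1, p[2], 1))
  diag(d, nrow = length(d))
}

# moment-based starting values on the unconstrained scale, plus fixed
# deterministic perturbations for the multi-start search
start_values <- function(family, rec, band_entry_age) {
  t_exit <- rec$exit - band_entry_age
  te <- t_exit[rec$event]
  exposure <- sum(t_exit - (rec$entry - band_entry_age))
  rate <- max(sum(rec$event) / max(exposure, 1e-9), 1e-6)
  m <- mean(log(te)); s <- sd(log(te))
  if (!is.finite(s) || s < 1e-3) s <- 1
  base <- switch(family,
    exponential = log(rate),
    weibull     = {  # median-matching: exp(b0) med^p = log 2
      p0 <- min(max(1.2 / s, 0.3), 5)
      c(log(log(2)) - p0 * m, log(p0))
    },
    lognormal   = c(m, log(s)),
    loglogistic = c(m, log(s * sqrt(3) / pi)),
    gompertz    = c(0, log(rate)),
    gengamma    = c(m, log(s), 0.5))
  jitters <- switch(family,
    exponential = list(0, 1, -1),
    gengamma    = list(c(0, 0, 0), c(0, 0, -1), c(0.5, 0.3, 0.5), c(-0.5, -0.3, 1)),
    list(c(0, 0), c(0.5, 0.3), c(-0.5, -0.3)))
  lapply(jitters, function(j) base + j)
}

#' Fit a parametric survival family by maximum likelihood
#'
#' Maximizes [log_likelihood()] over the family's parameters using a
#' deterministic multi-start quasi-Newton search from moment-based starting
#' values. The covariance of the estimates is the inverse observed information
#' at the optimum, mapped to the natural parameter scale by the delta method.
#'
#' @param records Data frame of survival records (`entry`, `exit`, `event`).
#' @param family Survival family name (see [parametric_model()]).
#' @param band_entry_age Clock origin age of the estimation band.
#' @param interval Treat event times as interval-censored to the annual grid
#'   (see [log_likelihood()]); use for annually interpolated series.
#' @return A `fit_result`: list with elements `model` ([parametric_model()]
#'   with covariance), `loglik`, `aic`, `bic`, `n_records`, `n_events`,
#'   `converged`.
#' @export
fit_parametric <- function(records, family, band_entry_age,
                           interval = FALSE) {
  family <- match.arg(family, SURV_FAMILIES)
  rec <- validate_survival_records(records)
  if (sum(rec$event) == 0) {
    stop("cannot fit a survival model to records with zero events", call. = FALSE)
  }
  negll <- function(theta) {
    p <- to_natural(family, theta)
    ok <- tryCatch({ check_param_domain(family, p); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(1e10)
    v <- tryCatch(suppressWarnings(
      -log_likelihood(parametric_model(family, p), rec,
                      band_entry_age, interval = interval)),
      error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (theta0 in start_values(family, rec, band_entry_age)) {
    opt <- tryCatch(
      if (length(theta0) == 1) {
        optim(theta0, negll, method = "Brent",
              lower = theta0 - 15, upper = theta0 + 15)
      } else {
        optim(theta0, negll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (is.null(opt)) next
    opt2 <- tryCatch(
      optim(opt$par, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) opt)
    cand <- if (!is.null(opt2) && opt2$value <= opt$value) opt2 else opt
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || best$value >= 1e10) {
    stop(sprintf("fit of family '%s' did not converge", family), call. = FALSE)
  }
  theta <- best$par
  vcov <- tryCatch({
    H <- optimHess(theta, negll)
    J <- natural_jacobian(family, theta)
    V <- J %*% solve(H) %*% t(J)
    if (any(!is.finite(V)) || any(diag(V) < 0)) NULL else V
  }, error = function(e) NULL)
  model <- parametric_model(family, to_natural(family, theta), vcov = vcov)
  ll <- -best$value
  k <- n_params(family)
  n <- nrow(rec)
  structure(list(model = model, loglik = ll,
                 aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
                 n_records = n, n_events = sum(rec$event),
                 converged = TRUE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s(%s)  loglik %.3f  AIC %.2f  BIC %.2f  (%d records, %d events)\n",
              x$model$family, paste(signif(x$model$params, 5), collapse = ", "),
              x$loglik, x$aic, x$bic, x$n_records, x$n_events))
  invisible(x)
}

#' Fit all six survival families to one set of records
#'
#' @inheritParams fit_parametric
#' @param families Families to attempt (default: all six).
#' @return Named list of `fit_result` objects; families that fail to converge
#'   are dropped with a message.
#' @export
fit_all_families <- function(records, band_entry_age, families = SURV_FAMILIES,
                             interval = FALSE) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parametric(records, fam, band_entry_age, interval = interval),
                  error = function(e) { message("family ", fam, " failed: ",
                                                conditionMessage(e)); NULL })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) == 0) stop("all families failed to converge", call. = FALSE)
  fits
}

#' Select a survival family by information criterion
#'
#' Picks the fit with the minimal AIC or BIC; ties are broken by fewer
#' parameters, then by the fixed family order (exponential, weibull,
#' lognormal, loglogistic, gompertz, gengamma).
#'
#' @param fits List of `fit_result` objects (e.g. from [fit_all_families()]).
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `fit_result`.
#' @export
select_family <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged fits to select from", call. = FALSE)
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  k <- vapply(fits, function(f) n_params(f$model$family), integer(1))
  ord <- match(vapply(fits, function(f) f$model$family, character(1)), SURV_FAMILIES)
  fits[[order(crit, k, ord)[1L]]]
}

#' Estimate transition models for every analysis, band and sex
#'
#' Runs the full estimation pipeline on restructured survival records: for
#' each of the six transitions and each estimation band, the survival family
#' is selected by information criterion on the pooled (both-sex) records, and
#' that family is then refitted separately for women and men — mirroring the
#' convention that model selection uses the whole cohort while parameters are
#' sex-specific.
#'
#' @param records Data frame of survival records with columns `sex`,
#'   `analysis` (1–6), `band`, `entry`, `exit`, `event`.
#' @param criterion Information criterion for family selection (`"aic"`/`"bic"`).
#' @param families Families to consider.
#' @param interval Treat event times as interval-censored to the annual grid
#'   (default TRUE: the records come from annually interpolated series).
#' @return Nested list `models[[sex]][[transition]][[band]]` of
#'   [parametric_model()] objects, usable by [build_schedule()].
#' @export
estimate_transition_models <- function(records, criterion = "aic",
                                       families = SURV_FAMILIES,
                                       interval = TRUE) {
  bands <- estimation_bands()
  models <- list(female = list(), male = list())
  for (a in sort(unique(records$analysis))) {
    trans <- TRANSITIONS[a]
    for (b in unique(records$band[records$analysis == a])) {
      entry <- bands$entry[bands$band == b]
      sub <- records[records$analysis == a & records$band == b, ]
      if (sum(sub$event %in% c(TRUE, 1, "event")) == 0) next
      pooled <- select_family(fit_all_families(sub, entry, families,
                                               interval = interval), criterion)
      fam <- pooled$model$family
      for (s in c("female", "male")) {
        ssub <- sub[sub$sex == s, ]
        fit <- tryCatch(fit_parametric(ssub, fam, entry, interval = interval),
                        error = function(e) NULL)
        if (is.null(fit)) next
        models[[s]][[trans]][[b]] <- fit$model
      }
    }
  }
  models
}
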