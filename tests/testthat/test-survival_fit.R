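test_that("log-likelihood matches closed forms for the exponential", {
  lam <- 0.3
  m <- parametric_model("exponential", lam)
  one_event <- data.frame(entry = 0, exit = 1, event = TRUE)
  expect_equal(log_likelihood(m, one_event, 0), log(lam) - lam)
  # left truncation cancels to pure exposure for a censored record
  censored <- data.frame(entry = 2, exit = 5, event = FALSE)
  expect_equal(log_likelihood(m, censored, 0), -3 * lam)
  expect_error(log_likelihood(m, data.frame(entry = 2, exit = 2, event = TRUE), 0),
               "exit > entry")
})

test_that("log-likelihood agrees with a quadrature oracle on a log-normal fixture", {
  set.seed(11)
  m <- parametric_model("lognormal", c(2.2, 0.9))
  n <- 100
  entry <- runif(n, 0, 2)
  exit <- entry + rexp(n, 0.5) + 0.01
  ev <- runif(n) < 0.5
  rec <- data.frame(entry = entry, exit = exit, event = ev)
  # oracle: survival by numerical integration of the closed-form density,
  # density by dlnorm — assembled independently of the package's S(t)
  S_num <- function(t) vapply(t, function(tt)
    1 - integrate(dlnorm, 0, tt, meanlog = 2.2, sdlog = 0.9,
                  rel.tol = 1e-12)$value, numeric(1))
  oracle <- sum(ifelse(ev, dlnorm(exit, 2.2, 0.9, log = TRUE),
                       log(S_num(exit)))) - sum(log(S_num(entry)))
  expect_equal(log_likelihood(m, rec, 0), oracle, tolerance = 1e-8)
})

test_that("fitted exponential equals the events-over-exposure closed form", {
  set.seed(3)
  n <- 400
  t <- rexp(n, 0.25)
  exit <- pmin(t, 4)
  rec <- data.frame(entry = 0, exit = exit, event = t <= 4)
  fit <- fit_parametric(rec, "exponential", 0)
  expect_equal(fit$model$params, sum(rec$event) / sum(rec$exit),
               tolerance = 1e-5)
  expect_equal(fit$n_events, sum(rec$event))
})

test_that("information-criterion arithmetic holds exactly", {
  set.seed(4)
  t <- rexp(300, 0.2)
  rec <- data.frame(entry = 0, exit = pmin(t, 6), event = t <= 6)
  for (fam in c("exponential", "weibull", "lognormal")) {
    fit <- fit_parametric(rec, fam, 0)
    k <- length(fit$model$params)
    expect_identical(fit$aic, -2 * fit$loglik + 2 * k)
    expect_identical(fit$bic, -2 * fit$loglik + k * log(fit$n_records))
  }
})

test_that("degenerate records are rejected", {
  rec <- data.frame(entry = 0, exit = 1:5, event = FALSE)
  expect_error(fit_parametric(rec, "lognormal", 0), "zero events")
})

test_that("left-truncated fits agree with an independent survival fitter", {
  set.seed(9)
  n <- 2000
  t <- rlnorm(n, meanlog = 2.0, sdlog = 0.8)
  entry <- runif(n, 0, 3)
  keep <- t > entry  # left truncation: only those surviving to entry observed
  exit <- pmin(t[keep], 15)
  rec <- data.frame(entry = entry[keep], exit = exit, event = t[keep] <= 15)
  fit <- fit_parametric(rec, "lognormal", 0)
  ref <- flexsurv::flexsurvreg(
    survival::Surv(rec$entry, rec$exit, rec$event) ~ 1, dist = "lnorm")
  expect_equal(fit$model$params, unname(ref$res[, "est"]), tolerance = 1e-4)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  # covariance from the observed information is close to the reference's
  expect_equal(sqrt(diag(fit$model$vcov)), unname(ref$res[, "se"]),
               tolerance = 0.02)
})

test_that("family selection minimizes the criterion with deterministic tie-breaks", {
  mk <- function(fam, ll, n) {
    structure(list(model = parametric_model(fam, switch(fam,
                     exponential = 0.1, weibull = c(0, 1), lognormal = c(0, 1))),
                   loglik = ll, aic = -2 * ll + 2 * n_par(fam),
                   bic = -2 * ll + n_par(fam) * log(n),
                   n_records = n, n_events = n, converged = TRUE),
              class = "fit_result")
  }
  n_par <- function(fam) if (fam == "exponential") 1L else 2L
  fits <- list(mk("exponential", -50, 100), mk("weibull", -48, 100),
               mk("lognormal", -51.5, 100))
  expect_equal(select_family(fits, "aic")$model$family, "weibull")
  # equal AIC: the fit with fewer parameters wins
  tie <- list(mk("weibull", -49, 100), mk("exponential", -50, 100))
  expect_equal(select_family(tie, "aic")$model$family, "exponential")
  # non-converged fits are excluded
  bad <- fits
  bad[[2]]$converged <- FALSE
  expect_equal(select_family(bad, "aic")$model$family, "exponential")
  expect_error(select_family(list(), "aic"), "no converged")
})

test_that("interval-censored likelihood treats annual events as cycle-censored", {
  m <- parametric_model("exponential", 0.2)
  rec <- data.frame(entry = 0, exit = 3, event = TRUE)
  expect_equal(log_likelihood(m, rec, 0, interval = TRUE),
               log(exp(-0.2 * 2) - exp(-0.2 * 3)))
  # censored contributions are identical under both forms
  cen <- data.frame(entry = 1, exit = 4, event = FALSE)
  expect_equal(log_likelihood(m, cen, 0, interval = TRUE),
               log_likelihood(m, cen, 0))
})

test_that("the estimation pipeline refits the pooled-selected family per sex", {
  set.seed(21)
  # two sexes with different exponential rates; pooled selection, per-sex fits
  mkrec <- function(sex, rate, n) {
    t <- rexp(n, rate)
    data.frame(person_id = seq_len(n), sex = sex, analysis = 1L,
               band = "adult", entry = 20, exit = 20 + pmin(t, 10),
               event = t <= 10)
  }
  rec <- rbind(mkrec("female", 0.10, 800), mkrec("male", 0.16, 800))
  rec <- rec[rec$exit > rec$entry, ]
  models <- suppressMessages(
    estimate_transition_models(rec, families = c("exponential", "weibull"),
                               interval = FALSE))
  f <- models$female[["NW-OW"]]$adult
  m <- models$male[["NW-OW"]]$adult
  expect_equal(f$family, m$family)  # same family for both sexes
  if (f$family == "exponential") {
    expect_gt(m$params[1], f$params[1])
  }
})
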