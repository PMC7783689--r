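#' Parameter-uncertainty specification for the PSA
#'
#' Builds the uncertainty blocks sampled by the probabilistic sensitivity
#' analysis:
#'
#' * survival blocks — one per (sex, transition, band): a mean vector and
#'   covariance over the survival coefficients on the unconstrained
#'   (log-scale for positivity-bounded) parameterization, sampled with a
#'   Cholesky factor of the covariance;
#' * hazard-ratio blocks — one per (state, age band): log-normal, located at
#'   the point estimate with the log-scale spread from the 95% CI when given;
#' * cost blocks — one per (sex, state): gamma with the point estimate as
#'   mean; negative increments are drawn as a sign-preserving negated gamma
#'   around the absolute mean (the gamma is defined on positives only).
#'
#' Fitted covariances travel with the models when available; otherwise a
#' synthetic covariance with relative standard error `rel_se` and no
#' correlation is used (published covariance matrices are replaceable inputs,
#' not package constants).
#'
#' @param models Nested model list (see [build_schedule()]).
#' @param hrs Hazard-ratio table; rows with `hr_lo`/`hr_hi` columns use them.
#' @param cost_points Data frame `sex,state,cost` of incremental cost point
#'   estimates.
#' @param rel_se Relative standard error for synthetic survival covariances.
#' @param hr_rel_se Log-scale standard error for HR blocks lacking a CI.
#' @param cost_rel_se Relative standard error of cost blocks.
#' @return A `parameter_uncertainty` list of blocks.
#' @export
make_uncertainty <- function(models, hrs, cost_points, rel_se = 0.05,
                             hr_rel_se = 0.1, cost_rel_se = 0.15) {
  blocks <- list()
  for (s in names(models)) for (tr in names(models[[s]]))
    for (b in names(models[[s]][[tr]])) {
      m <- models[[s]][[tr]][[b]]
      theta <- to_unconstrained(m$family, m$params)
      V <- if (!is.null(m$vcov)) {
        J <- solve(natural_jacobian(m$family, theta))
        J %*% m$vcov %*% t(J)  # map natural-scale vcov to theta scale
      } else {
        diag((rel_se * pmax(abs(theta), 0.1))^2, nrow = length(theta))
      }
      blocks[[paste("surv", s, tr, b, sep = "|")]] <-
        list(type = "survival", sex = s, transition = tr, band = b,
             family = m$family, mean = theta, vcov = V)
    }
  for (i in seq_len(nrow(hrs))) {
    if (hrs$state[i] == "NW") next  # reference class stays at 1
    has_ci <- all(c("hr_lo", "hr_hi") %in% names(hrs)) &&
      is.finite(hrs$hr_lo[i]) && is.finite(hrs$hr_hi[i]) && hrs$hr_lo[i] > 0
    sdlog <- if (has_ci) (log(hrs$hr_hi[i]) - log(hrs$hr_lo[i])) / (2 * qnorm(0.975))
             else hr_rel_se
    blocks[[paste("hr", hrs$state[i], hrs$age_lo[i], sep = "|")]] <-
      list(type = "hr", row = i, meanlog = log(hrs$hr[i]), sdlog = sdlog)
  }
  for (i in seq_len(nrow(cost_points))) {
    if (cost_points$state[i] == "NW" || cost_points$cost[i] == 0) next
    mu <- abs(cost_points$cost[i])
    v <- (cost_rel_se * mu)^2
    blocks[[paste("cost", cost_points$sex[i], cost_points$state[i], sep = "|")]] <-
      list(type = "cost", row = i, sign = sign(cost_points$cost[i]),
           shape = mu^2 / v, rate = mu / v)
  }
  structure(list(blocks = blocks, hrs = hrs, cost_points = cost_points),
            class = "parameter_uncertainty")
}

# deterministic 32-bit string hash, for per-block substreams: adding a block
# must not perturb the draws of other blocks
block_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483563
  as.integer((seed + h) %% 2147483563)
}

draw_mvn <- function(mean, vcov, name) {
  if (max(abs(vcov)) == 0) return(mean)
  L <- tryCatch(t(chol(vcov)), error = function(e)
    stop("covariance of block '", name, "' is not positive definite",
         call. = FALSE))
  as.numeric(mean + L %*% rnorm(length(mean)))
}

#' Draw one concrete parameter set
#'
#' Samples every uncertainty block with its own deterministic substream
#' derived from `seed`, so the same seed always yields the same parameter set
#' and blocks are mutually independent.
#'
#' @param u A [make_uncertainty()] specification.
#' @param seed Integer seed for this draw.
#' @return List with sampled `models`, `hrs` and `cost_points`, in the same
#'   shapes as the inputs to [make_uncertainty()].
#' @export
sample_parameters <- function(u, seed) {
  stopifnot(inherits(u, "parameter_uncertainty"))
  models <- list(female = list(), male = list())
  hrs <- u$hrs
  costs <- u$cost_points
  for (name in names(u$blocks)) {
    blk <- u$blocks[[name]]
    set.seed(block_seed(seed, name))
    if (blk$type == "survival") {
      theta <- draw_mvn(blk$mean, blk$vcov, name)
      models[[blk$sex]][[blk$transition]][[blk$band]] <-
        parametric_model(blk$family, to_natural(blk$family, theta))
    } else if (blk$type == "hr") {
      hrs$hr[blk$row] <- rlnorm(1, blk$meanlog, blk$sdlog)
    } else {
      costs$cost[blk$row] <- blk$sign *
        if (blk$rate > 0 && is.finite(blk$shape))
          rgamma(1, shape = blk$shape, rate = blk$rate)
        else abs(costs$cost[blk$row])
    }
  }
  list(models = models, hrs = hrs, cost_points = costs)
}

default_psa_outcomes <- function(traces, costs) {
  out <- c()
  for (s in names(traces)) {
    prev75 <- prevalence_among_alive(traces[[s]], 75)
    cs <- costs[[s]]$summary
    out <- c(out, setNames(
      c(life_expectancy(traces[[s]]),
        cs$cum_pp[cs$state == "total"], cs$cum_disc_pp[cs$state == "total"],
        sum(prev75[c("OB1", "OB2"), 1])),
      paste0(s, c("_le", "_cum_cost_pp", "_cum_cost_disc_pp", "_ob_prev_75"))))
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the full model — sample a parameter set, rebuild the transition
#' schedule, mortality and cost inputs, simulate both sexes — `n_iter` times,
#' and summarizes each outcome by its empirical 2.5% and 97.5% order
#' statistics (the ceil(0.025 n)-th and ceil(0.975 n)-th sorted values, no
#' interpolation). Iterations that fail are recorded and excluded; more than
#' 5% failures aborts.
#'
#' @param inputs Model inputs (see [default_inputs()]); must contain
#'   `cost_points` (the schedule is rebuilt from sampled points each draw).
#' @param u A [make_uncertainty()] specification.
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed; iteration i uses substreams derived from
#'   `seed + i`.
#' @param outcome_fn Function(traces, costs) returning a named numeric vector
#'   of outcomes per iteration.
#' @return A `psa_result`: list with the per-iteration outcome matrix
#'   (`draws`), percentile `bounds`, `n_iter`, `seed` and failed iteration
#'   indices.
#' @export
run_psa <- function(inputs, u, n_iter = 1000, seed = 1,
                    outcome_fn = default_psa_outcomes) {
  draws <- NULL
  failures <- integer()
  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      par <- sample_parameters(u, seed + i)
      schedule <- build_schedule(par$models)
      cost_schedule <- extend_cost_schedule(par$cost_points)
      traces <- list(); costs <- list()
      for (s in c("female", "male")) {
        traces[[s]] <- run_cohort(inputs$spec, schedule, inputs$lifetable,
                                  par$hrs, s)
        costs[[s]] <- expected_costs(traces[[s]], cost_schedule,
                                     inputs$spec$discount_rate)
      }
      outcome_fn(traces, costs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, i)
      if (length(failures) > 0.05 * n_iter) {
        stop("more than 5% of PSA iterations failed; last error: ",
             conditionMessage(res), call. = FALSE)
      }
      next
    }
    if (is.null(draws)) {
      draws <- matrix(NA_real_, nrow = n_iter, ncol = length(res),
                      dimnames = list(NULL, names(res)))
    }
    draws[i, ] <- res
  }
  ok <- draws[setdiff(seq_len(n_iter), failures), , drop = FALSE]
  n <- nrow(ok)
  lo_i <- max(1L, as.integer(ceiling(0.025 * n)))
  hi_i <- as.integer(ceiling(0.975 * n))
  bounds <- data.frame(
    outcome = colnames(ok),
    mean = colMeans(ok),
    lo = apply(ok, 2, function(v) sort(v)[lo_i]),
    hi = apply(ok, 2, function(v) sort(v)[hi_i]))
  rownames(bounds) <- NULL
  structure(list(draws = ok, bounds = bounds, n_iter = n_iter, seed = seed,
                 failures = failures),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (%d failed), seed %d\n",
              x$n_iter, length(x$failures), x$seed))
  print(x$bounds, digits = 4)
  invisible(x)
}
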