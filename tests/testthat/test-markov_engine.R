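test_that("the transition matrix is row-stochastic with the allowed arrows only", {
  inp <- default_inputs()
  for (age in c(2, 12, 13, 19, 20, 50, 99)) {
    M <- assemble_matrix(age, "female", inp$schedule, inp$lifetable, inp$hrs)
    expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(M >= 0))
    # arrow structure: OW can only stay, progress to OB1, regress to NW2 or die
    expect_equal(names(which(M["OW", ] > 0)) %in% c("OW", "OB1", "NW2", "DEAD"),
                 rep(TRUE, sum(M["OW", ] > 0)))
    # NW1 never reaches NW2 directly; OW regression never feeds NW1
    expect_equal(M["NW1", "NW2"], 0)
    expect_equal(M["OW", "NW1"], 0)
    expect_equal(unname(M["DEAD", ]), c(0, 0, 0, 0, 0, 1))
  }
})

test_that("zero transitions and zero mortality give the identity matrix", {
  sched <- flat_schedule()
  M <- assemble_matrix(30, "male", sched, flat_lifetable(0), flat_hrs())
  expect_equal(unname(M), diag(6))
  tr <- run_cohort(model_spec(), sched, flat_lifetable(0), flat_hrs(), "male")
  expect_equal(tr[, "100"], tr[, "2"], tolerance = 1e-12)
})

test_that("persons are conserved and death is absorbing", {
  inp <- default_inputs()
  tr <- run_cohort(inp$spec, inp$schedule, inp$lifetable, inp$hrs, "female")
  sizes <- colSums(tr)
  expect_equal(unname(sizes), rep(26458, 99), tolerance = 1e-9)
  expect_true(all(diff(tr["DEAD", ]) >= 0))
  expect_true(all(tr >= 0))
})

test_that("with unit hazard ratios the engine reproduces life-table survivorship", {
  inp <- default_inputs()
  spec <- inp$spec
  tr <- run_cohort(spec, inp$schedule, inp$lifetable, flat_hrs(), "male")
  lt <- inp$lifetable
  m <- lt$rate[lt$sex == "male"][match(2:99, lt$age[lt$sex == "male"])]
  survivorship <- c(1, cumprod(exp(-m)))
  alive <- colSums(tr[1:5, ]) / 28662
  expect_equal(unname(alive), survivorship, tolerance = 1e-12)
})

test_that("life expectancy matches closed forms", {
  # no mortality: horizon-truncated at 100
  tr0 <- run_cohort(model_spec(), flat_schedule(), flat_lifetable(0),
                    flat_hrs(), "female")
  expect_equal(life_expectancy(tr0), 100)
  # flat annual death probability q: LE - 2 = sum over t of (1-q)^t
  rate <- -log(0.9)  # q = 0.1
  tr <- run_cohort(model_spec(), flat_schedule(), flat_lifetable(rate),
                   flat_hrs(), "female")
  expect_equal(life_expectancy(tr), 2 + sum(0.9^(1:98)), tolerance = 1e-9)
  # half-cycle correction adds half of the first-vs-last alive difference
  expect_equal(life_expectancy(tr, half_cycle = TRUE),
               life_expectancy(tr) + 0.5 * (1 - 0.9^98), tolerance = 1e-9)
})

test_that("prevalence among the living starts at the initial distribution", {
  inp <- default_inputs()
  tr <- run_cohort(inp$spec, inp$schedule, inp$lifetable, inp$hrs, "female")
  p2 <- prevalence_among_alive(tr, 2)
  expect_equal(unname(p2[, 1]), c(0.8983, 0.0898, 0.0086, 0.0033),
               tolerance = 1e-12)
  p_all <- prevalence_among_alive(tr)
  expect_equal(unname(colSums(p_all)), rep(1, 99), tolerance = 1e-12)
})

test_that("prevalence comparison flags departures from a reference", {
  inp <- default_inputs()
  tr <- run_cohort(inp$spec, inp$schedule, inp$lifetable, inp$hrs, "male")
  prev <- prevalence_among_alive(tr)
  ref <- data.frame(age_lo = c(40, 40), age_hi = c(40, 40),
                    class = c("OW", "OB1"),
                    observed = c(prev["OW", "40"], prev["OB1", "40"]),
                    lo = c(prev["OW", "40"] - 0.01, prev["OB1", "40"] + 0.05),
                    hi = c(prev["OW", "40"] + 0.01, prev["OB1", "40"] + 0.10))
  out <- compare_prevalence(tr, ref)
  expect_equal(out$difference, c(0, 0), tolerance = 1e-12)
  expect_equal(out$within_bounds, c(TRUE, FALSE))
  expect_error(compare_prevalence(tr, transform(ref, age_lo = 150)), "band")
})

test_that("references sampled from the model fall within their own bounds", {
  # self-consistency: observed prevalences drawn from the model's multinomial
  # at n = 5000 per age band carry binomial 95% bounds that cover the model
  inp <- default_inputs()
  tr <- run_cohort(inp$spec, inp$schedule, inp$lifetable, inp$hrs, "female")
  prev <- prevalence_among_alive(tr)
  bands <- seq(20, 70, by = 10)
  n <- 5000
  set.seed(42)
  cover <- replicate(20, {
    ref <- do.call(rbind, lapply(bands, function(a) {
      counts <- drop(rmultinom(1, n, prev[, as.character(a)]))
      obs <- counts / n
      se <- sqrt(obs * (1 - obs) / n)
      data.frame(age_lo = a, age_hi = a, class = rownames(prev),
                 observed = obs, lo = obs - 1.96 * se, hi = obs + 1.96 * se)
    }))
    mean(compare_prevalence(tr, ref)$within_bounds)
  })
  expect_gte(mean(cover), 0.90)
})

test_that("cohort occupancies agree with an agent-level microsimulation", {
  inp <- default_inputs()
  spec <- inp$spec
  n_agents <- 20000
  counts <- microsimulate(n_agents, spec, inp$schedule, inp$lifetable,
                          inp$hrs, "female", seed = 1)
  tr <- run_cohort(spec, inp$schedule, inp$lifetable, inp$hrs, "female")
  frac <- sweep(tr, 2, colSums(tr), "/")
  mfrac <- counts / n_agents
  se <- sqrt(frac * (1 - frac) / n_agents)
  # allow 4 Monte-Carlo standard errors at this smaller agent count
  expect_true(all(abs(mfrac - frac) <= 4 * se + 1e-12))
})
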