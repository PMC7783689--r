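test_that("the two-part model recovers a known cost process", {
  # truth: participation 0.7 (no age effect), OB1 gamma effect such that the
  # incremental cost vs NW is EUR 500 at every age
  delta <- log(1 + 500 / (0.7 * 1500))
  recs <- simulate_cost_records(
    20000, seed = 5, participation = 0.7, mean_cost = 1500,
    part_class_logit = c(NW = 0, OW = 0, OB1 = 0, OB2 = 0),
    cost_class_log = c(NW = 0, OW = 0, OB1 = delta, OB2 = delta),
    age_slope_logit = 0, age_slope_log = 0)
  fit <- fit_two_part(recs, "female")
  est <- coef(fit$part2)[["weight_classOB1"]]
  se <- sqrt(diag(vcov(fit$part2)))[["weight_classOB1"]]
  expect_lt(abs(est - delta), 2 * se)
  for (age in c(30, 60)) {
    ame <- marginal_incremental_cost(fit, age, "OB1")
    expect_lt(abs(ame - 500) / 500, 0.10)
  }
  expect_identical(marginal_incremental_cost(fit, 50, "NW"), 0)
  # gamma GLM with log link reproduces the mean of the positives
  pos <- fit$data[fit$data$annual_cost > 0, ]
  expect_lt(abs(mean(predict(fit$part2, pos, type = "response")) /
                  mean(pos$annual_cost) - 1), 0.01)
})

test_that("null class effects give near-zero marginal increments", {
  recs <- simulate_cost_records(
    20000, seed = 6, part_class_logit = c(NW = 0, OW = 0, OB1 = 0, OB2 = 0),
    cost_class_log = c(NW = 0, OW = 0, OB1 = 0, OB2 = 0))
  fit <- fit_two_part(recs, "male")
  # zero truth up to Monte-Carlo noise (costs average ~EUR 1000)
  expect_lt(abs(marginal_incremental_cost(fit, 50, "OB2")), 120)
})

test_that("degenerate cost data is rejected", {
  recs <- simulate_cost_records(200, seed = 7, participation = 0)
  expect_error(fit_two_part(recs, "female"), "zero and positive")
  expect_error(marginal_incremental_cost(
    fit_two_part(simulate_cost_records(2000, seed = 8), "female"), 10, "OW"),
    "20-80")
})

test_that("cost schedules extend per the 80-plus and under-20 rules", {
  base <- data.frame(sex = "female", state = c("OW", "OB1", "OB2"),
                     cost = c(160, 631, 698))
  sch <- extend_cost_schedule(base)
  expect_equal(sch$cost[sch$state == "OB1" & sch$age == 95],
               sch$cost[sch$state == "OB1" & sch$age == 80])
  expect_equal(sch$cost[sch$state == "OB1" & sch$age == 10], 0)
  expect_true(all(sch$cost[sch$state == "NW"] == 0))
  sch2 <- extend_cost_schedule(base, under20_rule = "constant_at_20")
  expect_equal(sch2$cost[sch2$state == "OW" & sch2$age == 10],
               sch2$cost[sch2$state == "OW" & sch2$age == 20])
  expect_equal(sort(unique(sch$age)), 2:100)
})

test_that("expected costs match hand arithmetic on a toy cohort", {
  # 100 OB1 persons alive for 3 cycles, EUR 10 increment, cohort of 200
  occ <- matrix(0, 6, 3)
  occ[4, ] <- 100  # OB1 row
  occ[6, ] <- 100  # the rest are dead, conservation holds
  tr <- make_trace(occ, ages = 2:4, cohort_size = 200)
  sch <- extend_cost_schedule(
    data.frame(sex = "female", state = "OB1", cost = 10),
    under20_rule = "constant_at_20")
  out <- expected_costs(tr, sch, discount_rate = 0)
  expect_equal(out$summary$cum[out$summary$state == "total"], 3000)
  expect_equal(out$summary$cum_pp[out$summary$state == "total"], 15)
  # 4% discounting: closed-form geometric sum, base year at age 2
  sch100 <- extend_cost_schedule(
    data.frame(sex = "female", state = "OB1", cost = 10),
    under20_rule = "constant_at_20")
  out4 <- expected_costs(tr, sch100, discount_rate = 0.04)
  expect_equal(out4$summary$cum_disc[out4$summary$state == "total"],
               1000 * (1 + 1 / 1.04 + 1 / 1.04^2), tolerance = 1e-9)
})

test_that("discounting never increases costs and the occupancy identity holds", {
  inp <- default_inputs()
  tr <- run_cohort(inp$spec, inp$schedule, inp$lifetable, inp$hrs, "female")
  out <- expected_costs(tr, inp$cost_schedule, 0.04)
  tot <- out$summary[out$summary$state == "total", ]
  expect_lt(tot$cum_disc, tot$cum)
  # per-person cohort cost = occupancy-weighted mean of per-state increments
  inc <- bmicohort:::cost_increment_matrix(inp$cost_schedule, "female",
                                           as.integer(colnames(tr)))
  occ <- rbind(tr["NW1", ] + tr["NW2", ], tr["OW", ], tr["OB1", ], tr["OB2", ])
  expect_equal(tot$cum_pp, sum(occ * inc) / attr(tr, "cohort_size"),
               tolerance = 1e-9)
})

test_that("higher mortality lowers survival-adjusted late-life costs", {
  sched <- flat_schedule()
  sch <- extend_cost_schedule(
    data.frame(sex = "female", state = "OB1", cost = 100))
  spec <- model_spec(init = c(NW = 0, OW = 0, OB1 = 1, OB2 = 0))
  lo <- run_cohort(spec, sched, flat_lifetable(0.01), flat_hrs(), "female")
  hi <- run_cohort(spec, sched, flat_lifetable(0.05), flat_hrs(), "female")
  c_lo <- expected_costs(lo, sch, 0)$summary
  c_hi <- expected_costs(hi, sch, 0)$summary
  expect_lt(c_hi$cum[c_hi$state == "total"], c_lo$cum[c_lo$state == "total"])
})
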