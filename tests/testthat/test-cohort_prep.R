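test_that("weight interpolates linearly between measurements", {
  r <- rec("p1", "female", c(10, 14), c(1.40, 1.55), c(40, 44))
  out <- interpolate_series(r)
  expect_equal(out$age, 10:14)
  expect_equal(out$weight, c(40, 41, 42, 43, 44))
})

test_that("height grows linearly to the plateau age and is constant after", {
  r <- rec("p1", "male", c(16, 20), c(1.70, 1.80), c(60, 75))
  out <- interpolate_series(r)
  expect_equal(out$height[out$age == 17], 1.75)
  expect_equal(out$height[out$age %in% 18:20], rep(1.80, 3))
  # adult heights are constant throughout
  r2 <- rec("p2", "male", c(25, 35), c(1.80, 1.80), c(70, 90))
  out2 <- interpolate_series(r2)
  expect_equal(out2$height, rep(1.80, 11))
})

test_that("single-observation persons are excluded with a count", {
  r <- rbind(rec("a", "female", c(4, 8), c(1.0, 1.2), c(16, 25)),
             rec("b", "female", 5, 1.1, 19))
  expect_message(out <- interpolate_series(r), "1 person")
  expect_equal(attr(out, "n_excluded"), 1L)
  expect_true(all(out$person_id == "a"))
})

test_that("annualize_states applies the age-appropriate rule", {
  cut <- pkg_cutoffs()
  # girl with BMI 18.5 at age 2 (child OW band) and adult with BMI 31
  ann <- rbind(rec("g", "female", 2, 0.9, 18.5 * 0.9^2),
               rec("ad", "male", 40:42, 1.8, 31 * 1.8^2))
  st <- annualize_states(ann, cut)
  expect_equal(st$class[st$person_id == "g"], "OW")
  expect_equal(st$class[st$person_id == "ad"], rep("OB1", 3))
})

test_that("survival spells reproduce the delayed-entry schematics", {
  s1 <- series("p1", "female", 2:13, rep("NW", 12))
  out <- build_survival_records(s1, 1, split_bands = FALSE)
  expect_equal(nrow(out), 1L)
  expect_equal(out$entry, 2)
  expect_equal(out$exit, 13)
  expect_false(out$event)
  # delayed entry at 6 with an event at 11
  s3 <- series("p3", "female", 6:11, c(rep("NW", 5), "OW"))
  out3 <- build_survival_records(s3, 1)
  expect_equal(out3[, c("entry", "exit")], data.frame(entry = 6, exit = 11),
               ignore_attr = TRUE)
  expect_true(out3$event)
  expect_equal(out3$band, "child")
})

test_that("one trajectory contributes to several analyses", {
  # NW -> OW -> OB1 -> OW over ages 30-33
  s <- series("p", "male", 30:33, c("NW", "OW", "OB1", "OW"))
  a1 <- build_survival_records(s, 1)
  expect_equal(nrow(a1), 1L)
  expect_true(a1$event)
  expect_equal(c(a1$entry, a1$exit), c(30, 31))
  a2 <- build_survival_records(s, 2)
  expect_true(a2$event)
  expect_equal(c(a2$entry, a2$exit), c(31, 32))
  a5 <- build_survival_records(s, 5)
  expect_true(a5$event)
  expect_equal(c(a5$entry, a5$exit), c(32, 33))
  # OW -> NW analysis: first OW spell is censored at the competing exit to OB1;
  # the later OW observation is the final age and opens no usable spell
  a6 <- build_survival_records(s, 6)
  expect_equal(nrow(a6), 1L)
  expect_false(a6$event)
  expect_equal(c(a6$entry, a6$exit), c(31, 32))
})

test_that("re-entry opens a new spell", {
  s <- series("p", "female", 30:35, c("NW", "OW", "NW", "NW", "OW", "OW"))
  a1 <- build_survival_records(s, 1)
  expect_equal(nrow(a1), 2L)
  expect_equal(a1$entry, c(30, 32))
  expect_equal(a1$exit, c(31, 34))
  expect_true(all(a1$event))
})

test_that("two-class jumps decompose into one-class events and are counted", {
  s <- series("p", "male", 40:41, c("NW", "OB1"))
  a1 <- build_survival_records(s, 1)
  expect_true(a1$event)  # passes through OW
  expect_equal(attr(a1, "n_two_class_jumps"), 1L)
  a2 <- build_survival_records(s, 2)
  expect_equal(nrow(a2), 0L)  # zero-length OW spell contributes nothing
})

test_that("spells split at band boundaries without changing the likelihood", {
  s <- series("p", "female", 10:16, c(rep("NW", 6), "OW"))
  parts <- build_survival_records(s, 1)
  expect_equal(parts$entry, c(10, 13))
  expect_equal(parts$exit, c(13, 16))
  expect_equal(parts$event, c(FALSE, TRUE))
  expect_equal(parts$band, c("child", "adolescent"))
  whole <- build_survival_records(s, 1, split_bands = FALSE)
  m <- parametric_model("lognormal", c(2.5, 1.1))
  # on a shared clock the censored-part + delayed-entry-part contributions
  # telescope to the unsplit record's contribution
  expect_equal(log_likelihood(m, parts, 2), log_likelihood(m, whole, 2),
               tolerance = 1e-12)
})

test_that("every origin-class person-age is covered by exactly one spell", {
  set.seed(7)
  cut <- pkg_cutoffs()
  spec <- generator_spec(n_persons = 80, ages = 2:12, visit_ages = 2:12,
                         mean_visits = 11)
  recs <- simulate_longitudinal_cohort(spec, cut, seed = 7)
  lat <- attr(recs, "latent")
  for (a_id in c(1, 2, 6)) {
    origin <- bmicohort:::transition_origin(a_id)
    sr <- build_survival_records(lat, a_id, split_bands = FALSE)
    for (d in split(lat, lat$person_id)) {
      in_o <- d$age[d$class == origin & d$age < max(d$age)]
      sp <- sr[sr$person_id == d$person_id[1], ]
      covered <- unlist(lapply(seq_len(nrow(sp)), function(i)
        seq(sp$entry[i], sp$exit[i] - 1)))
      cov_o <- intersect(covered, in_o)
      expect_equal(as.numeric(sort(cov_o)), as.numeric(sort(in_o)))
    }
  }
})
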