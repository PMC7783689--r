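# Generates the packaged text fixtures under inst/extdata/.
# Run from the package root:  Rscript data-raw/make_fixtures.R
pkgload::load_all(".", quiet = TRUE)

out <- function(f) file.path("inst", "extdata", f)

## ---- child BMI cutoff table (synthetic) -------------------------------------
# Smooth U-shaped threshold curves anchored at the age-2 values and reaching
# the adult WHO thresholds (25/30/35) at 18, vertex at age 5.5. Age-2 girl
# anchors are the published example values; everything else is synthetic.
quad <- function(v2, v18, age) {
  B <- (v18 - v2) / ((18 - 5.5)^2 - (2 - 5.5)^2)
  A <- v2 - B * (2 - 5.5)^2
  A + B * (age - 5.5)^2
}
anchors <- list(
  female = c(ow = 18.09, ob1 = 19.81, ob2 = 21.13),
  male   = c(ow = 18.41, ob1 = 20.09, ob2 = 21.60))
ages <- 2:17
cut_tab <- do.call(rbind, lapply(names(anchors), function(s) {
  a <- anchors[[s]]
  data.frame(sex = s, age = ages,
             ow  = round(quad(a[["ow"]], 25, ages), 2),
             ob1 = round(quad(a[["ob1"]], 30, ages), 2),
             ob2 = round(quad(a[["ob2"]], 35, ages), 2))
}))
write.csv(cut_tab, out("child_bmi_cutoffs_synthetic.csv"),
          row.names = FALSE, quote = FALSE)

## ---- transition-model parameter table ---------------------------------------
# Published point estimates per sex/transition/band. The four adult
# log-logistic cells are calibrated: scale fixed at 1, location solved so the
# 80-year band-average annual transition probability equals the published
# band average (the published tuples are not interpretable as log-time
# location/scale pairs).
calibrate_llog_location <- function(target_mean) {
  f <- function(mu) {
    m <- parametric_model("loglogistic", c(mu, 1))
    mean(yearly_tp(m, 20, 20:99)) - target_mean
  }
  uniroot(f, c(-5, 10), tol = 1e-10)$root
}
llog <- vapply(c(f_nw_ow = 0.0325, m_nw_ow = 0.0386,
                 f_ow_ob1 = 0.0238, m_ow_ob1 = 0.0163),
               calibrate_llog_location, numeric(1))
print(round(llog, 4))

par_rows <- rbind(
  # transition, band, family, female p1,p2, male p1,p2
  c("NW-OW",   "child",      "lognormal",   3.16, 1.22,  3.27, 1.19),
  c("NW-OW",   "adolescent", "weibull",    -5.75, 1.85, -6.95, 2.42),
  c("NW-OW",   "adult",      "loglogistic", llog[["f_nw_ow"]], 1, llog[["m_nw_ow"]], 1),
  c("OW-OB1",  "child",      "lognormal",   3.32, 1.51,  3.28, 1.31),
  c("OW-OB1",  "adolescent", "weibull",    -5.22, 1.77, -4.53, 1.54),
  c("OW-OB1",  "adult",      "loglogistic", llog[["f_ow_ob1"]], 1, llog[["m_ow_ob1"]], 1),
  c("OB1-OB2", "child",      "lognormal",   3.35, 1.62,  3.44, 1.62),
  c("OB1-OB2", "adolescent", "gompertz",    0.12, 0.02,  0.02, 0.05),
  c("OB1-OB2", "adult",      "gompertz",   -0.02, 0.05,  0.01, 0.02),
  c("OW-NW",   "child",      "lognormal",   1.64, 0.95,  1.44, 0.91),
  c("OW-NW",   "adolescent", "gompertz",   -0.30, 0.22, -0.36, 0.22),
  c("OW-NW",   "adult",      "gompertz",    0.04, 0.00141, 0.05, 0.00086),
  c("OB1-OW",  "child",      "lognormal",   1.28, 0.92,  1.26, 0.89),
  c("OB1-OW",  "adolescent", "gompertz",   -0.43, 0.31, -0.32, 0.16),
  c("OB1-OW",  "adult",      "gompertz",    0.03, 0.00227, 0.05, 0.00160),
  c("OB2-OB1", "child",      "lognormal",   1.27, 0.77,  1.37, 0.84),
  c("OB2-OB1", "adolescent", "gompertz",   -0.35, 0.48, -0.16, 0.16),
  c("OB2-OB1", "adult",      "gompertz",    0.02, 0.00782, 0.04, 0.00414))
par_tab <- do.call(rbind, lapply(seq_len(nrow(par_rows)), function(i) {
  r <- par_rows[i, ]
  data.frame(sex = c("female", "male"), transition = r[1], band = r[2],
             family = r[3],
             p1 = round(as.numeric(c(r[4], r[6])), 6),
             p2 = round(as.numeric(c(r[5], r[7])), 6),
             p3 = NA_real_)
}))
write.csv(par_tab, out("transition_model_parameters.csv"),
          row.names = FALSE, quote = FALSE)

## ---- synthetic life table ----------------------------------------------------
# Gompertz-Makeham; lambda bisected per sex against the cohort engine's life
# expectancy at age 2 (all hazard ratios at 1), targets 83.5 / 80.5 years.
le_from_lambda <- function(lambda, sex, target) {
  lt <- simulate_life_table(lambda = setNames(c(lambda, lambda),
                                              c("female", "male")))
  hr1 <- data.frame(state = rep(CLASSES, 1), age_lo = 2, age_hi = 101, hr = 1)
  models <- transition_models_from_table(out("transition_model_parameters.csv"))
  sched <- build_schedule(models)
  tr <- run_cohort(model_spec(), sched, lt, hr1, sex)
  life_expectancy(tr) - target
}
lam <- vapply(c(female = 83.5, male = 80.5), function(tgt) {
  sex <- if (tgt == 83.5) "female" else "male"
  uniroot(le_from_lambda, c(1e-6, 3e-4), sex = sex, target = tgt,
          tol = 1e-10)$root
}, numeric(1))
print(signif(lam, 6))
lt <- simulate_life_table(lambda = lam)
lt$rate <- signif(lt$rate, 6)
write.csv(lt, out("life_table_synthetic.csv"), row.names = FALSE, quote = FALSE)

## ---- synthetic hazard ratios -------------------------------------------------
hr_tab <- rbind(
  data.frame(state = "NW", age_lo = 2, age_hi = 101, hr = 1, hr_lo = 1, hr_hi = 1),
  data.frame(state = c("OW", "OW"), age_lo = c(2, 65), age_hi = c(65, 101),
             hr = c(1.11, 1.07), hr_lo = c(1.07, 1.03), hr_hi = c(1.15, 1.11)),
  data.frame(state = c("OB1", "OB1"), age_lo = c(2, 65), age_hi = c(65, 101),
             hr = c(1.49, 1.30), hr_lo = c(1.41, 1.22), hr_hi = c(1.57, 1.38)),
  data.frame(state = c("OB2", "OB2"), age_lo = c(2, 65), age_hi = c(65, 101),
             hr = c(2.06, 1.65), hr_lo = c(1.88, 1.50), hr_hi = c(2.25, 1.81)))
write.csv(hr_tab, out("hazard_ratios_synthetic.csv"),
          row.names = FALSE, quote = FALSE)

## ---- incremental cost point estimates (2009 EUR) ----------------------------
cost_tab <- data.frame(
  sex = rep(c("female", "male"), each = 4),
  state = rep(CLASSES, 2),
  cost = c(0, 160, 631, 698, 0, -96, 182, 1456))
write.csv(cost_tab, out("incremental_cost_points.csv"),
          row.names = FALSE, quote = FALSE)

cat("fixtures written to inst/extdata/\n")
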