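clinical_row <- function(pid = "P1", surg = 0, fup = 24, death = NA,
                         death_ev = FALSE, met = NA, met_ev = FALSE) {
  data.frame(patient_id = pid, surgery_offset_months = surg,
             followup_months = fup, death_months = death,
             death_event = death_ev, metastasis_months = met,
             metastasis_event = met_ev, stringsAsFactors = FALSE)
}

test_that("endpoint construction follows the OS/MFS definitions", {
  # death at 12 months from diagnosis
  os <- build_endpoints(clinical_row(death = 12, death_ev = TRUE, fup = 12), "OS")
  expect_equal(os$time, 12); expect_true(os$event)
  # alive at last follow-up 24 months
  os2 <- build_endpoints(clinical_row(fup = 24), "OS")
  expect_equal(os2$time, 24); expect_false(os2$event)
  # metastasis 6 months after surgery (surgery 1 month after diagnosis),
  # death at 10: MFS = (6, event)
  cl <- clinical_row(surg = 1, met = 7, met_ev = TRUE, death = 11,
                     death_ev = TRUE, fup = 11)
  mfs <- build_endpoints(cl, "MFS")
  expect_equal(mfs$time, 6); expect_true(mfs$event)
  # death without metastasis censors MFS at death by default...
  cl2 <- clinical_row(surg = 1, death = 11, death_ev = TRUE, fup = 11)
  mfs2 <- build_endpoints(cl2, "MFS")
  expect_equal(mfs2$time, 10); expect_false(mfs2$event)
  # ...and counts as an event when toggled
  mfs3 <- build_endpoints(cl2, "MFS", mfs_death_as_event = TRUE)
  expect_true(mfs3$event)
  # inconsistent times are a hard error
  expect_error(build_endpoints(clinical_row(surg = 30, fup = 24), "MFS"),
               "negative")
})

test_that("product-limit estimator matches hand computation", {
  # no events: flat survival
  km0 <- kaplan_meier(data.frame(time = c(5, 10), event = c(FALSE, FALSE)))
  expect_true(all(km0$surv == 1))
  # three events: 2/3, 1/3, 0
  km1 <- kaplan_meier(data.frame(time = 1:3, event = rep(TRUE, 3)))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2: S(1) = 2/3, S(3) = 2/3 * (1 - 1/1) = 0
  km2 <- kaplan_meier(data.frame(time = 1:3, event = c(TRUE, FALSE, TRUE)))
  expect_equal(km2$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(km2$n_risk, c(3, 2, 1))
  # step evaluation, right-continuous with S(0) = 1
  expect_equal(km_surv_at(km1, c(0, 0.5, 1, 2.9, 10)),
               c(1, 1, 2 / 3, 1 / 3, 0))
})

test_that("KM matches the survival package on random censored data", {
  set.seed(12)
  for (i in 1:5) {
    n <- 40
    rec <- data.frame(time = round(rexp(n, 0.1), 1),
                      event = runif(n) < 0.7)
    km <- kaplan_meier(rec)
    or <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
    ev <- km$time %in% or$time
    expect_equal(km$surv[ev], or$surv[match(km$time[ev], or$time)],
                 tolerance = 1e-12)
  }
})

test_that("log-rank: identical groups give statistic 0, toy matches hand form", {
  g <- data.frame(time = c(1, 2, 3), event = c(TRUE, TRUE, FALSE))
  r0 <- log_rank(list(a = g, b = g))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # 4-subject toy: g1 events at 1, 3; g2 events at 2, 4
  g1 <- data.frame(time = c(1, 3), event = c(TRUE, TRUE))
  g2 <- data.frame(time = c(2, 4), event = c(TRUE, TRUE))
  r <- log_rank(list(g1 = g1, g2 = g2))
  # hand 2x2-per-event-time computation: O1 = 2, E1 = 4/3, V = 13/18
  expect_equal(r$statistic, (2 - 4 / 3)^2 / (13 / 18))
  expect_equal(r$statistic, 8 / 13)
  expect_equal(r$df, 1)
  expect_error(log_rank(list(g1, data.frame(time = numeric(),
                                            event = logical()))), "empty")
})

test_that("log-rank agrees with survival::survdiff and is label-symmetric", {
  set.seed(13)
  for (i in 1:5) {
    n <- 30
    df <- data.frame(time = round(rexp(2 * n, 0.08), 1),
                     event = runif(2 * n) < 0.8,
                     grp = rep(c("a", "b"), each = n))
    r <- log_rank(split(df[, 1:2], df$grp))
    or <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
    expect_equal(r$statistic, unname(or$chisq), tolerance = 1e-9)
    rsw <- log_rank(split(df[, 1:2], df$grp)[c(2, 1)])
    expect_equal(rsw$statistic, r$statistic)
  }
  # three groups
  set.seed(14)
  df3 <- data.frame(time = round(rexp(60, 0.08), 1) + 0.1,
                    event = runif(60) < 0.8,
                    grp = rep(c("a", "b", "c"), each = 20))
  r3 <- log_rank(split(df3[, 1:2], df3$grp))
  or3 <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df3)
  expect_equal(r3$statistic, unname(or3$chisq), tolerance = 1e-9)
  expect_equal(r3$df, 2)
})

test_that("log-rank statistic grows with hazard-ratio magnitude", {
  set.seed(15)
  stat_at <- function(hr) {
    mean(replicate(20, {
      a <- data.frame(time = rexp(40, 0.1), event = TRUE)
      b <- data.frame(time = rexp(40, 0.1 * hr), event = TRUE)
      log_rank(list(a, b))$statistic
    }))
  }
  s <- c(stat_at(1), stat_at(2), stat_at(4))
  expect_true(all(diff(s) > 0))
})

test_that("median stratification into survival groups, one and two markers", {
  sc <- data.frame(patient_id = c("P1", "P2", "P3"), marker = "NKp46",
                   value = c(0, 0, 5), stringsAsFactors = FALSE)
  lab <- stratify_by_median(sc)
  rec <- data.frame(patient_id = c("P1", "P2", "P3"), endpoint = "OS",
                    time = c(10, 20, 30), event = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  s1 <- stratified_km(lab, rec)
  expect_equal(unname(s1$group_sizes[c("NKp46_low", "NKp46_high")]), c(2, 1))
  # two independent markers partition the cohort into four groups
  set.seed(16)
  n <- 40
  sc1 <- data.frame(patient_id = sprintf("P%02d", 1:n), marker = "NKp46",
                    value = runif(n))
  sc2 <- data.frame(patient_id = sprintf("P%02d", 1:n), marker = "CD8",
                    value = runif(n))
  rec2 <- data.frame(patient_id = sprintf("P%02d", 1:n), endpoint = "OS",
                     time = rexp(n, 0.05), event = runif(n) < 0.7)
  s2 <- stratified_km(list(stratify_by_median(sc1), stratify_by_median(sc2)),
                      rec2)
  expect_equal(sum(s2$group_sizes), n)
  expect_lte(length(s2$absent_groups), 2)
  expect_equal(s2$logrank$df, length(s2$group_sizes) - 1)
  # degenerate: everyone in one stratum
  lab_one <- data.frame(patient_id = c("P1", "P2"), marker = "m",
                        label = "low", threshold = 0)
  rec_one <- rec[1:2, ]
  expect_warning(s3 <- stratified_km(lab_one, rec_one), "log-rank skipped")
  expect_null(s3$logrank)
})

test_that("empty subgroup is reported absent, not fabricated", {
  lab1 <- data.frame(patient_id = c("P1", "P2", "P3", "P4"), marker = "NKp46",
                     label = c("high", "high", "low", "low"), threshold = 1)
  lab2 <- data.frame(patient_id = c("P1", "P2", "P3", "P4"), marker = "CD8",
                     label = c("high", "high", "low", "low"), threshold = 1)
  rec <- data.frame(patient_id = sprintf("P%d", 1:4), endpoint = "OS",
                    time = c(5, 10, 15, 20), event = TRUE)
  s <- stratified_km(list(lab1, lab2), rec)
  expect_setequal(s$absent_groups,
                  c("NKp46_high/CD8_low", "NKp46_low/CD8_high"))
  expect_equal(sum(s$group_sizes), 4)
})
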