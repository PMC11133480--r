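# mRANO engine: lesion classification, SPD, timepoint rules, confirmation,
# and the PFS/OS event algebra, checked against rule-enumeration oracles.

baseline_lesion <- function(d1, d2, id = "L1", day = 0, present = TRUE) {
  data.frame(patient_id = "PX", visit_day = day, lesion_id = id,
             diam1_mm = d1, diam2_mm = d2, present = present,
             new_lesion = FALSE)
}

test_that("measurability at baseline follows the 10 mm rule, inclusive", {
  les <- rbind(baseline_lesion(12, 9, "L1"), baseline_lesion(10, 10, "L2"),
               baseline_lesion(25, 18, "L3"))
  roles <- classify_lesions(les)
  expect_identical(roles$role[roles$lesion_id == "L1"], "NTL")
  expect_identical(roles$role[roles$lesion_id == "L2"], "TL")
  expect_identical(roles$role[roles$lesion_id == "L3"], "TL")

  # single sub-measurable residual lesion: zero TLs, assessed on NTLs
  single <- baseline_lesion(9, 14)
  expect_identical(classify_lesions(single)$role, "NTL")
  a <- assess_series(rbind(single,
                           baseline_lesion(9, 14, day = 56)))
  expect_identical(a$assessments$preliminary, "SD")
})

test_that("SPD sums diameter products with absent lesions contributing zero", {
  expect_equal(spd(data.frame(diam1_mm = 20, diam2_mm = 10, present = TRUE)),
               200)
  expect_equal(spd(data.frame(diam1_mm = c(20, 15), diam2_mm = c(10, 12),
                              present = c(TRUE, TRUE))), 380)
  expect_equal(spd(data.frame(diam1_mm = c(0, 0), diam2_mm = c(0, 0),
                              present = c(FALSE, FALSE))), 0)
  expect_error(spd(data.frame(diam1_mm = NA_real_, diam2_mm = 10,
                              present = TRUE)), "missing")
})

test_that("timepoint rules: -50% PR, +25% PD vs nadir, else SD", {
  expect_identical(timepoint_response(400, 400, 200), "PR")
  expect_identical(timepoint_response(400, 200, 250), "PD")
  expect_identical(timepoint_response(400, 300, 300), "SD")
  # CR requires all lesions absent; a new non-measurable lesion spoils it
  expect_identical(timepoint_response(400, 100, 0, tl_all_absent = TRUE,
                                      ntl_all_absent = TRUE), "CR")
  expect_identical(timepoint_response(400, 100, 0, tl_all_absent = TRUE,
                                      ntl_all_absent = TRUE,
                                      new_nonmeasurable = TRUE), "PD")
  expect_identical(timepoint_response(400, 400, 380, new_measurable = TRUE),
                   "PD")
})

test_that("timepoint rules agree with the enumeration oracle on a value grid", {
  baseline <- 400
  for (nadir_f in c(0.4, 0.5, 0.8, 1.0)) {
    for (cur_f in seq(0.2, 1.6, by = 0.05)) {
      nadir <- baseline * nadir_f
      cur <- baseline * cur_f
      if (cur < nadir) nadir_eff <- nadir else nadir_eff <- nadir
      expect_identical(
        timepoint_response(baseline, nadir, cur),
        oracle_timepoint(baseline, nadir, cur),
        info = sprintf("nadir=%g cur=%g", nadir, cur))
    }
  }
})

test_that("responses are invariant to a common scaling of all diameters", {
  days <- seq(0, 224, by = 56)
  spds <- spds_for_sequence(c("SD", "PR", "PR", "PD"))
  a1 <- assess_series(lesions_from_spds(spds, days))
  les2 <- lesions_from_spds(spds, days)
  les2$diam1_mm <- les2$diam1_mm * 3.7
  les2$diam2_mm <- les2$diam2_mm * 3.7
  a2 <- assess_series(les2)
  expect_identical(a1$assessments$preliminary, a2$assessments$preliminary)
  expect_equal(a1$assessments$pct_change_baseline,
               a2$assessments$pct_change_baseline)
})

test_that("a responder course with late relapse walks PR -> confirmed PD", {
  # scans: baseline, week 9, week 17, week 27 (EOT relapse), week 33
  days <- c(0, 63, 119, 189, 231)
  spds <- c(400, 180, 170, 230, 300)  # PR at wk9 maintained, then regrowth
  a <- assess_series(lesions_from_spds(spds, days))
  s <- a$assessments
  expect_identical(s$preliminary, c("PR", "PR", "PD", "PD"))
  expect_true(s$confirmed[1])             # PR at week 9 confirmed at week 17
  expect_true(s$confirmed[3])             # relapse PD confirmed at week 33
  expect_identical(a$best_overall_response, "PR")
  rec <- derive_pfs_os(a, list(death_day = NA, new_therapy_day = NA,
                               clinical_pd_day = NA, last_contact_day = 420,
                               treatment_stop_reason = "eot"))
  expect_equal(rec$time_days[rec$endpoint == "PFS"], 189)
  expect_true(rec$event[rec$endpoint == "PFS"])
})

test_that("a transient PD that resolves with no qualifying condition is discarded", {
  days <- seq(0, 224, by = 56)
  spds <- spds_for_sequence(c("SD", "PD", "SD", "SD"))
  a <- assess_series(lesions_from_spds(spds, days))
  expect_false(a$assessments$confirmed[2])
  rec <- derive_pfs_os(a, list(death_day = NA, new_therapy_day = NA,
                               clinical_pd_day = NA, last_contact_day = 300))
  expect_false(rec$event[rec$endpoint == "PFS"])
  expect_equal(rec$time_days[rec$endpoint == "PFS"], 300)
})

test_that("flat series stays SD with best response 0%", {
  days <- seq(0, 168, by = 56)
  a <- assess_series(lesions_from_spds(rep(400, 4), days))
  expect_identical(unique(a$assessments$preliminary), "SD")
  expect_equal(a$best_response_pct, 0)
})

test_that("pseudo-progression voids the PD call", {
  days <- seq(0, 224, by = 56)
  spds <- spds_for_sequence(c("SD", "PD", "PD", "PD"))
  a <- assess_series(lesions_from_spds(spds, days),
                     pseudo_progression_days = 112)
  expect_identical(a$assessments$preliminary[2], "SD")
  expect_true(a$assessments$pseudo_pd[2])
  # the later, non-voided PD still drives the event
  rec <- derive_pfs_os(a, list(death_day = NA, new_therapy_day = NA,
                               clinical_pd_day = NA, last_contact_day = 400))
  expect_equal(rec$time_days[rec$endpoint == "PFS"], 168)
})

test_that("worked event-algebra examples hold", {
  days <- c(0, 62, 118, 174, 230)
  spds <- spds_for_sequence(c("SD", "SD", "PD", "PD"))
  a <- assess_series(lesions_from_spds(spds, days))
  rec <- derive_pfs_os(a, list(death_day = 389, new_therapy_day = NA,
                               clinical_pd_day = NA, last_contact_day = 389))
  expect_equal(rec$time_days, c(174, 389))
  expect_true(all(rec$event))
  expect_identical(rec$reason, c("confirmed_PD", "death"))

  # no progression, new therapy at day 120: censored there
  flat <- assess_series(lesions_from_spds(rep(400, 3), c(0, 56, 112)))
  rec <- derive_pfs_os(flat, list(death_day = NA, new_therapy_day = 120,
                                  clinical_pd_day = NA,
                                  last_contact_day = 300))
  expect_false(rec$event[1])
  expect_equal(rec$time_days[1], 120)
  expect_identical(rec$reason[1], "censor_new_therapy")

  # preliminary PD at day 100 with no further scans, death day 130
  a <- assess_series(lesions_from_spds(c(400, 530), c(0, 100)))
  rec <- derive_pfs_os(a, list(death_day = 130, new_therapy_day = NA,
                               clinical_pd_day = NA, last_contact_day = 130))
  expect_equal(rec$time_days[1], 100)
  expect_true(rec$event[1])
  expect_identical(rec$reason[1], "unconfirmed_PD_qualified")
})

test_that("delaying the confirming scan never moves the PFS event earlier", {
  for (gap in c(56, 84, 112)) {
    days <- c(0, 56, 112, 112 + gap)
    spds <- c(400, 380, 500, 520)  # PD at 112 confirmed later
    a <- assess_series(lesions_from_spds(spds, days))
    rec <- derive_pfs_os(a, list(death_day = NA, new_therapy_day = NA,
                                 clinical_pd_day = NA,
                                 last_contact_day = 600))
    expect_equal(rec$time_days[1], 112)
  }
})

test_that("event algebra matches the exhaustive rule-enumeration oracle", {
  states <- c("SD", "PR", "PD")
  interval <- 56
  n_checked <- 0
  for (len in 0:3) {
    seqs <- if (len == 0) list(character(0)) else
      apply(expand.grid(rep(list(states), len)), 1, as.character,
            simplify = FALSE)
    for (sq in seqs) {
      days <- seq(0, by = interval, length.out = len + 1)
      spds <- spds_for_sequence(sq)
      last_day <- max(days)
      for (death in c(NA, last_day + 40)) {
        for (newtx in c(NA, 30, if (len >= 2) 90)) {
          for (stopr in c(NA, "clinical_progression", "eot")) {
            clin_opts <- c(NA, if (len >= 2) days[3])
            for (clin in clin_opts) {
              ev <- list(death_day = death, new_therapy_day = newtx,
                         clinical_pd_day = clin,
                         last_contact_day = if (!is.na(death)) death
                                            else last_day + 100,
                         treatment_stop_reason = stopr)
              a <- assess_series(lesions_from_spds(spds, days))
              got <- derive_pfs_os(a, ev)
              want <- oracle_derive(spds, days, ev)
              expect_equal(got$time_days, c(want$pfs_time, want$os_time),
                           info = paste(c(sq, unlist(ev)), collapse = "|"))
              expect_equal(got$event, c(want$pfs_event, want$os_event),
                           info = paste(c(sq, unlist(ev)), collapse = "|"))
              n_checked <- n_checked + 1
            }
          }
        }
      }
    }
  }
  expect_gt(n_checked, 1000)
})

test_that("PFS never exceeds OS on simulated cohorts", {
  for (seed in 1:5) {
    co <- generate_cohort(synth_config(seed = seed, n_patients = 15),
                          tables = "truth")
    s <- co$survival
    pfs <- s$time_days[s$endpoint == "PFS"]
    os <- s$time_days[s$endpoint == "OS"]
    expect_true(all(pfs <= os))
  }
})
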