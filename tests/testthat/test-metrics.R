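test_that("accuracy and FP rate follow their defining ratios", {
  expect_equal(accuracy(confusion(TP = 3, TN = 5, FP = 1, FN = 1)), 80.0)
  expect_equal(accuracy(confusion(TP = 10, TN = 10)), 100.0)
  expect_equal(accuracy(confusion(FP = 4, FN = 6)), 0.0)
  expect_error(accuracy(confusion()), "empty")
  expect_equal(fp_rate(confusion(FP = 2, TN = 98)), 2.0)
  expect_equal(fp_rate(confusion(FP = 0, TN = 50)), 0.0)
  expect_equal(fp_rate(confusion(FP = 5, TN = 0)), 100.0)
  expect_error(fp_rate(confusion(TP = 5)), "undefined")
  expect_error(confusion(TP = -1), ">= 0")
})

test_that("event sensitivity reports the documented two-decimal values", {
  expect_equal(event_sensitivity(5, 6), 83.33)
  expect_equal(event_sensitivity(16, 16), 100.00)
  expect_equal(event_sensitivity(90, 91), 98.90)
  # scale invariance
  expect_equal(event_sensitivity(3, 4), event_sensitivity(30, 40))
  expect_error(event_sensitivity(1, 0), "zero")
  expect_error(event_sensitivity(7, 6), "detected")
})

test_that("accuracy plus error rate is exactly 100 on random confusions", {
  for (seed in 1:200) {
    cf <- withr::with_seed(seed, {
      v <- sample(0:50, 4, replace = TRUE)
      if (sum(v) == 0) v[1] <- 1
      confusion(v[1], v[2], v[3], v[4])
    })
    err <- 100 * (cf$FP + cf$FN) / (cf$TP + cf$TN + cf$FP + cf$FN)
    expect_equal(accuracy(cf) + err, 100, tolerance = 1e-12)
    if (cf$FP + cf$TN > 0) {
      expect_identical(fp_rate(cf), 100 * cf$FP / (cf$FP + cf$TN))
    }
  }
})

test_that("window confusion scores decisions against overlap labels", {
  ann <- seizure_annotation(20, 40)
  dec <- toy_decisions(positive_at = 20:39, t_max = 99)
  cf <- window_confusion(dec, ann)
  truth_pos <- sum(label_window(dec$start_s, 1.35, ann) == "seizure-active")
  expect_identical(cf$TP + cf$FN, truth_pos)
  expect_identical(cf$TP + cf$TN + cf$FP + cf$FN, nrow(dec))
  # perfect decisions: no errors
  perfect <- dec
  perfect$label <- label_window(dec$start_s, 1.35, ann)
  cfp <- window_confusion(perfect, ann)
  expect_identical(cfp$FP, 0L)
  expect_identical(cfp$FN, 0L)
  # all-positive on a seizure-free recording
  allpos <- toy_decisions(positive_at = 0:99, t_max = 99)
  cfa <- window_confusion(allpos, seizure_annotation())
  expect_identical(cfa$TN, 0L)
  expect_identical(cfa$FP, 100L)
  # randomized case equals a brute-force per-window comparison
  for (seed in 1:20) {
    cs <- random_case(seed)
    cf <- window_confusion(cs$decisions, cs$ann)
    tru <- vapply(cs$decisions$start_s, function(s) {
      ov <- 0
      for (j in seq_len(nrow(cs$ann))) {
        ov <- ov + max(0, min(s + 1.35, cs$ann$offset_s[j]) -
                         max(s, cs$ann$onset_s[j]))
      }
      ov >= 0.675
    }, logical(1))
    pos <- cs$decisions$label == "seizure-active"
    expect_identical(c(cf$TP, cf$TN, cf$FP, cf$FN),
                     c(sum(pos & tru), sum(!pos & !tru),
                       sum(pos & !tru), sum(!pos & tru)))
  }
})

test_that("per-case evaluation and pooling mirror the report layout", {
  ann <- seizure_annotation(c(100, 300), c(140, 350))
  dec <- toy_decisions(positive_at = c(106, 305, 306), t_max = 499)
  row <- evaluate_case(dec, ann, case = "caseA")
  expect_identical(row$n_seizures, 2L)
  expect_identical(row$n_detected, 2L)
  expect_equal(row$sensitivity_pct, 100)
  expect_equal(row$mean_delay_s, mean(c(6, 5)))
  # single case: pooled equals the case row
  rep1 <- aggregate_cases(row)
  expect_equal(rep1$pooled$pooled_sensitivity_pct, row$sensitivity_pct)
  expect_equal(rep1$pooled$mean_fp_rate_pct, row$fp_rate_pct)
  expect_equal(rep1$pooled$mean_delay_s, row$mean_delay_s)
  # pooled sensitivity uses summed counts: 90 of 91 -> 98.90
  pc <- data.frame(case = c("a", "b"), n_seizures = c(45, 46),
                   n_detected = c(45, 45), fp_rate_pct = c(1, 3),
                   sensitivity_pct = c(100, 97.83),
                   mean_delay_s = c(6, 0), accuracy_pct = c(99, 97))
  rep2 <- aggregate_cases(pc)
  expect_equal(rep2$pooled$pooled_sensitivity_pct, 98.90)
  expect_equal(rep2$pooled$mean_fp_rate_pct, 2)
  # mean delay averages per-case delays of detected cases: {6, 0, 12} -> 6
  pc3 <- rbind(pc, data.frame(case = "c", n_seizures = 1, n_detected = 1,
                              fp_rate_pct = 0, sensitivity_pct = 100,
                              mean_delay_s = 12, accuracy_pct = 100))
  expect_equal(aggregate_cases(pc3)$pooled$mean_delay_s, 6)
  expect_error(aggregate_cases(pc[0, ]), "no cases")
})

test_that("evaluation reports serialize to CSV and JSON", {
  pc <- data.frame(case = "a", n_seizures = 3L, n_detected = 2L,
                   fp_rate_pct = 1.234, sensitivity_pct = 66.67,
                   mean_delay_s = 4.5, accuracy_pct = 98.765)
  rep <- aggregate_cases(pc)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, csv)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 2L)                    # case + pooled rows
  expect_identical(names(tab)[1], "case")
  expect_equal(tab$fp_rate_pct[1], 1.23)             # two-decimal half-up
  expect_equal(tab$accuracy_pct[1], 98.77)
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$pooled$pooled_sensitivity_pct, 66.67)
})

test_that("half-up rounding matches table formatting conventions", {
  # exact binary halves round away from zero (R's round() would give 0.12)
  expect_identical(rtseizure:::round_half_up(0.125, 2), 0.13)
  expect_identical(rtseizure:::round_half_up(-0.125, 2), -0.13)
  expect_identical(rtseizure:::round_half_up(83.3333, 2), 83.33)
  expect_identical(rtseizure:::round_half_up(98.9010989, 2), 98.9)
})
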