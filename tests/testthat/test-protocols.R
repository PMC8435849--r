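# minimal synthetic recording for classification tests
fake_recording <- function(t, activity, stopped_early = FALSE) {
  structure(list(t_ms = t, activity = activity,
                 stopped_early = stopped_early),
            class = "tissue_recording")
}

test_that("termination outcomes are classified per the 800 ms window rule", {
  t <- 0:2000
  light_off <- 1100
  # quiescent from light onset onward -> success during light
  act <- ifelse(t < 80, 0.2, 0)
  out <- detect_termination(fake_recording(t, act), light_off)
  expect_equal(out$outcome, "success_during_light")
  # persistent activity throughout -> failure
  out <- detect_termination(fake_recording(t, rep(0.2, length(t))),
                            light_off)
  expect_equal(out$outcome, "failure")
  expect_true(is.na(out$termination_ms))
  # activity persists through light, extinguishes ~100 ms after light off
  act <- ifelse(t <= light_off + 100, 0.2, 0)
  out <- detect_termination(fake_recording(t, act), light_off)
  expect_equal(out$outcome, "success_indirect")
  expect_equal(out$termination_ms, light_off + 100)
  # resumption near the end of the window -> failure
  act <- ifelse(t <= light_off | (t > 1800 & t < 1900), 0.2, 0)
  expect_equal(
    detect_termination(fake_recording(t, act), light_off)$outcome,
    "failure")
  # early-exit runs count as quiet through the window
  tshort <- 0:1400
  act <- ifelse(tshort <= 1250, 0.2, 0)
  out <- detect_termination(fake_recording(tshort, act, TRUE), light_off)
  expect_equal(out$outcome, "success_indirect")
  # too-short recordings are protocol errors
  expect_error(
    detect_termination(fake_recording(0:1200, rep(0, 1201)), light_off),
    "extend")
})

test_that("single-cell suppression verdict matches the forcing picture", {
  for (m in c("ventricular", "atrial")) {
    res <- run_single_cell_suppression(m, e_e = 1.0)
    expect_true(res$suppressed)
    expect_gt(res$peak_before, 0)
    expect_lt(res$peak_during, -20)
    expect_lt(abs(res$plateau - (-40)), 5)
  }
  # darkness: both stimuli elicit APs, verdict false
  dark <- run_single_cell_suppression("ventricular", e_e = 0)
  expect_false(dark$suppressed)
  expect_gt(dark$peak_during, 0)
})

test_that("sweep bookkeeping: shapes, counts and full-success summary", {
  counts <- matrix(c(3L, 3L, 0L, 2L, 1L, 3L), 3, 2,
                   dimnames = list(c("0.05", "0.5", "5"),
                                   c("GtACR1", "ChR2")))
  sw <- structure(list(counts = counts, onsets = c(0, 100, 200),
                       attempts = data.frame(), light_ms = 1000,
                       window = 800, meta = list()),
                  class = "sweep_table")
  mfs <- min_full_success(sw)
  expect_equal(unname(mfs["GtACR1"]), 0.05)
  expect_equal(unname(mfs["ChR2"]), 5)
  counts[, 2] <- 0L
  sw$counts <- counts
  expect_equal(unname(min_full_success(sw)["ChR2"]), Inf)
})

test_that("report bundle has the published table layout and is reproducible", {
  counts <- matrix(c(0L, 3L, 3L, 0L, 0L, 2L), 3, 2,
                   dimnames = list(c("0.05", "0.5", "5"),
                                   c("GtACR1", "ChR2-RED")))
  sw <- structure(list(
    counts = counts, onsets = c(0, 100, 200),
    attempts = data.frame(opsin = "GtACR1", irradiance = 0.5, onset = 0,
                          outcome = "success_during_light"),
    light_ms = 1000, window = 800,
    meta = list(expression_seed = 1)), class = "sweep_table")
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  report(sw, d1); report(sw, d2)
  tab <- read.csv(file.path(d1, "success_rates.csv"), check.names = FALSE)
  expect_equal(nrow(tab), 3)            # one row per irradiance
  expect_equal(colnames(tab)[-1], c("GtACR1", "ChR2-RED"))
  expect_equal(tab$GtACR1, c("0/3", "3/3", "3/3"))
  expect_identical(readLines(file.path(d1, "success_rates.csv")),
                   readLines(file.path(d2, "success_rates.csv")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true("success_rates.csv" %in% names(man$artifacts))
})

test_that("an empty sweep still yields a valid bundle", {
  sw <- structure(list(
    counts = matrix(integer(0), 0, 0), onsets = c(0, 100, 200),
    attempts = data.frame(), light_ms = 1000, window = 800,
    meta = list(expression_seed = 1)), class = "sweep_table")
  d <- file.path(tempdir(), "rep_empty")
  expect_no_error(report(sw, d))
  expect_true(file.exists(file.path(d, "success_rates.csv")))
})
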