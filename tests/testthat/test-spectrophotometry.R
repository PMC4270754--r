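# Temperature-corrected net optical density, replicate averaging,
# blank QC and the CSV readers.

test_that("delta_od passes net OD through unchanged at the 25 C reference", {
  expect_equal(delta_od(0.35, 0.05, 25, 25), 0.300)
  expect_equal(delta_od(0.12, 0.12, 31, 18), 0)
})

test_that("delta_od applies the two-factor correction away from 25 C", {
  # hand arithmetic: 0.300 / (1.0024 * 1.0069)
  expect_equal(
    delta_od(0.35, 0.05, t_irr = 27, t_read = 26,
             coeff_irr = 0.0012, coeff_read = 0.0069),
    0.2972308, tolerance = 1e-6)
})

test_that("delta_od is linear in the net OD and offset-invariant", {
  for (off in c(0, 0.05, 0.4)) {
    expect_equal(delta_od(0.35 + off, 0.05 + off, 27, 26),
                 delta_od(0.35, 0.05, 27, 26))
  }
  base <- delta_od(0.35, 0.05, 27, 26)
  expect_equal(delta_od(0.65, 0.05, 27, 26), 2 * base, tolerance = 1e-12)
})

test_that("raising the reading temperature above 25 C shrinks the corrected OD", {
  vals <- vapply(c(25, 27, 30, 35), function(tr) delta_od(0.35, 0.05, 25, tr),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("delta_od rejects unphysical temperatures and correction factors", {
  expect_error(delta_od(0.35, 0.05, t_irr = 5, t_read = 25), "\\[10, 40\\]")
  expect_error(delta_od(0.35, 0.05, t_irr = 25, t_read = 45), "\\[10, 40\\]")
  expect_error(delta_od(0.35, 0.05, 30, 30, coeff_irr = -0.3, coeff_read = 0),
               "non-positive")
  expect_warning(out <- delta_od(0.05, 0.35, 25, 25), "swapped")
  expect_lt(out, 0)  # negative net OD carried through, not clamped
})

test_that("cuvette readings and irradiation records validate their fields", {
  expect_error(cuvette_reading("c1", "irradiated", od = -0.1), "non-negative")
  expect_error(cuvette_reading("c1", "irradiated", 0.3, t_read = 45), "\\[10, 40\\]")
  expect_warning(cuvette_reading("c1", "control", 0.05, path_length = 0.5),
                 "plausibility")
  expect_error(irradiation_record("r1", duration = 0), "positive")
  expect_warning(irradiation_record("r1", nominal_dose = 2), "operating band")
  expect_error(irradiation_record("r1", s_k = -5), "positive")
})

make_reading <- function(od, t_read = 25, id = "c", run = "r1",
                         role = "irradiated", path = 1.0) {
  cuvette_reading(id, role, od, path, t_read, run)
}

test_that("replicate averaging reports the sample SD of the mean as Type A", {
  irr <- irradiation_record("r1", t_irr = 25, duration = 0.05, nominal_dose = 20)
  ctrl <- make_reading(0.05, role = "control", id = "ctrl")

  two_same <- rbind(make_reading(0.35, id = "a"), make_reading(0.35, id = "b"))
  r <- average_replicates(two_same, ctrl, irr)
  expect_equal(r$value, 0.300)
  expect_identical(r$type_a_percent, 0)   # zero spread gives 0%, not NA
  expect_equal(r$n_replicates, 2L)

  spread <- rbind(make_reading(0.349, id = "a"), make_reading(0.351, id = "b"))
  r2 <- average_replicates(spread, ctrl, irr)
  expect_equal(r2$value, 0.300)
  # sample SD of {0.299, 0.301} is 0.0014142; SD of the mean 0.001 -> 0.3333%
  expect_equal(r2$type_a_percent, 100 * (0.001) / 0.300, tolerance = 1e-6)

  single <- make_reading(0.35, id = "a")
  r3 <- average_replicates(single, ctrl, irr)
  expect_equal(r3$value, 0.300)
  expect_true(is.na(r3$type_a_percent))
})

test_that("replicate averaging carries the mean path length and flags non-positive means", {
  irr <- irradiation_record("r1")
  ctrl <- make_reading(0.05, role = "control", id = "ctrl")
  reps <- rbind(make_reading(0.35, path = 0.9995, id = "a"),
                make_reading(0.35, path = 1.0005, id = "b"))
  r <- average_replicates(reps, ctrl, irr)
  expect_equal(r$path_length, 1.0)
  expect_false(r$flagged)

  swapped <- make_reading(0.01, id = "a")
  # warns twice: once for the negative corrected OD, once for the flag
  expect_warning(expect_warning(rf <- average_replicates(swapped, ctrl, irr)))
  expect_true(rf$flagged)
  expect_lt(rf$value, 0)
})

test_that("replicate averaging enforces roles and run membership", {
  irr <- irradiation_record("r1")
  ctrl <- make_reading(0.05, role = "control", id = "ctrl")
  expect_error(average_replicates(ctrl, ctrl, irr), "irradiated")
  mixed <- rbind(make_reading(0.35, run = "r1"), make_reading(0.35, run = "r2"))
  expect_error(average_replicates(mixed, ctrl, irr), "one run")
  expect_error(
    average_replicates(make_reading(0.35), make_reading(0.35), irr),
    "control")
})

test_that("blank QC applies a strict threshold to blank and control drift", {
  ctrl <- make_reading(0.05, role = "control", id = "ctrl")
  pass <- blank_qc(make_reading(0.002, role = "water_blank"), ctrl,
                   threshold = 0.01, control_baseline = 0.05)
  expect_true(pass$pass)
  fail <- blank_qc(make_reading(0.02, role = "water_blank"), ctrl,
                   threshold = 0.01, control_baseline = 0.05)
  expect_false(fail$blank_pass)
  expect_equal(fail$blank_od, 0.02)
  # boundary convention: a reading exactly at the threshold fails
  edge <- blank_qc(make_reading(0.01, role = "water_blank"), ctrl,
                   threshold = 0.01, control_baseline = 0.05)
  expect_false(edge$pass)
  expect_error(blank_qc(ctrl, ctrl), "water_blank")
})

test_that("CSV readers round-trip the schemas and reject missing columns", {
  rd <- rbind(make_reading(0.35, id = "a"), make_reading(0.05, id = "ctrl",
                                                         role = "control"))
  rf <- tempfile(fileext = ".csv")
  irf <- tempfile(fileext = ".csv")
  utils::write.csv(rd, rf, row.names = FALSE)
  back <- read_cuvette_readings(rf)
  expect_equal(back$od, rd$od)
  expect_equal(back$role, rd$role)

  ir <- irradiation_record("r1", 25, 0.05, 20, 40000)
  utils::write.csv(ir, irf, row.names = FALSE)
  bir <- read_irradiation_records(irf)
  expect_equal(bir$s_k_u, 40000)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("run_id,od", "r1,0.3"), bad)
  expect_error(read_cuvette_readings(bad), "missing columns")
  expect_error(read_irradiation_records(bad), "missing columns")
  unlink(c(rf, irf, bad))
})
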