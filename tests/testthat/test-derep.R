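test_that("formula parsing and monoisotopic masses match textbook values", {
  expect_equal(parse_formula("C26H46N2O8"),
               c(C = 26L, H = 46L, N = 2L, O = 8L))
  expect_equal(round(monoisotopic_mass("H2O"), 4), 18.0106)
  expect_equal(monoisotopic_mass("H2O"),
               2 * 1.00782503207 + 15.9949146196, tolerance = 1e-12)
  expect_equal(round(monoisotopic_mass("C26H46N2O8"), 4), 514.3254)
  expect_equal(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass("C2Xx3"), "unknown element")

  # additivity over merged compositions
  a <- "C10H15N3O2"
  b <- "C5H8O4S"
  ab <- "C15H23N3O6S"
  expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b),
               monoisotopic_mass(ab), tolerance = 1e-9)
})

test_that("protonated adduct m/z reproduces the lipopeptide reference values", {
  expect_equal(round(adduct_mz("C53H93N9O16", "[M+H]+"), 4), 1112.6813)
  expect_equal(round(adduct_mz("C21H44NO7P", "[M+H]+"), 4), 454.2928)
  expect_equal(round(adduct_mz("C53H93N9O16", "[M+2H]2+"), 4), 556.8443)
  # doubly charged always lighter on the m/z scale
  for (f in c("C26H46N2O8", "C53H93N9O16", "C6H12O6"))
    expect_lt(adduct_mz(f, "[M+2H]2+"), adduct_mz(f, "[M+H]+"))
  expect_error(adduct_mz("C6H12O6", "[M+NH4]+"), "supported")
})

test_that("ppm error is the signed relative deviation in parts per million", {
  expect_equal(ppm_error(500, 500), 0)
  th <- adduct_mz("C26H46N2O8", "[M+H]+")
  e1 <- ppm_error(515.3329, th)
  expect_equal(round(e1, 1), 0.4)
  expect_lte(abs(e1), 2)
  expect_gt(ppm_error(515.3340, th), 2)
  expect_error(ppm_error(500, 0), "> 0")
})

test_that("percent inhibition interpolates between the plate controls", {
  expect_equal(as.numeric(percent_inhibition(0.1, 0.1, 1.0)), 100)
  expect_equal(as.numeric(percent_inhibition(1.0, 0.1, 1.0)), 0)
  expect_equal(as.numeric(percent_inhibition(0.55, 0.1, 1.0)), 50)
  # clipping is applied and flagged
  p <- percent_inhibition(c(-0.5, 2), 0.1, 1.0)
  expect_equal(as.numeric(p), c(110, -10))
  expect_identical(attr(p, "clipped"), c(TRUE, TRUE))
  expect_error(percent_inhibition(0.5, 1.0, 0.9), "assay failure")
})

test_that("fraction windows are half-open 7-second slices", {
  sch <- fraction_scheme()  # 159 fractions, 7 s, offset 30 s
  expect_equal(fraction_rt_window(1, sch), c(30, 37))
  expect_equal(fraction_rt_window(159, sch), c(1136, 1143))
  expect_error(fraction_rt_window(0, sch), "1..159")
  expect_error(fraction_rt_window(160, sch), "crude")
})

test_that("active-fraction calling applies the inclusive 70% rule", {
  mk_plate <- function(percents) {
    rbind(data.frame(well = "M1", role = "medium-control",
                     fraction = NA, readout = 0.1),
          data.frame(well = "G1", role = "growth-control",
                     fraction = NA, readout = 1.0),
          data.frame(well = sprintf("F%02d", seq_along(percents)),
                     role = "sample", fraction = seq_along(percents),
                     readout = 1.0 - percents / 100 * 0.9))
  }
  ca <- call_active(mk_plate(c(10, 69.9, 70, 95, 96, 20)), 70)
  expect_equal(ca$active, c(3, 4, 5))
  expect_equal(ca$windows, data.frame(start = 3L, end = 5L))

  expect_error(call_active(mk_plate(50)[-1, ], 70), "medium-control")
})

test_that("a spiked activity window is recovered exactly from a synthetic plate", {
  syn <- gen_fraction_plate(
    spiked_windows = list(list(fractions = 84:87, inhibition = 95)),
    noise_sd = 2, seed = 8)
  ca <- call_active(syn$plate, 70)
  expect_equal(ca$active, 84:87)
  expect_equal(ca$windows, data.frame(start = 84L, end = 87L))

  # no spikes -> nothing called
  syn0 <- gen_fraction_plate(noise_sd = 2, seed = 8)
  expect_length(call_active(syn0$plate, 70)$active, 0)

  # boundary: exactly 70% with zero noise is active
  syn70 <- gen_fraction_plate(
    spiked_windows = list(list(fractions = 10, inhibition = 70)),
    noise_sd = 0, seed = 1)
  expect_true(10 %in% call_active(syn70$plate, 70)$active)
})

test_that("dereplication finds the serratamolide ion within 2 ppm", {
  db <- data.frame(name = c("serratamolide A", "massetolide E"),
                   formula = c("C26H46N2O8", "C53H93N9O16"))
  feats <- data.frame(rt_s = c(615, 700), mz = c(515.3329, 999.9))
  out <- dereplicate(feats, db, active_fractions = 84:87)
  # fraction of rt 615 s: floor((615-30)/7)+1 = 84
  expect_equal(nrow(out$hits), 1)
  expect_identical(out$hits$compound, "serratamolide A")
  expect_identical(out$hits$adduct, "[M+H]+")
  expect_lte(abs(out$hits$ppm_error), 2)
  expect_equal(out$hits$fraction, 84L)

  # empty reference table: everything is an unknown
  out0 <- dereplicate(feats, db[0, ], active_fractions = 84:87)
  expect_equal(nrow(out0$hits), 0)
  expect_equal(nrow(out0$unknowns), 1)
  expect_match(out0$unknowns$status, "unknown")

  # boundary: |error| exactly at tolerance is retained
  th <- adduct_mz("C26H46N2O8")
  obs <- th * (1 + 2e-6)
  out2 <- dereplicate(data.frame(rt_s = 615, mz = obs), db,
                      active_fractions = 84:87)
  expect_equal(nrow(out2$hits), 1)

  # hits sorted by |ppm error|
  feats3 <- data.frame(rt_s = c(615, 616), mz = c(th * (1 + 1.5e-6), th))
  out3 <- dereplicate(feats3, db, active_fractions = 84:87)
  expect_true(!is.unsorted(abs(out3$hits$ppm_error)))
})
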