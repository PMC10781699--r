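ion_row <- function(...) {
  v <- c(Na = 0, K = 0, Ca = 0, Mg = 0, Cl = 0, SO4 = 0, HCO3 = 0, CO3 = 0)
  args <- c(...)
  v[names(args)] <- args
  v
}

test_that("meq conversion divides by the documented equivalent weights", {
  expect_equal(unname(to_meq(ion_row(Na = 22.99))[1, "Na"]), 1)
  expect_equal(unname(to_meq(ion_row())[1, ]), rep(0, 8))
  # independent constant table, written out by hand
  hand <- c(Na = 22.99, K = 39.10, Ca = 20.04, Mg = 12.155,
            Cl = 35.45, SO4 = 48.03, HCO3 = 61.02, CO3 = 30.005)
  set.seed(4)
  x <- ion_row(Na = runif(1, 1, 100), K = runif(1, 1, 10),
               Ca = runif(1, 1, 100), Mg = runif(1, 1, 50),
               Cl = runif(1, 1, 200), SO4 = runif(1, 1, 100),
               HCO3 = runif(1, 1, 100), CO3 = runif(1, 0, 10))
  expect_equal(to_meq(x)[1, ], x / hand)
})

test_that("TDS by summation adds the eight major ions", {
  expect_equal(tds_by_summation(ion_row()), 0)
  expect_equal(tds_by_summation(ion_row(Na = 192)), 192)
  set.seed(8)
  x <- ion_row(Na = 100, K = 5, Ca = 50, Mg = 30, Cl = 200, SO4 = 80,
               HCO3 = 120, CO3 = 3)
  expect_equal(tds_by_summation(x), sum(rev(x)))  # re-add in another order
  expect_error(tds_by_summation(x[-1]), "Na")
})

test_that("ionic balance error follows its definition and edge cases", {
  # cations exactly balance anions -> 0 (1 meq Na vs 1 meq Cl)
  expect_equal(ionic_balance_error(ion_row(Na = 22.99, Cl = 35.45)), 0)
  # cations 10.5 meq, anions 9.5 meq -> +5%
  expect_equal(ionic_balance_error(ion_row(Na = 10.5 * 22.99,
                                           Cl = 9.5 * 35.45)), 5)
  expect_error(ionic_balance_error(ion_row()), "undefined ionic balance")
})

test_that("CAI-I matches its definition, sign convention and scale invariance", {
  # Na + K meq equal to Cl meq -> 0
  expect_equal(cai_one(ion_row(Na = 22.99, Cl = 35.45)), 0)
  # Cl 2 meq, Na 1 meq -> +0.5 (reverse exchange)
  expect_equal(cai_one(ion_row(Na = 22.99, Cl = 2 * 35.45)), 0.5)
  expect_error(cai_one(ion_row(Na = 1)), "Cl is zero")
  # invariant under uniform scaling
  set.seed(12)
  x <- ion_row(Na = 40, K = 3, Ca = 30, Mg = 10, Cl = 120, SO4 = 60,
               HCO3 = 90, CO3 = 1)
  for (f in c(0.1, 3, 117)) expect_equal(cai_one(f * x), cai_one(x))
  # marine-type, Cl-dominant waters give positive CAI-I
  sv <- generate_survey(generator_config(seed = 3))
  expect_gt(mean(cai_one(sv) > 0), 0.95)
})

test_that("salinity classes follow the TDS cuts and are monotone", {
  expect_equal(classify_salinity(c(1120, 153589, 999.999)),
               c("brackish", "hypersaline", "fresh"))
  expect_equal(classify_salinity(c(1000, 10000, 100000)),
               c("brackish", "saline", "hypersaline"))
  levels_ord <- c("fresh", "brackish", "saline", "hypersaline")
  tds <- sort(c(runif(50, 0, 2e5), 999.999, 1000, 1e4, 1e5))
  idx <- match(classify_salinity(tds), levels_ord)
  expect_true(all(diff(idx) >= 0))
})

test_that("Sulin typing applies the genetic-coefficient rules with fixed ties", {
  meq_row <- function(na, cl, mg = 1, so4 = 1)
    ion_row(Na = na * 22.99, Cl = cl * 35.45, Mg = mg * 12.155,
            SO4 = so4 * 48.03)
  expect_equal(sulin_type(meq_row(na = 6, cl = 10, mg = 2)), "CaCl2")
  expect_equal(sulin_type(meq_row(na = 8, cl = 10, mg = 4)), "MgCl2")
  expect_equal(sulin_type(meq_row(na = 12, cl = 10, so4 = 4)), "Na2SO4")
  expect_equal(sulin_type(meq_row(na = 15, cl = 10, so4 = 4)), "NaHCO3")
  # ties: Na/Cl == 1 goes down the marine branch; the secondary boundary
  # falls on the CaCl2 / NaHCO3 side (probed from both sides of the cut,
  # since exact unity is not constructible in floating point from mg/L)
  expect_equal(sulin_type(meq_row(na = 10, cl = 10, mg = 5)), "MgCl2")
  expect_equal(sulin_type(meq_row(na = 8, cl = 10, mg = 2 - 1e-9)), "CaCl2")
  expect_equal(sulin_type(meq_row(na = 8, cl = 10, mg = 2 + 1e-9)), "MgCl2")
  expect_equal(sulin_type(meq_row(na = 14, cl = 10, so4 = 4 - 1e-9)),
               "NaHCO3")
  expect_equal(sulin_type(meq_row(na = 14, cl = 10, so4 = 4 + 1e-9)),
               "Na2SO4")
  expect_error(sulin_type(ion_row(Na = 10)), "Cl is zero")
  # exactly one type per sample on generated surveys
  sv <- generate_survey(generator_config(seed = 5))
  types <- sulin_type(sv)
  expect_true(all(types %in% c("MgCl2", "CaCl2", "Na2SO4", "NaHCO3")))
  expect_length(types, nrow(sv))
})

test_that("hydrochem_summary appends the five derived columns consistently", {
  sv <- generate_survey(generator_config(seed = 2))
  hc <- hydrochem_summary(sv)
  expect_true(all(c("TDS_sum", "IBE_pct", "CAI_I", "salinity_class",
                    "sulin_type") %in% names(hc)))
  expect_equal(hc$TDS_sum, tds_by_summation(sv))
  expect_equal(hc$salinity_class, classify_salinity(hc$TDS_sum))
})
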