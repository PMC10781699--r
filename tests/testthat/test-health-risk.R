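test_that("oral chronic daily intake follows its defining product", {
  # 2.2 * 350 * 70 / (70 * 25550), written out as an independent check
  expect_equal(cdi_oral(1, "adult"), 770 / 25550, tolerance = 1e-12)
  expect_equal(cdi_oral(0, "adult"), 0)
  expect_equal(cdi_oral(0.0015, "adult"), 0.0015 * 770 / 25550,
               tolerance = 1e-12)
  expect_equal(signif(cdi_oral(0.0015, "adult"), 5), 4.5205e-5)
  expect_error(cdi_oral(-1, "adult"), "non-negative")
})

test_that("dermal chronic daily intake follows its defining product", {
  expect_equal(cdi_dermal(0, "adult", 0.002), 0)
  # survey-maximum Cr for a child
  expect_equal(cdi_dermal(12.3, "child", 0.002),
               12.3 * 1 * 350 * 0.002 * 6600 * 0.001 * 6 / (15 * 2190),
               tolerance = 1e-12)
  expect_equal(signif(cdi_dermal(12.3, "child", 0.002), 5), 1.0379e-2)
  # linear in skin area
  prof <- exposure_profile(receptor = "adult")
  prof2 <- prof; prof2$sa <- 2 * prof$sa
  expect_equal(cdi_dermal(1, prof2, 0.001), 2 * cdi_dermal(1, prof, 0.001))
  expect_error(cdi_dermal(1, "adult", 0), "kp")
})

test_that("hazard quotients reproduce the reported survey extrema for Zn", {
  tox <- default_metal_toxicity()
  zn <- tox[tox$metal == "Zn", ]
  hq_oral <- hq(cdi_oral(0.0002, "adult"), zn$rfd_oral)
  expect_equal(signif(hq_oral, 3), 2.01e-5)
  hq_derm <- hq(cdi_dermal(0.0002, "adult", zn$kp), zn$rfd_dermal)
  expect_equal(signif(hq_derm, 3), 2.86e-7)
  expect_equal(hq(0.5, 0.5), 1)
  expect_error(hq(1, 0), "invalid parameter")
})

test_that("hazard index is the plain sum of quotients", {
  expect_equal(hi(rep(0, 8)), 0)
  expect_equal(hi(c(2, rep(0, 7))), 2)
  set.seed(31)
  v <- runif(8)
  total <- 0; for (x in v) total <- total + x   # brute-force re-sum
  expect_equal(hi(v), total)
  m <- matrix(runif(24), 3)
  expect_equal(hi(m), apply(m, 1, sum))
})

test_that("carcinogenic risk reproduces the reported Cr minima and rejects absent CSF", {
  tox <- default_metal_toxicity()
  cr_csf <- tox$csf_oral[tox$metal == "Cr"]
  expect_equal(signif(cr(cdi_oral(0.0015, "adult"), cr_csf), 3), 2.26e-5)
  expect_equal(signif(cr(cdi_oral(0.0015, "child"), cr_csf), 3), 8.63e-5)
  expect_equal(cr(0, 6.1), 0)
  expect_error(cr(0.01, NA), "not applicable")
})

test_that("risk classes apply strict printed thresholds", {
  expect_equal(classify_hi(c(1.6, 0, 1, 1 + 1e-12)),
               c("high_risk", "low_risk", "low_risk", "high_risk"))
  expect_equal(classify_cr(c(1e-4, 2e-4, 0)),
               c("acceptable", "high_risk", "acceptable"))
})

test_that("child-to-adult oral quotient ratio is the fixed intake/body-weight ratio", {
  ratio <- (1.8 / 2.2) * (70 / 15)
  set.seed(7)
  tox <- default_metal_toxicity()
  for (i in seq_len(nrow(tox))) {
    conc <- runif(1, 1e-4, 10)
    hq_a <- hq(cdi_oral(conc, "adult"), tox$rfd_oral[i])
    hq_c <- hq(cdi_oral(conc, "child"), tox$rfd_oral[i])
    expect_equal(hq_c / hq_a, ratio, tolerance = 1e-12)
  }
})

test_that("dermal quotients are identical through either route-consistent RfD", {
  tox <- default_metal_toxicity()
  set.seed(15)
  conc <- runif(8, 0.001, 5)
  for (i in seq_len(8)) {
    cdi <- cdi_dermal(conc[i], "child", tox$kp[i])
    expect_equal(hq(cdi, tox$rfd_dermal[i]),
                 hq(cdi, derive_rfd_dermal(tox$rfd_oral[i], tox$abs_gi[i])),
                 tolerance = 1e-12)
  }
})

test_that("risk_table at the survey-mean concentrations reproduces the reported Cd risk", {
  df <- data.frame(sample_id = "M", source_class = "TCA_well", pH = 7.9,
                   Na = 2240.9, K = 42.8, Ca = 366.5, Mg = 676.6, Cl = 5933.9,
                   SO4 = 486.6, HCO3 = 166.7, CO3 = 6.2,
                   stringsAsFactors = FALSE)
  for (m in metal_names()) df[[m]] <- study_mean_conc[[m]]
  rt <- risk_table(as_survey(df))
  cd <- rt$by_metal[rt$by_metal$metal == "Cd" & rt$by_metal$receptor == "adult"
                    & rt$by_metal$route == "oral", ]
  expect_equal(cd$cr, 0.04 * 770 / 25550 * 6.1, tolerance = 1e-12)
  expect_equal(round(cd$cr, 3), 0.007)   # reported survey mean
  expect_equal(cd$cr_class, "high_risk")
  # hi equals the sum of the eight hq values
  hi_row <- rt$hi[rt$hi$receptor == "adult" & rt$hi$route == "oral", ]
  sub <- rt$by_metal[rt$by_metal$receptor == "adult" &
                       rt$by_metal$route == "oral", ]
  expect_equal(hi_row$hi, sum(sub$hq), tolerance = 1e-12)
  # cr present iff Cd, Cr, Pb
  expect_setequal(unique(rt$by_metal$metal[!is.na(rt$by_metal$cr)]),
                  c("Cd", "Cr", "Pb"))
})

test_that("vectorized risk equals a scalar per-sample loop", {
  sv <- random_survey(15, seed = 44)
  rt <- risk_table(sv)
  tox <- default_metal_toxicity()
  for (k in sample(nrow(rt$by_metal), 40)) {
    row <- rt$by_metal[k, ]
    i <- match(row$metal, tox$metal)
    cdi <- if (row$route == "oral") cdi_oral(row$conc, row$receptor)
           else cdi_dermal(row$conc, row$receptor, tox$kp[i])
    rfd <- if (row$route == "oral") tox$rfd_oral[i] else tox$rfd_dermal[i]
    expect_equal(row$cdi, cdi, tolerance = 1e-12)
    expect_equal(row$hq, cdi / rfd, tolerance = 1e-12)
  }
})

test_that("risk summary percentages equal a brute-force recount", {
  sv <- generate_survey(generator_config(seed = 9))
  rt <- risk_table(sv)
  lab <- "CRCr Child (Oral)"
  start <- which(rt$summary$criteria == lab)
  row <- rt$summary[start:(start + 1), ]   # the two-class block
  sub <- rt$by_metal[rt$by_metal$metal == "Cr" & rt$by_metal$receptor ==
                       "child" & rt$by_metal$route == "oral", ]
  expect_equal(row$n[row$class == "high_risk"], sum(sub$cr > 1e-4))
  expect_equal(sum(row$n), nrow(sv))
  # every criterion block sums to 100%
  blocks <- split(rt$summary$pct, cumsum(rt$summary$criteria != ""))
  for (b in blocks) expect_equal(sum(b), 100, tolerance = 1e-9)
})

test_that("an unusable metal column aborts with no partial output", {
  sv <- as.data.frame(make_toy_survey(3))
  sv$Cu <- NA_real_
  expect_error(risk_table(as_survey(sv)), "Cu|row")
})
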