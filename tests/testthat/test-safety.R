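test_that("volume-to-mole conversion matches hand arithmetic", {
  water <- list(density = 1.0, molar_mass = 18.015)
  eth <- list(density = 0.789, molar_mass = 46.07)
  expect_equal(unname(vv_to_mole_fraction(0, water, eth)["x_water"]), 0)
  expect_equal(unname(vv_to_mole_fraction(100, water, eth)["x_water"]), 1)
  x50 <- (50 / 18.015) / ((50 / 18.015) + (50 * 0.789 / 46.07))
  expect_equal(unname(vv_to_mole_fraction(50, water, eth)["x_water"]), x50)
  expect_equal(round(x50, 3), 0.764)
  expect_equal(sum(vv_to_mole_fraction(37, water, eth)), 1)
  expect_error(vv_to_mole_fraction(10, list(density = 1), eth), "molar_mass")
})

test_that("linear mixture rules behave as convex combinations", {
  db <- solvent_db()
  pure_eth <- mixture_spec(0, db)
  expect_equal(mixture_boiling_point(pure_eth),
               db$components$ethanol$boiling_point)
  expect_equal(hansen_mix(pure_eth), db$components$ethanol$hansen_delta)

  # equimolar values from direct arithmetic
  x <- c(ethanol = 0.5, water = 0.5)
  eqm <- mixture_spec(50, db, mole_fractions = x)
  expect_equal(mixture_boiling_point(eqm), (78.37 + 100) / 2)
  expect_equal(hansen_mix(eqm), (26.52 + 47.81) / 2)

  # bounds and monotonicity over the sweep
  sweep <- seq(0, 100, by = 10)
  tb <- vapply(sweep, function(w) mixture_boiling_point(mixture_spec(w, db)),
               numeric(1))
  dl <- vapply(sweep, function(w) hansen_mix(mixture_spec(w, db)),
               numeric(1))
  expect_true(all(tb >= 78.37 - 1e-9 & tb <= 100 + 1e-9))
  expect_true(all(diff(tb) > 0))  # water boils higher
  expect_true(all(diff(dl) > 0))  # water has the larger Hansen value
})

test_that("mixture flash point solves the Le Chatelier condition", {
  db <- solvent_db()
  # pure-component limit: recovers the ethanol flash point
  pure <- mixture_spec(0, db)
  expect_equal(mixture_flash_point(pure, "ideal"), 13, tolerance = 1e-3)
  expect_equal(mixture_flash_point(pure, "van_laar"), 13, tolerance = 1e-3)

  # two identical flammable components at any split: same flash point
  twin_db <- db
  twin <- db$components$ethanol
  twin$name <- "water"  # occupy the second slot with an ethanol clone
  twin_db$components$water <- twin
  for (w in c(10, 40, 75)) {
    m <- mixture_spec(w, twin_db)
    expect_equal(mixture_flash_point(m, "ideal"), 13, tolerance = 1e-3)
  }

  # solver agrees with a 0.01 degC brute-force scan of the same condition
  for (w in c(10, 30, 50, 80)) {
    m <- mixture_spec(w, db)
    for (act in c("van_laar", "ideal")) {
      gamma <- if (act == "van_laar")
        oracle_van_laar(m$x[1], db$van_laar$a12, db$van_laar$a21)
      else c(1, 1)
      oracle <- oracle_flash_point(m$x, m$components, gamma)
      expect_equal(mixture_flash_point(m, act), oracle, tolerance = 0.02)
    }
  }

  # dilution by the non-flammable component never lowers the flash point
  fps <- vapply(c(0, 20, 40, 60, 80), function(w)
    mixture_flash_point(mixture_spec(w, db), "ideal"), numeric(1))
  expect_true(all(diff(fps) > 0))

  # no flammable component -> explicit error
  inert_db <- db
  inert_db$components$ethanol$flammable <- FALSE
  expect_error(mixture_flash_point(mixture_spec(20, inert_db)),
               "no flammable")
  # no root in a silly bracket
  expect_error(mixture_flash_point(mixture_spec(20, db),
                                   bracket = c(100, 150)), "bracket")
})

test_that("logistic scores reproduce direct evaluations of the formulas", {
  expect_equal(score_flammability(0), 77.11670480549199, tolerance = 1e-12)
  expect_equal(score_toxicity(0), 99.75273768831498, tolerance = 1e-12)
  expect_equal(score_reactivity(0), 0.36841911358361, tolerance = 1e-12)
  expect_equal(score_reactivity(4), 99.63157113363211, tolerance = 1e-12)
  expect_equal(score_explosiveness(0), 0.09110538159489, tolerance = 1e-12)
  # ethanol's explosive range UEL - LEL = 19 - 3.3
  expect_equal(score_explosiveness(15.7), 0.81464184547538, tolerance = 1e-12)
  # 50-digit arithmetic oracle
  expect_equal(score_toxicity(500), 50.00000040324742, tolerance = 1e-12)

  # asymptotes and monotonicity
  expect_equal(score_flammability(1e6), 0, tolerance = 1e-9)
  expect_equal(score_flammability(-1e6), 100, tolerance = 1e-9)
  expect_equal(score_toxicity(1e6), 0, tolerance = 1e-9)
  expect_true(all(diff(score_flammability(seq(-60, 200, by = 5))) < 0))
  expect_true(all(diff(score_toxicity(seq(0, 2000, by = 50))) < 0))
  expect_true(all(diff(score_reactivity(0:4)) > 0))
  expect_true(all(diff(score_explosiveness(seq(0, 100, by = 5))) > 0))
  expect_error(score_reactivity(5))
  expect_error(score_explosiveness(-1))
})

test_that("CSTS is the score sum, bounded, and peaks at the driest blend", {
  db <- solvent_db()
  sweep <- c(7, 10, 20, 30, 33)
  scores <- lapply(sweep, csts, db = db)
  for (s in scores) {
    vals <- c(s$s_fl, s$s_tx, s$s_r, s$s_exp)
    expect_true(all(vals >= 0 & vals <= 100))
    expect_equal(s$csts, sum(vals))
    expect_true(s$csts >= 0 && s$csts <= 400)
  }
  total <- vapply(scores, `[[`, numeric(1), "csts")
  expect_equal(which.max(total), 1L)         # 7% water is most hazardous
  expect_true(all(diff(total) < 0))          # nonincreasing in water
  sfl <- vapply(scores, `[[`, numeric(1), "s_fl")
  expect_true(all(diff(sfl) < 0))            # flammability drives the trend
  # the other three scores are composition-independent by policy
  for (f in c("s_tx", "s_r", "s_exp"))
    expect_equal(length(unique(vapply(scores, `[[`, numeric(1), f))), 1L)

  # pure-cosolvent flash-point mode is composition-independent for S_FL
  a <- csts(10, db, flash_point_method = "pure_cosolvent")
  b <- csts(30, db, flash_point_method = "pure_cosolvent")
  expect_equal(a$s_fl, b$s_fl)
})

test_that("hazard register lists the pressure equipment scenarios", {
  hz <- hazard_tables()
  expect_named(hz, c("equipment_risks", "bleve_scenarios"))
  expect_equal(nrow(hz$equipment_risks), 4L)
  expect_true("Pressure vessel" %in% hz$equipment_risks$equipment)
  expect_true(all(grepl("BLEVE|Overpressure", hz$equipment_risks$risk)))
  expect_equal(unique(hz$bleve_scenarios$main_scenario), "BLEVE")
})
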