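test_that("MPPA is the arithmetic mean of the side views", {
  expect_equal(mppa(1000, 2000), 1500)
  expect_equal(mppa(777, 777), 777)
  expect_equal(mppa(0, 0), 0)
  expect_true(is.na(suppressMessages(mppa(c(10, NA), c(5, 5)))[2]))
  expect_error(mppa(-1, 5), "non-negative")
})

test_that("digital volumes follow the sum, product and side-sum-plus-log forms", {
  v <- digital_volumes(1, 2, 3)
  expect_equal(v$V, 6)
  expect_equal(digital_volumes(2, 3, 4)$V_lemnatec, 24)
  expect_equal(digital_volumes(100, 200, exp(3))$V_keygene, 309)
  # base-10 alternative is selectable
  expect_equal(digital_volumes(0, 0, 100, log_base = "10")$V_keygene, 6)
  expect_error(digital_volumes(1, 1, 0), "positive")
})

test_that("supplied N follows the schedule arithmetic in grams of elemental N", {
  expect_equal(n_supplied(0.5, 0.1, 7), 0.5 * 0.1 * 7 * 0.014007)
  expect_equal(round(n_supplied(0.5, 0.1, 7) * 1000, 1), 4.9)   # mg
  expect_equal(round(n_supplied(5, 0.1, 7) * 1000, 0), 49)      # mg
  expect_error(n_supplied(5, 0.1, 0), "positive")
  expect_error(n_supplied(-1, 0.1, 7), "positive")
})

test_that("NUE is the exact DM/Ns quotient with dose inversion", {
  expect_equal(nue(2.45, 0.049), 50)
  expect_equal(nue(0, 0.01), 0)
  x <- nue(1.7, 0.0049)
  expect_equal(nue(1.7, 0.049), x / 10)   # 10x dose -> NUE / 10
  expect_error(nue(1, 0), "positive")
  expect_error(nue(-1, 0.01), "non-negative")
})

test_that("phase assignment uses half-open intervals anchored at the cuts", {
  cuts <- c(28, 56, 84)
  expect_equal(as.character(assign_phases(30, cuts)), "EP-1")
  expect_equal(as.character(assign_phases(56, cuts)), "EP-2")   # exactly at cut 2
  expect_equal(as.character(assign_phases(0, cuts)), "AP")
  expect_equal(as.character(assign_phases(27.999, cuts)), "AP")
  expect_equal(as.character(suppressMessages(assign_phases(90, cuts))), "out-of-study")
  expect_error(assign_phases(10, c(56, 28, 84)), "increasing")
  expect_error(assign_phases(10, cuts, start = 30), "start")
})

test_that("phase-level RGR recovers the rate of an exact exponential series", {
  # regardless of which interior imaging dates exist
  for (days in list(c(0, 28), c(0, 7, 21, 28), c(0, 3.5, 24.5, 28))) {
    tl <- data.frame(pot_id = "X", day = days,
                     mppa = 500 * exp(0.2 * days), phase = "EP-1")
    pr <- growth_rates(tl)$phase_rates
    expect_equal(pr$RGR, 0.2, tolerance = 1e-12)
  }
  # forced arithmetic: 100 -> 100*e^1.4 over 7 days is 0.2 per day
  tl <- data.frame(pot_id = "X", day = c(0, 7), mppa = c(100, 100 * exp(1.4)),
                   phase = "EP-1")
  expect_equal(growth_rates(tl)$phase_rates$RGR, 0.2)
  tl$mppa <- c(1000, 8000)
  expect_equal(growth_rates(tl)$phase_rates$AGR_area, 1000)
})

test_that("constant series give zero growth, missing endpoints degrade gracefully", {
  tl <- data.frame(pot_id = "X", day = c(0, 7, 14), mppa = 500, phase = "EP-1")
  pr <- growth_rates(tl)$phase_rates
  expect_equal(pr$AGR_area, 0)
  expect_equal(pr$RGR, 0)
  # non-positive endpoint: RGR missing, AGR still computed
  tl$mppa <- c(0, 200, 400)
  pr <- growth_rates(tl)$phase_rates
  expect_true(is.na(pr$RGR))
  expect_equal(pr$AGR_area, 400 / 14)
  # a single date in a phase yields no row and a logged warning
  tl2 <- data.frame(pot_id = "X", day = 3, mppa = 100, phase = "AP")
  expect_null(suppressMessages(growth_rates(tl2))$phase_rates)
})

test_that("AGR_dm divides harvest DM by the actual phase duration", {
  tl <- data.frame(pot_id = "X", day = c(28, 35, 52), mppa = c(100, 300, 900),
                   phase = "EP-1")
  h <- data.frame(pot_id = "X", phase = "EP-1", DM = 1.4, phase_duration = 28)
  pr <- growth_rates(tl, harvests = h)$phase_rates
  expect_equal(pr$AGR_dm, 0.05)
})

test_that("derived trait table couples NUE, DM and Ns exactly", {
  tt <- tiny_trial(G = 6, R = 2, seed = 21)
  cfg <- default_config()
  dt <- derive_traits(tt$traj, tt$harvests, c(28, 56, 84), cfg$schedule$nutrient)
  tr <- dt$traits
  ep <- tr[tr$phase != "AP", ]
  expect_equal(ep$NUE, ep$DM / ep$Ns)
  expect_true(all(is.na(tr$NUE[tr$phase == "AP"])))
  expect_equal(sort(unique(ep$Ns)), sort(c(n_supplied(0.5, 0.1, 7), n_supplied(5, 0.1, 7))))
  # one row per pot x phase
  expect_equal(nrow(tr), nrow(tt$design) * 3)
  # MPPA column matches the mean of the simulated side views at phase end
  expect_true(all(c("V", "V_lemnatec", "V_keygene", "AGR_area", "RGR") %in% names(tr)))
})

test_that("long feature tables with empty flags reshape into missing traits", {
  feats <- expand.grid(pot_id = c("A", "B"), day = c(1, 5),
                       view = c("top", "side-0", "side-90"),
                       stringsAsFactors = FALSE)
  feats$area <- 100
  feats$empty_flag <- FALSE
  feats$empty_flag[feats$pot_id == "B" & feats$day == 5 & feats$view == "side-0"] <- TRUE
  w <- ryeNUE:::features_to_wide(feats)
  expect_equal(nrow(w), 4)
  expect_true(is.na(w$area_side0[w$pot_id == "B" & w$day == 5]))
  expect_equal(w$area_top[w$pot_id == "A" & w$day == 1], 100)
})
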