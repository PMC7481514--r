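test_that("noiseless trajectories equal the closed-form logistic and reset at cuts", {
  d <- generate_design(1, 1, 1, 1, seed = 1)
  tr <- growth_truth(d, sd_genotype = 0, sd_interaction = 0, sd_replicate = 0,
                     sd_obs = 0, sd_fm = 0, sd_dm = 0, seed = 1)
  traj <- simulate_growth(d, tr, cut_dates = c(28, 56, 84),
                          imaging_interval = 3.5, seed = 1)
  K <- unname(tr$K["1"])  # single treatment level -> treatments = 1
  expect_equal(traj$true_area, logistic_regrowth(traj$t_in_phase, K, tr$A0, tr$r))
  expect_equal(traj$area_side0, traj$true_area)  # noiseless observation
  # post-cut imaging dates carry the residual area A0
  expect_equal(traj$true_area[traj$t_in_phase == 0],
               rep(tr$A0, sum(traj$t_in_phase == 0)))
})

test_that("doubled asymptote doubles mean final area between treatments", {
  d <- generate_design(60, 2, 2, 60, seed = 2)   # 240 pots
  tr <- growth_truth(d, K = c(60000, 120000), sd_genotype = 0.1,
                     sd_interaction = 0, sd_replicate = 0, sd_obs = 0.02, seed = 2)
  traj <- simulate_growth(d, tr, seed = 2)
  fin <- traj[traj$phase == "EP-1" & traj$t_in_phase == max(traj$t_in_phase[traj$phase == "EP-1"]), ]
  m <- tapply(fin$area_side0, fin$treatment, mean)
  # ratio of Monte-Carlo means vs closed-form logistic ratio
  expected <- logistic_regrowth(24.5, 120000, tr$A0, tr$r) /
              logistic_regrowth(24.5, 60000, tr$A0, tr$r)
  expect_equal(unname(m["5"] / m["0.5"]), expected, tolerance = 0.05)
})

test_that("acclimation phase shows no treatment effect, experimental phases do", {
  d <- generate_design(30, 2, 2, 30, seed = 3)
  tr <- growth_truth(d, sd_obs = 0, sd_genotype = 0, sd_interaction = 0,
                     sd_replicate = 0, seed = 3)
  traj <- simulate_growth(d, tr, seed = 3)
  last_ap <- traj[traj$phase == "AP" & traj$t_in_phase == 24.5, ]
  m_ap <- tapply(last_ap$true_area, last_ap$treatment, mean)
  expect_equal(unname(m_ap["0.5"]), unname(m_ap["5"]))
  last_ep <- traj[traj$phase == "EP-1" & traj$t_in_phase == 24.5, ]
  m_ep <- tapply(last_ep$true_area, last_ep$treatment, mean)
  expect_gt(unname(m_ep["5"]), unname(m_ep["0.5"]) * 1.5)
})

test_that("trajectories and harvests are pure functions of their seeds", {
  d <- generate_design(4, 2, 2, 4, seed = 4)
  tr <- growth_truth(d, seed = 5)
  t1 <- simulate_growth(d, tr, seed = 6)
  t2 <- simulate_growth(d, tr, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$area_side0, simulate_growth(d, tr, seed = 7)$area_side0))
  h1 <- simulate_harvests(t1, tr, seed = 8)
  expect_identical(h1, simulate_harvests(t1, tr, seed = 8))
})

test_that("analytic AGR is unimodal and RGR decreasing when A0 < K/2", {
  t <- seq(0, 28, by = 0.25)
  a <- logistic_regrowth(t, K = 80000, A0 = 8000, r = 0.22)
  agr <- diff(a) / diff(t)
  pk <- which.max(agr)
  expect_gt(pk, 1)
  expect_lt(pk, length(agr))
  expect_true(all(diff(agr[1:pk]) > 0))
  expect_true(all(diff(agr[pk:length(agr)]) < 0))
  rgr <- diff(log(a)) / diff(t)
  expect_true(all(diff(rgr) < 0))
})

test_that("noiseless harvests are an exact linear map of area gain", {
  tt <- tiny_trial(G = 6, R = 2, seed = 9, sd_fm = 0, sd_dm = 0)
  pe <- attr(tt$traj, "phase_end")
  h <- tt$harvests[order(tt$harvests$pot_id, tt$harvests$phase), ]
  pe <- pe[order(pe$pot_id, pe$phase), ]
  expect_equal(h$FM, tt$truth$fm_per_px * (pe$true_end_area - tt$truth$A0))
  expect_equal(cor(h$FM, pe$true_end_area - tt$truth$A0), 1)
  # constant dry-matter fraction applies exactly
  expect_equal(h$DM, h$FM * 0.20)
  expect_true(all(h$DM <= h$FM & h$DM > 0))
})

test_that("growth input validation: cut dates must increase", {
  d <- generate_design(2, 1, 1, 2, seed = 1)
  tr <- growth_truth(d, seed = 1)
  expect_error(simulate_growth(d, tr, cut_dates = c(28, 28, 84)), "increasing")
})
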