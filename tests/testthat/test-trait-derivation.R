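test_that("growth rate reproduces the log-ratio over the exponential phase", {
  ## doubling in one day
  s <- data.frame(day = c(0, 1), rfu = c(100, 200))
  expect_equal(growth_rate(s), log(2), tolerance = 1e-12)
  ## analytic: F2 = F1 * exp(1.2) over 2 days
  s <- data.frame(day = c(0, 2), rfu = c(50, 50 * exp(1.2)))
  expect_equal(growth_rate(s), 0.6, tolerance = 1e-12)
  ## no increase in fluorescence -> exactly zero
  s <- data.frame(day = 0:3, rfu = c(100, 90, 90, 80))
  expect_identical(growth_rate(s), 0)
  expect_error(growth_rate(data.frame(day = 0, rfu = 5)), "2 points")
})

test_that("growth rate is invariant to fluorescence scale", {
  set.seed(5)
  for (i in 1:10) {
    day <- sort(sample(0:20, 6))
    rfu <- exp(0.3 * day) * exp(rnorm(6, 0, 0.05))
    s <- data.frame(day = day, rfu = rfu)
    k <- runif(1, 0.01, 100)
    expect_equal(growth_rate(s),
                 growth_rate(data.frame(day = day, rfu = k * rfu)),
                 tolerance = 1e-10)
  }
})

test_that("exponential-phase detection finds the rise, not lag or plateau", {
  ## 2 flat lag days, exact doubling days 2-5, plateau after
  s <- data.frame(day = 0:7, rfu = c(100, 100, 100, 200, 400, 800, 800, 800))
  ph <- detect_exponential_phase(s)
  expect_false(ph$no_growth)
  expect_equal(c(ph$t1, ph$t2), c(2, 5))
  expect_equal(ph$slope, log(2), tolerance = 1e-9)
  expect_equal(growth_rate(s), log(2), tolerance = 1e-12)

  ## brute-force cross-check: the chosen window has the max OLS slope,
  ## with longest-window tie-breaking
  slopes <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    y <- log(s$rfu[i:j]); x <- s$day[i:j]
    slopes[[length(slopes) + 1]] <-
      c(i, j, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  }
  sl <- do.call(rbind, slopes)
  best <- sl[abs(sl[, 3] - max(sl[, 3])) <= 1e-9, , drop = FALSE]
  best <- best[which.max(best[, 2] - best[, 1]), ]
  expect_equal(unname(best[1:2]), c(ph$i, ph$j))

  ## pure exponential: full-series window by the longest-window tie-break
  s2 <- data.frame(day = 0:5, rfu = 10 * exp(0.4 * (0:5)))
  ph2 <- detect_exponential_phase(s2)
  expect_equal(c(ph2$i, ph2$j), c(1, 6))
  ## strictly decreasing: no-growth sentinel
  expect_true(detect_exponential_phase(
    data.frame(day = 0:4, rfu = c(50, 40, 30, 20, 10)))$no_growth)
})

test_that("net uptake follows batch drawdown with a zero clamp", {
  expect_equal(net_uptake_rate(36, 16, 1e9, 5), 4e-9, tolerance = 1e-12)
  expect_identical(net_uptake_rate(882, 882, 1e9, 5), 0)
  ## apparent release clamps to exactly zero
  expect_identical(net_uptake_rate(882, 900, 1e9, 5), 0)
  expect_error(net_uptake_rate(882, 500, 0, 5), "cell_density")
  expect_error(net_uptake_rate(882, 500, 1e9, 0), "dt")
})

test_that("uptake is linear in drawdown and inverse in density", {
  set.seed(9)
  for (i in 1:10) {
    n0 <- runif(1, 100, 900); n1 <- runif(1, n0 / 2, n0)
    C <- runif(1, 1e7, 1e10); dt <- runif(1, 1, 20)
    s <- net_uptake_rate(n0, n1, C, dt)
    expect_equal(net_uptake_rate(n0, n0 - 2 * (n0 - n1), C, dt), 2 * s,
                 tolerance = 1e-10)
    expect_equal(net_uptake_rate(n0, n1, 2 * C, dt), s / 2,
                 tolerance = 1e-10)
  }
})

test_that("resource use efficiency is a log ratio with molar conversion", {
  spec <- trait_spec()
  ## POC 100 umol C/L vs TN 10 uM -> log10(10) = 1
  expect_equal(resource_use_efficiency(100 * 12.011, 10, "N", spec), 1,
               tolerance = 1e-12)
  expect_equal(resource_use_efficiency(10 * 12.011, 10, "N", spec), 0,
               tolerance = 1e-12)
  ## translation property: scaling POC by k adds log10(k)
  set.seed(2)
  for (i in 1:10) {
    poc <- runif(1, 10, 1e4); tn <- runif(1, 1, 900); k <- runif(1, 0.1, 50)
    expect_equal(resource_use_efficiency(k * poc, tn, "N", spec) -
                 resource_use_efficiency(poc, tn, "N", spec),
                 log10(k), tolerance = 1e-10)
  }
  ## mass mode divides by the nutrient molar mass instead
  spec_m <- trait_spec(rue_unit_mode = "mass")
  expect_equal(resource_use_efficiency(140.07, 10, "N", spec_m), 0,
               tolerance = 1e-12)
  expect_error(resource_use_efficiency(0, 10, "N", spec), "undefined")
})

test_that("per-cell quotas and the chl-a standard curve behave linearly", {
  expect_equal(per_cell_quota(10, 1e9), 1e-8)
  expect_identical(per_cell_quota(0, 1e9), 0)
  expect_equal(per_cell_quota(14, 2e9), per_cell_quota(7, 1e9))
  expect_error(per_cell_quota(10, 0), "undefined")

  expect_equal(calibrate_chla(5, standard_curve(1, 0)), 5)
  expect_equal(calibrate_chla(0.25, standard_curve(2, -1)), 0)  # floored
  expect_equal(calibrate_chla(4, standard_curve(0.5, 1)), 3)
  expect_error(standard_curve(0), "slope")
})

test_that("stoichiometric ratios are molar and scale invariant", {
  ## Redfield construction: C:N:P = 106:16:1 in moles
  k <- 3.7
  r <- stoichiometric_ratios(106 * 12.011 * k, 16 * 14.007 * k, 30.974 * k)
  expect_equal(unname(r), c(106 / 16, 106, 16), tolerance = 1e-12)
  ## equal molar C and N
  r2 <- stoichiometric_ratios(12.011, 14.007, 30.974)
  expect_equal(r2[["cn_ratio"]], 1, tolerance = 1e-12)
  ## scaling all inputs leaves ratios unchanged
  expect_equal(stoichiometric_ratios(700, 100, 20),
               stoichiometric_ratios(7 * 700, 7 * 100, 7 * 20),
               tolerance = 1e-12)
  expect_error(stoichiometric_ratios(100, 0, 3), "undefined")
})

test_that("the full trait row matches independent hand computation", {
  tm <- build_trait_matrix(hand_record())
  expect_equal(dim(tm), c(1L, 15L))
  r <- tm$traits[1, ]
  ## literal arithmetic, written out independently of the implementation
  expect_equal(r[["growth_rate"]], log(625 / 100) / 4, tolerance = 1e-10)
  expect_equal(r[["chla_per_cell"]], 50 / 2e9, tolerance = 1e-10)
  expect_equal(r[["poc_per_cell"]], 4000 / 2e9, tolerance = 1e-10)
  expect_equal(r[["pon_per_cell"]], 700 / 2e9, tolerance = 1e-10)
  expect_equal(r[["pop_per_cell"]], 90 / 2e9, tolerance = 1e-10)
  expect_equal(r[["cn_ratio"]], (4000 / 12.011) / (700 / 14.007),
               tolerance = 1e-10)
  expect_equal(r[["cp_ratio"]], (4000 / 12.011) / (90 / 30.974),
               tolerance = 1e-10)
  expect_equal(r[["np_ratio"]], (700 / 14.007) / (90 / 30.974),
               tolerance = 1e-10)
  expect_equal(r[["no3_uptake"]], (882 - 500) / (2e9 * 6), tolerance = 1e-10)
  expect_equal(r[["po4_uptake"]], (36 - 20) / (2e9 * 6), tolerance = 1e-10)
  expect_equal(r[["rue_n"]], log10((4000 / 12.011) / 600), tolerance = 1e-10)
  expect_equal(r[["rue_p"]], log10((4000 / 12.011) / 30), tolerance = 1e-10)
  expect_equal(r[["poc_ugL"]], 4000)
  expect_equal(r[["cell_density"]], 2e9)
  expect_equal(r[["chla_ugL"]], 50)
  expect_identical(tm$flags, "")
})

test_that("dead cultures and zero clamps produce exact zeros with flags", {
  rec <- hand_record()
  rec$samples$cell_density_per_L <- 0
  rec$fluorescence$rfu <- c(100, 90, 80, 70)
  tm <- build_trait_matrix(rec)
  expect_identical(unname(tm$traits[1, c("growth_rate", "chla_per_cell",
                                         "no3_uptake", "po4_uptake",
                                         "cell_density")]),
                   rep(0, 5))
  expect_match(tm$flags[1], "dead_culture")
  ## residual above medium: uptake clamps to exactly 0, row flagged
  rec2 <- hand_record()
  rec2$samples$no3_uM <- 900
  tm2 <- build_trait_matrix(rec2)
  expect_identical(tm2$traits[1, "no3_uptake"], c(no3_uptake = 0))
  expect_match(tm2$flags[1], "zero_clamped_uptake")
})

test_that("trait derivation is deterministic and complete on the design", {
  cfg <- synthetic_config(seed = 21)
  sim <- generate_experiment(cfg)
  tm1 <- build_trait_matrix(sim$records)
  tm2 <- build_trait_matrix(sim$records)
  expect_identical(tm1$traits, tm2$traits)
  expect_equal(dim(tm1), c(180L, 15L))
  expect_false(anyNA(tm1$traits))
  ## clamped traits are never negative
  expect_true(all(tm1$traits[, c("growth_rate", "no3_uptake",
                                 "po4_uptake")] >= 0))
})
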