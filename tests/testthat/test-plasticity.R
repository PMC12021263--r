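test_that("centroids are coordinate-wise means with translation equivariance", {
  expect_equal(centroid(rbind(c(0, 0), c(2, 0))), c(1, 0))
  expect_equal(centroid(rbind(c(3, -1))), c(3, -1))
  set.seed(81)
  p <- matrix(rnorm(20), 10, 2)
  v <- c(5, -2)
  expect_equal(centroid(sweep(p, 2, v, "+")), centroid(p) + v,
               tolerance = 1e-12)
  expect_error(centroid(p[0, , drop = FALSE]), "empty")
})

test_that("species plasticity is the mean replicate-to-centroid distance", {
  keys <- data.frame(species = rep("a", 2), salinity_psu = c(5, 20),
                     replicate = c(1, 1))
  sc <- rbind(c(1, 0), c(-1, 0))
  sp <- species_plasticity(sc, keys, n_dims = 2)
  expect_equal(unname(sp$plasticity), 1)
  ## identical replicates: zero plasticity
  sp0 <- species_plasticity(rbind(c(2, 2), c(2, 2), c(2, 2)),
                            data.frame(species = "a", salinity_psu = c(0, 5, 15),
                                       replicate = 1), 2)
  expect_equal(unname(sp0$plasticity), 0)
  ## 7 random points vs direct arithmetic
  set.seed(82)
  pts <- matrix(rnorm(14), 7, 2)
  keys7 <- data.frame(species = "a", salinity_psu = 1:7, replicate = 1)
  cen <- c(mean(pts[, 1]), mean(pts[, 2]))
  manual <- mean(sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2))
  expect_equal(unname(species_plasticity(pts, keys7, 2)$plasticity), manual,
               tolerance = 1e-12)
  ## the stored replicate distances average back to the species value
  sim <- generate_experiment(synthetic_config(seed = 83))
  tm <- build_trait_matrix(sim$records)
  e <- extended_traitscape(tm)
  sp_all <- species_plasticity(e$scores, e$row_keys, 2)
  agg <- tapply(sp_all$distances$distance, sp_all$distances$species, mean)
  expect_equal(as.numeric(agg[names(sp_all$plasticity)]),
               unname(sp_all$plasticity), tolerance = 1e-12)
})

test_that("interspecific variability variants match direct computation", {
  ## two species at (+-2, 0), salinity centroid at origin
  keys <- data.frame(species = rep(c("a", "b"), each = 2),
                     salinity_psu = 5, replicate = c(1, 2, 1, 2))
  sc <- rbind(c(2, 0), c(2, 0), c(-2, 0), c(-2, 0))
  ivc <- interspecific_variability(sc, keys, 2, "centroid_based")
  expect_equal(unname(ivc$variability), 2)
  ivr <- interspecific_variability(sc, keys, 2, "replicate_based")
  expect_equal(unname(ivr$variability), 2)
  ## coincident centroids: zero centroid-based variability
  sc2 <- rbind(c(1, 1), c(-1, -1), c(1, 1), c(-1, -1))
  expect_equal(unname(interspecific_variability(sc2, keys, 2,
               "centroid_based")$variability), 0, tolerance = 1e-12)
  ## random fixture vs independent arithmetic for both variants
  set.seed(84)
  k2 <- data.frame(species = rep(c("a", "b", "c"), each = 3),
                   salinity_psu = 15, replicate = rep(1:3, 3))
  p <- matrix(rnorm(18), 9, 2)
  cen <- colMeans(p)
  manual_rep <- mean(sqrt(rowSums(sweep(p, 2, cen, "-")^2)))
  cents <- rbind(colMeans(p[1:3, ]), colMeans(p[4:6, ]), colMeans(p[7:9, ]))
  manual_cen <- mean(sqrt(rowSums(sweep(cents, 2, cen, "-")^2)))
  expect_equal(unname(interspecific_variability(p, k2, 2,
               "replicate_based")$variability), manual_rep, tolerance = 1e-12)
  expect_equal(unname(interspecific_variability(p, k2, 2,
               "centroid_based")$variability), manual_cen, tolerance = 1e-12)
  ## single-species salinity is flagged but still reported
  k3 <- data.frame(species = "a", salinity_psu = 30, replicate = 1:3)
  iv3 <- interspecific_variability(matrix(rnorm(6), 3, 2), k3, 2)
  expect_equal(iv3$flagged, 30)
  expect_length(iv3$variability, 1)
})

test_that("distances are invariant under rotation + translation", {
  sim <- generate_experiment(synthetic_config(seed = 85))
  tm <- build_trait_matrix(sim$records)
  e <- extended_traitscape(tm)
  sc <- e$scores[, 1:2]
  keys <- e$row_keys
  Q <- random_rotation(2, 86)
  sc_rt <- sweep(sc %*% Q, 2, c(3.7, -11), "+")
  expect_equal(species_plasticity(sc_rt, keys, 2)$plasticity,
               species_plasticity(sc, keys, 2)$plasticity,
               tolerance = 1e-10)
  expect_equal(interspecific_variability(sc_rt, keys, 2)$variability,
               interspecific_variability(sc, keys, 2)$variability,
               tolerance = 1e-10)
})

test_that("inflating replicate scatter scales plasticity exactly linearly", {
  sim <- generate_experiment(synthetic_config(seed = 87))
  tm <- build_trait_matrix(sim$records)
  e <- extended_traitscape(tm)
  sc <- e$scores[, 1:2]
  keys <- e$row_keys
  base <- species_plasticity(sc, keys, 2)$plasticity
  target <- unique(keys$species)[3]
  idx <- which(keys$species == target)
  cen <- centroid(sc[idx, , drop = FALSE])
  c_fac <- 2.5
  sc2 <- sc
  sc2[idx, ] <- sweep(sweep(sc[idx, , drop = FALSE], 2, cen, "-") * c_fac,
                      2, cen, "+")
  infl <- species_plasticity(sc2, keys, 2)$plasticity
  expect_equal(unname(infl[target]), c_fac * unname(base[target]),
               tolerance = 1e-10)
  others <- setdiff(names(base), target)
  expect_equal(infl[others], base[others], tolerance = 1e-12)
})

test_that("one-way ANOVA matches the direct sum-of-squares formulas", {
  g <- rep(c("a", "b", "c"), times = c(3, 4, 3))
  y <- c(1, 2, 3, 2, 3, 4, 5, 5, 6, 7)
  res <- one_way_anova(y, g)
  ## independent route: explicit decomposition
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  f_manual <- (ssb / 2) / (ssw / 7)
  expect_equal(res$ss_between, ssb, tolerance = 1e-10)
  expect_equal(res$ss_within, ssw, tolerance = 1e-10)
  expect_equal(res$f, f_manual, tolerance = 1e-10)
  expect_equal(res$p, pf(f_manual, 2, 7, lower.tail = FALSE),
               tolerance = 1e-10)
  ## equal group means with spread: F exactly 0
  res0 <- one_way_anova(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(res0$f, 0, tolerance = 1e-12)
  ## two groups: F equals the squared pooled-variance t statistic
  y2 <- c(1.2, 2.3, 1.8, 4.1, 3.3, 3.9)
  g2 <- rep(c("a", "b"), each = 3)
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(one_way_anova(y2, g2)$f, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_error(one_way_anova(c(1, 2), c("a", "b")), "degenerate")
})

test_that("the combined metrics object is internally consistent", {
  sim <- generate_experiment(synthetic_config(seed = 88))
  tm <- build_trait_matrix(sim$records)
  e <- extended_traitscape(tm)
  pl <- plasticity_metrics(e, n_dims = 2, variant = "centroid_based")
  expect_identical(pl$variant, "centroid_based")
  expect_true(all(pl$replicate_distances$distance >= 0))
  expect_length(pl$species_plasticity, 10)
  expect_length(pl$interspecific_variability, 6)
  expect_true(all(is.finite(unlist(pl$anova[c("f", "p", "ss_between")]))))
  ## a single-salinity trait-scape has no across-salinity contrast
  tm5 <- tm[which(tm$keys$salinity_psu == 5)]
  pl5 <- plasticity_metrics(extended_traitscape(tm5))
  expect_null(pl5$anova)
  ## dropping dead-culture rows is supported
  dead <- tm$flags != "" & grepl("dead_culture", tm$flags)
  pl2 <- plasticity_metrics(e, drop_rows = dead)
  expect_lt(length(pl2$replicate_distances$distance),
            length(pl$replicate_distances$distance) + 1)
})
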