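# Fixtures and independent oracles shared across the suite.

# A single hand-built culture record whose 15 traits can be checked against
# literal arithmetic: exact doubling fluorescence every 2 days, then plateau.
hand_record <- function() {
  samples <- data.frame(
    species = "sp_hand", salinity_psu = 5, replicate = 1,
    duration_days = 6, cell_density_per_L = 2e9,
    chla_ugL = 50, poc_ugL = 4000, pon_ugL = 700, pop_ugL = 90,
    no3_uM = 500, nh4_uM = 0.2, po4_uM = 20, si_uM = 100,
    tn_uM = 600, tp_uM = 30)
  fl <- data.frame(species = "sp_hand", salinity_psu = 5, replicate = 1,
                   day = c(0, 2, 4, 6), rfu = c(100, 250, 625, 800))
  culture_records(samples, fl)
}

# long-form data frame for a set of records (for file round-trips)
records_to_long <- function(records) {
  merge(records$fluorescence, records$samples,
        by = c("species", "salinity_psu", "replicate"), sort = FALSE)
}

# Gaussian blobs in 2-D with centers far apart relative to spread
make_blobs <- function(centers, n_per = 10, sd = 0.5, seed = 42) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
}

# Exhaustive greedy Ward oracle: at every step evaluates the within-SS
# increase of every candidate merge from scratch (no Lance-Williams) and
# applies the smallest/second-smallest original-index tie-break. Returns
# the member set merged at each step (canonical signature) and its dSS.
ward_brute <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ss <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs), "-")^2)
  }
  clusters <- as.list(seq_len(n))
  sigs <- character(n - 1)
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1)) {
      for (b in seq(a + 1, length(clusters))) {
        d <- ss(c(clusters[[a]], clusters[[b]])) -
          ss(clusters[[a]]) - ss(clusters[[b]])
        u <- sort(c(clusters[[a]], clusters[[b]]))
        better <- is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (u[1] < best$u1 || (u[1] == best$u1 && u[2] < best$u2)))
        if (better) best <- list(a = a, b = b, d = d, u1 = u[1], u2 = u[2],
                                 members = u)
      }
    }
    sigs[m] <- paste(best$members, collapse = ",")
    heights[m] <- best$d
    clusters[[best$a]] <- best$members
    clusters[[best$b]] <- NULL
  }
  list(signatures = sigs, heights = heights)
}

# canonical merge signatures of a ward_tree, comparable with ward_brute
ward_signatures <- function(tree) {
  n <- tree$n
  members <- vector("list", n - 1)
  sigs <- character(n - 1)
  for (m in seq_len(n - 1)) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[m]] <- sort(c(get(tree$merge[m, 1]), get(tree$merge[m, 2])))
    sigs[m] <- paste(members[[m]], collapse = ",")
  }
  sigs
}

# the plasticity-recovery study: 10 species identical except for a 4-fold
# range of plasticity amplitudes, sublethal salinity gradient, 10% noise
recovery_amps <- function() seq(0.25, 1, length.out = 10)

recovery_rho <- function(seed) {
  amps <- recovery_amps()
  sp <- lapply(seq_along(amps), function(i) {
    species_params(paste0("sp", i), cell_volume = 200, mu_max = 0.9,
                   s_opt = 10, s_tol = 25, plasticity_amp = amps[i])
  })
  cfg <- synthetic_config(species = sp, noise_cv = 0.10, seed = seed)
  sim <- generate_experiment(cfg)
  tm <- build_trait_matrix(sim$records)
  pl <- plasticity_metrics(extended_traitscape(tm), n_dims = "all")
  cor(amps, pl$species_plasticity[paste0("sp", seq_along(amps))],
      method = "spearman")
}

# random orthogonal matrix
random_rotation <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}
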