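## Synthetic culture-experiment generator: species-specific Gaussian
## salinity reaction norms, allometric scaling of quotas and uptake with
## cell volume, batch growth capped by nutrient exhaustion with an exact
## mass balance, a salinity-stress modifier on cell quotas (the plasticity
## signal), and multiplicative lognormal replicate noise. Ground truth for
## every latent parameter and noiseless trait is returned alongside the
## records so parameter-recovery tests can close the loop.

#' Species parameter set for the generator
#'
#' @param name species label
#' @param cell_volume cell volume, um^3 (> 0)
#' @param mu_max maximum specific growth rate, day^-1
#' @param s_opt optimal salinity, psu
#' @param s_tol salinity tolerance width (Gaussian sigma), psu
#' @param plasticity_amp amplitude of salinity-driven quota shifts,
#'   dimensionless >= 0 (fractional shift at full stress)
#' @param quota_c baseline carbon quota, ug C cell^-1; default allometric,
#'   2e-5 * (volume / 100)^0.9 (about 0.2 pg C um^-3)
#' @return an object of class `species_params`
#' @export
species_params <- function(name, cell_volume, mu_max, s_opt, s_tol,
                           plasticity_amp = 0.1, quota_c = NULL) {
  stopifnot(cell_volume > 0, mu_max > 0, s_tol > 0, plasticity_amp >= 0)
  if (is.null(quota_c)) {
    quota_c <- allometric_trait(2e-5, cell_volume, 0.9)
  }
  stopifnot(quota_c > 0)
  structure(list(name = name, cell_volume = cell_volume, mu_max = mu_max,
                 s_opt = s_opt, s_tol = s_tol,
                 plasticity_amp = plasticity_amp, quota_c = quota_c),
            class = "species_params")
}

#' Default ten-species community
#'
#' A caricature of a brackish-water culture collection spanning five orders
#' of magnitude in cell volume: a broadly euryhaline pennate diatom, a
#' larger stenohaline diatom, three dinoflagellates (one very large), two
#' cryptophytes, a small haptophyte, a freshwater-leaning chlorophyte and a
#' picocyanobacterium. Volumes follow published biovolumes for such taxa;
#' growth optima sit mostly in the brackish 2-15 psu range and plasticity
#' amplitudes span roughly four-fold. Illustrative, not inferential.
#'
#' @return list of [species_params()]
#' @export
default_species_params <- function() {
  list(
    species_params("pennate_diatom_euryhaline",  115,   1.40, 15, 30, 0.05),
    species_params("diatom_stenohaline",         567,   1.00, 10,  7, 0.12),
    species_params("dinoflagellate_large",      9039,   0.45,  8,  8, 0.15),
    species_params("dinoflagellate_mixotroph",   750,   0.50,  5,  5, 0.20),
    species_params("dinoflagellate_benthic",   96503,   0.40, 12, 10, 0.14),
    species_params("cryptophyte_marine",         382,   0.90, 15,  9, 0.10),
    species_params("cryptophyte_brackish",       400,   0.90,  8,  7, 0.11),
    species_params("haptophyte_small",            37,   1.10, 10,  8, 0.08),
    species_params("chlorophyte_freshwater",       9,   1.30,  2,  6, 0.07),
    species_params("picocyanobacterium",           5,   1.20,  8, 10, 0.09)
  )
}

#' Generator configuration
#'
#' Defaults emulate a 10-species x 6-salinity x 3-replicate mono-algal
#' batch design: salinities 0, 5, 15, 20, 30, 35 psu, fluorescence
#' monitored every 2 days to day 20, 10% multiplicative lognormal
#' measurement noise, F/2 medium.
#'
#' @param species list of [species_params()]
#' @param salinities treatment levels, psu
#' @param replicates replicate flasks per treatment
#' @param noise_cv coefficient of variation of the lognormal measurement
#'   noise applied to every observable
#' @param monitoring_days fluorescence monitoring schedule, days
#' @param seed integer random seed; all randomness flows from it
#' @param medium a [medium_spec()]
#' @param lag_days growth lag after inoculation, days
#' @param viability_frac growth below this fraction of mu_max is treated as
#'   no growth (reaction-norm floor)
#' @param don_frac,dop_frac dissolved-organic fraction of total N / total P
#' @param inoculum_biovolume inoculated biovolume, um^3 L^-1 (sets the
#'   starting cell density as biovolume / cell volume)
#' @param decay_rate fluorescence decay rate of non-growing cultures,
#'   day^-1
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(species = default_species_params(),
                             salinities = c(0, 5, 15, 20, 30, 35),
                             replicates = 3L, noise_cv = 0.10,
                             monitoring_days = seq(0, 20, by = 2),
                             seed = 1L, medium = medium_spec(),
                             lag_days = 1, viability_frac = 0.05,
                             don_frac = 0.05, dop_frac = 0.05,
                             inoculum_biovolume = 5e7, decay_rate = 0.03) {
  stopifnot(replicates >= 1, noise_cv >= 0,
            !anyDuplicated(salinities), length(monitoring_days) >= 2)
  structure(list(species = species, salinities = salinities,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 monitoring_days = monitoring_days, seed = as.integer(seed),
                 medium = medium, lag_days = lag_days,
                 viability_frac = viability_frac, don_frac = don_frac,
                 dop_frac = dop_frac,
                 inoculum_biovolume = inoculum_biovolume,
                 decay_rate = decay_rate),
            class = "synthetic_config")
}

#' Gaussian salinity reaction norm
#'
#' mu(s) = mu_max * exp(-(s - s_opt)^2 / (2 s_tol^2)), floored to exactly 0
#' below `viability_frac * mu_max` — salinities far outside the tolerance
#' are lethal, not merely slow.
#'
#' @param s salinity, psu (vectorized)
#' @param p a [species_params()]
#' @param viability_frac viability floor as a fraction of mu_max
#' @return growth rate(s), day^-1
#' @export
reaction_norm <- function(s, p, viability_frac = 0.05) {
  mu <- p$mu_max * exp(-(s - p$s_opt)^2 / (2 * p$s_tol^2))
  mu[mu < viability_frac * p$mu_max] <- 0
  mu
}

#' Allometric scaling of a trait with cell volume
#'
#' value = base * (volume / v_ref)^exponent. Conventional exponents:
#' ~0.67 for maximum uptake (surface-limited), ~0.9 for quotas.
#'
#' @param base trait value at the reference volume
#' @param volume cell volume, um^3 (> 0)
#' @param exponent scaling exponent
#' @param v_ref reference volume, um^3 (default 100)
#' @return scaled trait value
#' @export
allometric_trait <- function(base, volume, exponent, v_ref = 100) {
  stopifnot(all(volume > 0))
  base * (volume / v_ref)^exponent
}

## lognormal multiplicative noise with mean 1 and the requested CV
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Simulate one batch culture
#'
#' Exponential fluorescence growth at the reaction-norm rate after a lag,
#' capped when the cumulative N or P demand of new cells exhausts the
#' medium (stationary phase). The treatment is terminated at the first
#' monitoring day in stationary phase, after three monitoring days without
#' growth (6 days, for non-growing cultures), or at the end of the
#' schedule. Residual nutrients are mass-balanced (initial minus new cells
#' times quota); particulate pools are cells times quota under a
#' salinity-stress modifier 1 + plasticity_amp * tanh(|s - s_opt| / s_tol)
#' whose sign per quota trait is supplied in `signs`; total N/P close over
#' the inorganic + particulate pools plus a dissolved-organic fraction.
#' All observables are finally multiplied by lognormal noise drawn from the
#' current RNG stream.
#'
#' @param p a [species_params()]
#' @param s salinity, psu
#' @param cfg a [synthetic_config()]
#' @param signs named vector in {-1, +1} for quota traits c, n, p, chla
#'   (direction of the salinity-stress shift; fixed per species by the
#'   experiment seed)
#' @param replicate replicate index (bookkeeping only)
#' @return list with `sample` (one-row data frame of end-point
#'   measurements), `fluorescence` (monitoring series), and `truth`
#'   (one-row data frame of latent parameters and noiseless traits)
#' @export
simulate_culture <- function(p, s, cfg = synthetic_config(),
                             signs = c(c = 1, n = 1, p = 1, chla = 1),
                             replicate = 1L) {
  mu <- reaction_norm(s, p, cfg$viability_frac)
  vol <- p$cell_volume
  C0 <- cfg$inoculum_biovolume / vol            # cells/L
  q_c <- p$quota_c                              # ug C / cell
  q_n <- (q_c / .MW[["C"]]) / 6.625             # umol N / cell (Redfield)
  q_p <- (q_c / .MW[["C"]]) / 106               # umol P / cell
  q_chla <- 0.02 * q_c                          # ug chl-a / cell
  stress <- tanh(abs(s - p$s_opt) / p$s_tol)
  mod <- 1 + p$plasticity_amp * stress * signs[c("c", "n", "p", "chla")]
  qm_c <- q_c * mod[["c"]]; qm_n <- q_n * mod[["n"]]
  qm_p <- q_p * mod[["p"]]; qm_chla <- q_chla * mod[["chla"]]

  days <- cfg$monitoring_days
  if (mu > 0) {
    Cmax <- C0 + min(cfg$medium$no3_uM / qm_n, cfg$medium$po4_uM / qm_p)
    cells_t <- pmin(C0 * exp(mu * pmax(0, days - cfg$lag_days)), Cmax)
    stat <- which(cells_t >= Cmax * (1 - 1e-12))
    duration <- if (length(stat)) days[stat[1]] else days[length(days)]
    dead <- FALSE
  } else {
    cells_t <- C0 * exp(-cfg$decay_rate * days)
    ## no sign of growth over three consecutive monitoring days
    duration <- days[min(4L, length(days))]
    dead <- TRUE
  }
  keep <- days <= duration
  days <- days[keep]; cells_t <- cells_t[keep]
  ## physical biomass at harvest; a dead culture still carries (decaying)
  ## inoculum particulates, but no live cells are counted
  cells_phys <- cells_t[length(cells_t)]
  cells_end <- if (dead) 0 else cells_phys
  new_cells <- max(0, cells_phys - C0)

  gain <- 50  # fluorometer gain, RFU per (ug chl-a / L)
  rfu <- cells_t * qm_chla * gain

  resid_no3 <- max(0, cfg$medium$no3_uM - new_cells * qm_n)
  resid_po4 <- max(0, cfg$medium$po4_uM - new_cells * qm_p)
  resid_nh4 <- 0.1
  resid_si <- cfg$medium$si_uM
  poc <- cells_phys * qm_c
  pon_umol <- cells_phys * qm_n
  pop_umol <- cells_phys * qm_p
  chla <- cells_phys * qm_chla

  ## noise, one deterministic draw order per culture
  nz <- .lnoise(length(rfu) + 9L, cfg$noise_cv)
  rfu_o <- rfu * nz[seq_along(rfu)]
  o <- nz[length(rfu) + 1:9]
  cells_o <- cells_end * o[1]
  chla_o <- chla * o[2]
  poc_o <- poc * o[3]
  pon_o <- pon_umol * .MW[["N"]] * o[4]
  pop_o <- pop_umol * .MW[["P"]] * o[5]
  no3_o <- resid_no3 * o[6]
  nh4_o <- resid_nh4 * o[7]
  po4_o <- resid_po4 * o[8]
  si_o <- resid_si * o[9]
  ## totals close over the (noisy) measured pools, keeping TN >= inorganic N
  tn_o <- (no3_o + nh4_o + pon_o / .MW[["N"]]) / (1 - cfg$don_frac)
  tp_o <- (po4_o + pop_o / .MW[["P"]]) / (1 - cfg$dop_frac)

  sample <- data.frame(
    species = p$name, salinity_psu = s, replicate = replicate,
    strain = p$name, duration_days = duration,
    cell_density_per_L = cells_o, chla_ugL = chla_o,
    poc_ugL = poc_o, pon_ugL = pon_o, pop_ugL = pop_o,
    no3_uM = no3_o, nh4_uM = nh4_o, po4_uM = po4_o, si_uM = si_o,
    tn_uM = tn_o, tp_uM = tp_o, stringsAsFactors = FALSE)
  fluor <- data.frame(species = p$name, salinity_psu = s,
                      replicate = replicate, day = days, rfu = rfu_o)

  ## noiseless traits exactly as the derivation stage defines them
  tn_true <- (resid_no3 + resid_nh4 + pon_umol) / (1 - cfg$don_frac)
  tp_true <- (resid_po4 + pop_umol) / (1 - cfg$dop_frac)
  truth <- data.frame(
    species = p$name, salinity_psu = s, replicate = replicate,
    cell_volume = vol, mu_max = p$mu_max, s_opt = p$s_opt, s_tol = p$s_tol,
    plasticity_amp = p$plasticity_amp, dead = dead,
    sign_c = signs[["c"]], sign_n = signs[["n"]], sign_p = signs[["p"]],
    sign_chla = signs[["chla"]],
    growth_rate = mu,
    chla_per_cell = if (dead) 0 else qm_chla,
    poc_per_cell = if (dead) 0 else qm_c,
    pon_per_cell = if (dead) 0 else qm_n * .MW[["N"]],
    pop_per_cell = if (dead) 0 else qm_p * .MW[["P"]],
    cn_ratio = (qm_c / .MW[["C"]]) / qm_n,
    cp_ratio = (qm_c / .MW[["C"]]) / qm_p,
    np_ratio = qm_n / qm_p,
    no3_uptake = if (dead) 0 else
      max(0, (cfg$medium$no3_uM - resid_no3) / (cells_end * duration)),
    po4_uptake = if (dead) 0 else
      max(0, (cfg$medium$po4_uM - resid_po4) / (cells_end * duration)),
    rue_n = log10((poc / .MW[["C"]]) / tn_true),
    rue_p = log10((poc / .MW[["C"]]) / tp_true),
    poc_ugL = poc, cell_density = cells_end, chla_ugL = chla,
    stringsAsFactors = FALSE)
  list(sample = sample, fluorescence = fluor, truth = truth)
}

#' Generate a full synthetic culture experiment
#'
#' Simulates every species x salinity x replicate combination of the
#' configuration (default 10 x 6 x 3 = 180 cultures). The per-species
#' quota-shift signs are drawn once from the experiment seed; all noise
#' then flows from the same stream in a fixed culture order, so a given
#' seed yields bit-identical output.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `records` (a [culture_records()] object) and `truth`
#'   (data frame of latent parameters and noiseless traits, one row per
#'   culture)
#' @export
generate_experiment <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  signs <- lapply(cfg$species, function(p) {
    s <- sample(c(-1, 1), 4L, replace = TRUE)
    names(s) <- c("c", "n", "p", "chla")
    s
  })
  samples <- list(); fluor <- list(); truth <- list()
  k <- 0L
  for (si in seq_along(cfg$species)) {
    p <- cfg$species[[si]]
    for (s in cfg$salinities) {
      for (r in seq_len(cfg$replicates)) {
        k <- k + 1L
        out <- simulate_culture(p, s, cfg, signs[[si]], replicate = r)
        samples[[k]] <- out$sample
        fluor[[k]] <- out$fluorescence
        truth[[k]] <- out$truth
      }
    }
  }
  records <- culture_records(do.call(rbind, samples), do.call(rbind, fluor))
  truth <- do.call(rbind, truth)
  ## same canonical order as the records container
  truth <- truth[order(truth$species, truth$salinity_psu, truth$replicate), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}
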