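## Derivation of physiological traits from culture records: specific growth
## rate from the chlorophyll-a fluorescence series, per-cell quotas, molar
## C:N:P ratios, net nutrient uptake rates (batch drawdown), and resource
## use efficiencies.

#' Default trait list of the derived matrix
#'
#' Fifteen traits: specific growth rate; per-cell chl-a/C/N/P quotas; molar
#' C:N, C:P, N:P ratios; net NO3 and PO4 uptake rates; nitrogen and
#' phosphorus resource use efficiency; and three bulk biomass descriptors
#' (POC concentration, final cell density, chl-a concentration).
#'
#' @return character vector of trait names
#' @export
default_trait_names <- function() {
  c("growth_rate", "chla_per_cell", "poc_per_cell", "pon_per_cell",
    "pop_per_cell", "cn_ratio", "cp_ratio", "np_ratio",
    "no3_uptake", "po4_uptake", "rue_n", "rue_p",
    "poc_ugL", "cell_density", "chla_ugL")
}

.trait_units <- function(trait_names) {
  u <- c(growth_rate = "1/day", chla_per_cell = "ug/cell",
         poc_per_cell = "ug/cell", pon_per_cell = "ug/cell",
         pop_per_cell = "ug/cell", cn_ratio = "mol/mol",
         cp_ratio = "mol/mol", np_ratio = "mol/mol",
         no3_uptake = "umol/cell/day", po4_uptake = "umol/cell/day",
         rue_n = "log10", rue_p = "log10", poc_ugL = "ug/L",
         cell_density = "cells/L", chla_ugL = "ug/L")
  out <- u[trait_names]
  out[is.na(out)] <- ""
  names(out) <- trait_names
  out
}

#' Trait-derivation options
#'
#' @param trait_names ordered trait list (default [default_trait_names()])
#' @param log_base base of the resource-use-efficiency logarithm (default 10)
#' @param rue_unit_mode `"molar"` (POC converted to umol C L^-1) or `"mass"`
#'   (both sides in ug L^-1)
#' @param exp_phase_window minimum number of monitoring points in the
#'   exponential-phase window (default 2)
#' @param exp_phase_method `"max_slope"` (contiguous log-linear window with
#'   the steepest least-squares slope) or `"endpoints"` (first and last
#'   observation)
#' @return an object of class `trait_spec`
#' @export
trait_spec <- function(trait_names = default_trait_names(),
                       log_base = 10,
                       rue_unit_mode = c("molar", "mass"),
                       exp_phase_window = 2L,
                       exp_phase_method = c("max_slope", "endpoints")) {
  rue_unit_mode <- match.arg(rue_unit_mode)
  exp_phase_method <- match.arg(exp_phase_method)
  if (!length(trait_names) || anyDuplicated(trait_names)) {
    stop("trait_names must be non-empty and unique", call. = FALSE)
  }
  if (!is.numeric(log_base) || log_base <= 1) {
    stop("log_base must be > 1", call. = FALSE)
  }
  if (exp_phase_window < 2L) stop("exp_phase_window must be >= 2",
                                  call. = FALSE)
  structure(list(trait_names = trait_names, log_base = log_base,
                 rue_unit_mode = rue_unit_mode,
                 exp_phase_window = as.integer(exp_phase_window),
                 exp_phase_method = exp_phase_method),
            class = "trait_spec")
}

#' Linear chlorophyll-a standard curve
#'
#' @param slope concentration per fluorescence unit (> 0)
#' @param intercept concentration offset
#' @return an object of class `standard_curve`
#' @export
standard_curve <- function(slope = 1, intercept = 0) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept),
            class = "standard_curve")
}

#' Convert raw fluorescence to a chl-a concentration
#'
#' Applies the linear standard curve and floors the result at zero (a
#' blank-corrected reading below the curve's intercept is reported as no
#' detectable pigment).
#'
#' @param rfu fluorescence reading(s), >= 0
#' @param curve a [standard_curve()]
#' @return chl-a concentration(s), ug L^-1
#' @export
calibrate_chla <- function(rfu, curve = standard_curve()) {
  stopifnot(all(rfu >= 0))
  pmax(0, curve$slope * rfu + curve$intercept)
}

## OLS slope of log(rfu) on day for a window; assumes rfu > 0
.log_slope <- function(day, rfu) {
  y <- log(rfu)
  dx <- day - mean(day)
  sum(dx * (y - mean(y))) / sum(dx * dx)
}

#' Locate the exponential growth phase of a fluorescence series
#'
#' With method `"max_slope"`, scans every contiguous window of at least
#' `exp_phase_window` points whose fluorescence is strictly positive and
#' returns the one maximizing the least-squares slope of log(rfu) against
#' day; slope ties (within 1e-9 relative) are broken in favour of the
#' longest window, then the earliest start. With method `"endpoints"` the
#' window is the whole series. A series with no positive-slope window
#' returns a no-growth sentinel.
#'
#' @param series data frame with columns `day` (strictly increasing) and
#'   `rfu`
#' @param spec a [trait_spec()]
#' @return list with `no_growth` (logical), and when growth was found:
#'   `t1`, `t2` (window endpoints, days), `i`, `j` (indices), `slope`
#'   (log-linear slope, day^-1)
#' @export
detect_exponential_phase <- function(series, spec = trait_spec()) {
  day <- series$day; rfu <- series$rfu
  n <- length(day)
  w <- spec$exp_phase_window
  if (n < w) stop("fluorescence series shorter than the minimum window",
                  call. = FALSE)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing",
                                call. = FALSE)
  if (spec$exp_phase_method == "endpoints") {
    if (any(rfu <= 0)) stop("non-positive fluorescence in selected window",
                            call. = FALSE)
    sl <- .log_slope(day, rfu)
    if (sl <= 0) return(list(no_growth = TRUE))
    return(list(no_growth = FALSE, t1 = day[1], t2 = day[n],
                i = 1L, j = n, slope = sl))
  }
  tol <- 1e-9
  best <- NULL
  for (i in seq_len(n - w + 1L)) {
    for (j in seq(i + w - 1L, n)) {
      r <- rfu[i:j]
      if (any(r <= 0)) next
      sl <- .log_slope(day[i:j], r)
      if (is.null(best)) {
        best <- list(i = i, j = j, slope = sl)
        next
      }
      gap <- sl - best$slope
      scale <- max(1, abs(best$slope))
      if (gap > tol * scale) {
        best <- list(i = i, j = j, slope = sl)
      } else if (abs(gap) <= tol * scale) {
        ## tie: prefer the longer window, then the earlier start
        if ((j - i) > (best$j - best$i)) best <- list(i = i, j = j, slope = sl)
      }
    }
  }
  if (is.null(best) || best$slope <= 0) return(list(no_growth = TRUE))
  list(no_growth = FALSE, t1 = day[best$i], t2 = day[best$j],
       i = best$i, j = best$j, slope = best$slope)
}

#' Specific growth rate from a fluorescence series
#'
#' mu = (ln F2 - ln F1) / (t2 - t1) over the detected exponential-phase
#' window (fluorescence at the beginning and end of the exponential phase).
#' A series that never shows increased fluorescence yields exactly 0.
#'
#' @inheritParams detect_exponential_phase
#' @return growth rate mu, day^-1, >= 0
#' @export
growth_rate <- function(series, spec = trait_spec()) {
  if (nrow(series) < 2L) stop("series must have at least 2 points",
                              call. = FALSE)
  ph <- detect_exponential_phase(series, spec)
  if (isTRUE(ph$no_growth)) return(0)
  f1 <- series$rfu[ph$i]; f2 <- series$rfu[ph$j]
  if (f1 <= 0 || f2 <= 0) stop("non-positive fluorescence at window endpoint",
                               call. = FALSE)
  max(0, (log(f2) - log(f1)) / (ph$t2 - ph$t1))
}

#' Net nutrient uptake rate from batch drawdown
#'
#' S = (N_t0 - N_t1) / (C * dt): medium concentration minus residual at the
#' end of the incubation, normalized by final cell density and incubation
#' length. Negative drawdown (apparent release or measurement noise) is
#' clamped to exactly 0.
#'
#' @param n_t0 initial medium concentration, umol L^-1
#' @param n_t1 residual concentration at the end, umol L^-1
#' @param cell_density final cell density, cells L^-1 (> 0)
#' @param dt incubation length, days (> 0)
#' @return net uptake rate, umol cell^-1 day^-1, >= 0
#' @export
net_uptake_rate <- function(n_t0, n_t1, cell_density, dt) {
  if (any(cell_density <= 0)) {
    stop("cell_density must be > 0 (non-growing cultures take the zero-growth path)",
         call. = FALSE)
  }
  if (any(dt <= 0)) stop("dt must be > 0", call. = FALSE)
  stopifnot(all(n_t0 >= 0), all(n_t1 >= 0))
  pmax(0, (n_t0 - n_t1) / (cell_density * dt))
}

#' Resource use efficiency
#'
#' RUE = log(POC / T) where T is the total nutrient pool (TN or TP). In
#' `"molar"` mode the POC mass concentration is first converted to
#' umol C L^-1 (divide by 12.011) so both sides are molar; in `"mass"` mode
#' the nutrient pool is converted to ug L^-1 instead.
#'
#' @param poc_ugL particulate organic carbon, ug L^-1 (> 0)
#' @param total_uM total nutrient pool, umol L^-1 (> 0)
#' @param element `"N"` or `"P"` (used only for the mass-mode conversion)
#' @param spec a [trait_spec()] supplying log base and unit mode
#' @return dimensionless log ratio
#' @export
resource_use_efficiency <- function(poc_ugL, total_uM, element = c("N", "P"),
                                    spec = trait_spec()) {
  element <- match.arg(element)
  if (any(poc_ugL <= 0) || any(total_uM <= 0)) {
    stop("undefined trait: RUE requires positive POC and total nutrient",
         call. = FALSE)
  }
  if (spec$rue_unit_mode == "molar") {
    log(poc_ugL / .MW[["C"]] / total_uM, base = spec$log_base)
  } else {
    log(poc_ugL / (total_uM * .MW[[element]]), base = spec$log_base)
  }
}

#' Per-cell quota
#'
#' Bulk concentration divided by cell density.
#'
#' @param total_conc bulk concentration, ug L^-1 (>= 0)
#' @param cell_density cells L^-1 (> 0)
#' @return quota, ug cell^-1
#' @export
per_cell_quota <- function(total_conc, cell_density) {
  if (any(cell_density <= 0)) {
    stop("undefined trait: per-cell quota requires cell_density > 0",
         call. = FALSE)
  }
  stopifnot(all(total_conc >= 0))
  total_conc / cell_density
}

#' Molar C:N, C:P and N:P ratios from particulate mass concentrations
#'
#' @param poc_ugL,pon_ugL,pop_ugL particulate C, N, P, ug L^-1 (> 0)
#' @return named numeric vector `c(cn_ratio, cp_ratio, np_ratio)` of molar
#'   ratios
#' @export
stoichiometric_ratios <- function(poc_ugL, pon_ugL, pop_ugL) {
  if (any(c(poc_ugL, pon_ugL, pop_ugL) <= 0)) {
    stop("undefined trait: stoichiometric ratios require positive C, N and P",
         call. = FALSE)
  }
  cmol <- poc_ugL / .MW[["C"]]
  nmol <- pon_ugL / .MW[["N"]]
  pmol <- pop_ugL / .MW[["P"]]
  c(cn_ratio = cmol / nmol, cp_ratio = cmol / pmol, np_ratio = nmol / pmol)
}

#' Derive the trait matrix from culture records
#'
#' Computes one row of derived traits per experimental unit. Net uptake uses
#' the medium NO3 and PO4 as the time-zero concentrations and the measured
#' residuals as the endpoint. Units from cultures that died (zero final
#' cell density) get growth rate, quotas and uptake rates of exactly 0 and a
#' `dead_culture` flag; traits undefined on a unit (non-positive POC, PON or
#' POP) are set to 0 and flagged, so the matrix is always complete.
#'
#' @param records a [culture_records()] object
#' @param medium a [medium_spec()] (time-zero dissolved concentrations)
#' @param spec a [trait_spec()]
#' @return an object of class `trait_matrix`: list with `keys` (data frame
#'   species/salinity_psu/replicate), `traits` (numeric matrix), `units`,
#'   and `flags` (one semicolon-joined string per row)
#' @export
build_trait_matrix <- function(records, medium = medium_spec(),
                               spec = trait_spec()) {
  s <- records$samples
  if (!nrow(s)) stop("no culture records", call. = FALSE)
  fl <- records$fluorescence
  fkey <- paste(fl$species, fl$salinity_psu, fl$replicate, sep = "\r")
  skey <- paste(s$species, s$salinity_psu, s$replicate, sep = "\r")
  n <- nrow(s)
  tn <- spec$trait_names
  out <- matrix(NA_real_, n, length(tn), dimnames = list(NULL, tn))
  flags <- character(n)
  flag <- function(i, f) flags[i] <<- ifelse(flags[i] == "", f,
                                             paste(flags[i], f, sep = ";"))
  set <- function(i, trait, value) {
    if (trait %in% tn) out[i, trait] <<- value
  }
  for (i in seq_len(n)) {
    ser <- fl[fkey == skey[i], c("day", "rfu"), drop = FALSE]
    if (nrow(ser) < 2L) {
      stop(sprintf("derivation error: unit %s/%s/rep%s lacks a fluorescence series",
                   s$species[i], s$salinity_psu[i], s$replicate[i]),
           call. = FALSE)
    }
    mu <- growth_rate(ser, spec)
    if (mu == 0) flag(i, "zero_growth_rate")
    set(i, "growth_rate", mu)

    C <- s$cell_density_per_L[i]
    dt <- s$duration_days[i]
    dead <- !is.finite(C) || C <= 0
    if (dead) {
      flag(i, "dead_culture")
      set(i, "growth_rate", 0)
      for (q in c("chla_per_cell", "poc_per_cell", "pon_per_cell",
                  "pop_per_cell", "no3_uptake", "po4_uptake")) set(i, q, 0)
      set(i, "cell_density", 0)
    } else {
      set(i, "chla_per_cell", per_cell_quota(s$chla_ugL[i], C))
      set(i, "poc_per_cell", per_cell_quota(s$poc_ugL[i], C))
      set(i, "pon_per_cell", per_cell_quota(s$pon_ugL[i], C))
      set(i, "pop_per_cell", per_cell_quota(s$pop_ugL[i], C))
      s_no3 <- net_uptake_rate(medium$no3_uM, s$no3_uM[i], C, dt)
      s_po4 <- net_uptake_rate(medium$po4_uM, s$po4_uM[i], C, dt)
      if (s_no3 == 0 || s_po4 == 0) flag(i, "zero_clamped_uptake")
      set(i, "no3_uptake", s_no3)
      set(i, "po4_uptake", s_po4)
      set(i, "cell_density", C)
    }
    if (all(c(s$poc_ugL[i], s$pon_ugL[i], s$pop_ugL[i]) > 0)) {
      r <- stoichiometric_ratios(s$poc_ugL[i], s$pon_ugL[i], s$pop_ugL[i])
      set(i, "cn_ratio", r[["cn_ratio"]])
      set(i, "cp_ratio", r[["cp_ratio"]])
      set(i, "np_ratio", r[["np_ratio"]])
    } else {
      flag(i, "undefined_stoichiometry")
      for (q in c("cn_ratio", "cp_ratio", "np_ratio")) set(i, q, 0)
    }
    if (s$poc_ugL[i] > 0 && s$tn_uM[i] > 0 && s$tp_uM[i] > 0) {
      set(i, "rue_n", resource_use_efficiency(s$poc_ugL[i], s$tn_uM[i],
                                              "N", spec))
      set(i, "rue_p", resource_use_efficiency(s$poc_ugL[i], s$tp_uM[i],
                                              "P", spec))
    } else {
      flag(i, "undefined_rue")
      set(i, "rue_n", 0); set(i, "rue_p", 0)
    }
    set(i, "poc_ugL", s$poc_ugL[i])
    set(i, "chla_ugL", s$chla_ugL[i])
  }
  if (anyNA(out)) {
    miss <- which(is.na(out), arr.ind = TRUE)[1, ]
    stop(sprintf("derivation error: trait '%s' unavailable for record %d",
                 tn[miss[2]], miss[1]), call. = FALSE)
  }
  trait_matrix(s[, .key_cols], out, flags = flags)
}

#' Construct a trait matrix object
#'
#' @param keys data frame with columns species, salinity_psu, replicate
#' @param traits numeric matrix, one named column per trait
#' @param units optional named character vector of per-trait units
#' @param flags optional character vector of row flags
#' @return an object of class `trait_matrix`
#' @export
trait_matrix <- function(keys, traits, units = NULL, flags = NULL) {
  keys <- as.data.frame(keys)
  traits <- as.matrix(traits)
  stopifnot(nrow(keys) == nrow(traits), !is.null(colnames(traits)))
  if (anyDuplicated(paste(keys$species, keys$salinity_psu, keys$replicate))) {
    stop("row keys must be unique", call. = FALSE)
  }
  if (is.null(units)) units <- .trait_units(colnames(traits))
  if (is.null(flags)) flags <- character(nrow(traits))
  rownames(keys) <- NULL
  rownames(traits) <- NULL
  structure(list(keys = keys, traits = traits, units = units, flags = flags),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d rows x %d traits (%d flagged rows)\n",
              nrow(x$traits), ncol(x$traits), sum(x$flags != "")))
  cat("traits:", paste(colnames(x$traits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$traits)

#' @export
as.data.frame.trait_matrix <- function(x, ...) {
  cbind(x$keys, as.data.frame(x$traits), flags = x$flags)
}

#' Subset a trait matrix by row
#' @param x a `trait_matrix`
#' @param i row index vector
#' @param ... ignored
#' @export
`[.trait_matrix` <- function(x, i, ...) {
  trait_matrix(x$keys[i, , drop = FALSE], x$traits[i, , drop = FALSE],
               units = x$units, flags = x$flags[i])
}
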