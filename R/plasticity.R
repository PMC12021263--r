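## Centroid-distance statistics on trait-scape scores: species-level trait
## plasticity (mean distance of a species' replicate positions from the
## species centroid, pooled across salinities) and per-salinity
## interspecific variability (distances from the salinity centroid), plus
## the one-way ANOVA comparing variability across salinity levels.

#' Centroid of a set of score points
#'
#' @param points m x d numeric matrix (m >= 1)
#' @return d-vector of coordinate-wise means
#' @export
centroid <- function(points) {
  points <- rbind(points)
  if (!nrow(points)) stop("centroid of an empty point set", call. = FALSE)
  colMeans(points)
}

.dist_to <- function(points, center) {
  sqrt(rowSums(sweep(rbind(points), 2, center, "-")^2))
}

#' Species trait plasticity
#'
#' For each species, the mean Euclidean distance (over the first `n_dims`
#' score dimensions) of all its replicate positions — all salinities pooled
#' — from the species centroid. A species whose trait expression does not
#' move along the salinity gradient scores near zero.
#'
#' @param scores score matrix (rows x components)
#' @param keys data frame aligned with `scores`, columns `species`,
#'   `salinity_psu`, `replicate`
#' @param n_dims number of leading dimensions to use (default 2)
#' @return list with `plasticity` (named per-species means) and `distances`
#'   (data frame of every replicate distance)
#' @export
species_plasticity <- function(scores, keys, n_dims = 2L) {
  sc <- .take_dims(scores, n_dims)
  sp <- unique(keys$species)
  rows <- lapply(sp, function(s) {
    idx <- which(keys$species == s)
    d <- .dist_to(sc[idx, , drop = FALSE], centroid(sc[idx, , drop = FALSE]))
    data.frame(species = s, salinity_psu = keys$salinity_psu[idx],
               replicate = keys$replicate[idx], distance = d)
  })
  distances <- do.call(rbind, rows)
  pl <- vapply(split(distances$distance, distances$species), mean, numeric(1))
  list(plasticity = pl[sp], distances = distances)
}

#' Interspecific variability per salinity level
#'
#' Variant `"replicate_based"`: the mean distance of every replicate
#' position at a salinity from that salinity's centroid. Variant
#' `"centroid_based"`: the mean distance of the species centroids (within
#' the salinity) from the salinity centroid.
#'
#' @inheritParams species_plasticity
#' @param variant `"replicate_based"` (default) or `"centroid_based"`
#' @return list with `variability` (named per-salinity means), `distances`
#'   (underlying distances with keys), `variant`, and `flagged` (salinity
#'   levels with fewer than 2 species)
#' @export
interspecific_variability <- function(scores, keys, n_dims = 2L,
                                      variant = c("replicate_based",
                                                  "centroid_based")) {
  variant <- match.arg(variant)
  sc <- .take_dims(scores, n_dims)
  sals <- sort(unique(keys$salinity_psu))
  flagged <- numeric(0)
  rows <- lapply(sals, function(s) {
    idx <- which(keys$salinity_psu == s)
    if (length(unique(keys$species[idx])) < 2) flagged <<- c(flagged, s)
    cen <- centroid(sc[idx, , drop = FALSE])
    if (variant == "replicate_based") {
      d <- .dist_to(sc[idx, , drop = FALSE], cen)
      data.frame(salinity_psu = s, unit = paste(keys$species[idx],
                 keys$replicate[idx], sep = "@"), distance = d)
    } else {
      spl <- split(idx, keys$species[idx])
      cents <- t(vapply(spl, function(ii) {
        centroid(sc[ii, , drop = FALSE])
      }, numeric(ncol(sc))))
      d <- .dist_to(cents, cen)
      data.frame(salinity_psu = s, unit = names(spl), distance = d)
    }
  })
  distances <- do.call(rbind, rows)
  v <- vapply(split(distances$distance, distances$salinity_psu), mean,
              numeric(1))
  list(variability = v[as.character(sals)], distances = distances,
       variant = variant, flagged = flagged)
}

.take_dims <- function(scores, n_dims) {
  sc <- as.matrix(scores)
  if (identical(n_dims, "all")) return(sc)
  n_dims <- as.integer(n_dims)
  if (n_dims > ncol(sc)) {
    stop("n_dims exceeds the available components", call. = FALSE)
  }
  sc[, seq_len(n_dims), drop = FALSE]
}

#' Classical one-way fixed-effects ANOVA
#'
#' Fitted with `stats::lm`/`stats::anova`; the p-value comes from the F
#' distribution with (g - 1, n - g) degrees of freedom.
#'
#' @param values numeric response
#' @param groups group labels (>= 2 groups, n > number of groups)
#' @return list `ss_between`, `ss_within`, `f`, `p`, `df`
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  n <- length(values)
  if (g < 2 || n <= g) stop("degenerate ANOVA degrees of freedom",
                            call. = FALSE)
  tab <- stats::anova(stats::lm(values ~ groups))
  list(ss_between = tab[["Sum Sq"]][1], ss_within = tab[["Sum Sq"]][2],
       f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]))
}

#' Plasticity and interspecific-variability metrics of a trait-scape
#'
#' Computes per-species plasticity, per-salinity interspecific variability,
#' and the one-way ANOVA asking whether mean replicate-to-salinity-centroid
#' distance differs among salinity levels.
#'
#' @param scape a `traitscape` (uses its scores and row keys)
#' @param n_dims PC dimensions for all distances (default 2, the
#'   interpreted biplot plane)
#' @param variant salinity-metric variant, see [interspecific_variability()]
#' @param exclude_flagged optional character vector of row flags; rows of an
#'   accompanying `trait_matrix` are not known here, so flags must be passed
#'   as a logical mask via `drop_rows`
#' @param drop_rows optional logical/integer vector of score rows to exclude
#'   (e.g. dead cultures)
#' @return object of class `plasticity_result` with fields
#'   `species_plasticity`, `interspecific_variability`,
#'   `replicate_distances`, `anova`, `n_dims`, `variant`
#' @export
plasticity_metrics <- function(scape, n_dims = 2L,
                               variant = c("replicate_based",
                                           "centroid_based"),
                               drop_rows = NULL) {
  variant <- match.arg(variant)
  sc <- scape$scores
  keys <- scape$row_keys
  if (!is.null(drop_rows)) {
    keep <- setdiff(seq_len(nrow(sc)),
                    if (is.logical(drop_rows)) which(drop_rows) else drop_rows)
    sc <- sc[keep, , drop = FALSE]
    keys <- keys[keep, , drop = FALSE]
  }
  sp <- species_plasticity(sc, keys, n_dims)
  iv <- interspecific_variability(sc, keys, n_dims, variant)
  anova_in <- interspecific_variability(sc, keys, n_dims, "replicate_based")
  ## a single salinity level leaves nothing to compare across
  av <- if (length(unique(keys$salinity_psu)) >= 2) {
    one_way_anova(anova_in$distances$distance,
                  anova_in$distances$salinity_psu)
  } else NULL
  structure(list(species_plasticity = sp$plasticity,
                 interspecific_variability = iv$variability,
                 replicate_distances = sp$distances,
                 salinity_distances = iv$distances,
                 anova = av, n_dims = n_dims, variant = variant,
                 flagged_salinities = iv$flagged),
            class = "plasticity_result")
}

#' @export
print.plasticity_result <- function(x, ...) {
  cat(sprintf("plasticity_result (%d PC dims, %s salinity metric)\n",
              x$n_dims, x$variant))
  cat("species plasticity:\n")
  print(round(x$species_plasticity, 3))
  cat("interspecific variability per salinity:\n")
  print(round(x$interspecific_variability, 3))
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA across salinity: SS = %.4g, F = %.4g, p = %.3g\n",
                x$anova$ss_between, x$anova$f, x$anova$p))
  }
  invisible(x)
}
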