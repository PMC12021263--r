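## Standardized (correlation) PCA of the trait matrix: the "trait-scape".
## The basal trait-scape is fitted on the maintenance-salinity subset only;
## the extended trait-scape pools all salinity treatments.

## column names treated as cell size and excluded from any trait-scape:
## the species are deliberately chosen to span a wide size range, so size
## would dominate and inflate collinearity
.cell_size_cols <- c("cell_size", "cell_volume", "biovolume")

#' Center and scale trait columns
#'
#' Each column is centered to mean 0 and scaled to standard deviation 1
#' (n - 1 denominator). A zero-variance column cannot be standardized and
#' raises an error naming the trait.
#'
#' @param x numeric matrix or `trait_matrix`
#' @return list with `scaled` (matrix), `means`, `sds` (named vectors)
#' @export
standardize_traits <- function(x) {
  if (inherits(x, "trait_matrix")) x <- x$traits
  x <- as.matrix(x)
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance trait column(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(sweep(x, 2, means, "-"), 2, sds, "/")
  list(scaled = scaled, means = means, sds = sds)
}

#' Fit a PCA on a standardized matrix
#'
#' Singular value decomposition of the centered/scaled data; components are
#' the eigenvectors of the correlation matrix ordered by eigenvalue, scores
#' are the data projected on them, and explained-variance fractions are
#' eigenvalues over their total. Sign convention: the largest-magnitude
#' entry of each loading column is made positive, which fixes the otherwise
#' arbitrary component signs and makes output reproducible.
#'
#' @param x standardized numeric matrix (rows >= 2, no missing values)
#' @param n_components number of components to retain, or `"all"`
#' @param row_keys optional data frame of row identifiers carried along
#' @param trait_means,trait_sds optional standardization parameters stored
#'   for later projection
#' @return an object of class `traitscape`: loadings (traits x components,
#'   columns unit-norm), scores, `eigenvalues` and `explained_var` over all
#'   components, plus the stored standardization parameters
#' @export
fit_pca <- function(x, n_components = "all", row_keys = NULL,
                    trait_means = NULL, trait_sds = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("PCA requires at least 2 rows", call. = FALSE)
  if (anyNA(x)) stop("PCA input must have no missing values", call. = FALSE)
  sv <- svd(x)
  eig <- sv$d^2 / (n - 1)
  loadings <- sv$v
  scores <- x %*% loadings
  for (k in seq_len(ncol(loadings))) {
    m <- which.max(abs(loadings[, k]))
    if (loadings[m, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  keep <- if (identical(n_components, "all")) ncol(loadings) else {
    min(as.integer(n_components), ncol(loadings))
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  dimnames(scores) <- list(NULL, colnames(loadings))
  structure(list(
    trait_means = trait_means, trait_sds = trait_sds,
    trait_names = colnames(x),
    loadings = loadings[, seq_len(keep), drop = FALSE],
    scores = scores[, seq_len(keep), drop = FALSE],
    eigenvalues = eig,
    explained_var = eig / sum(eig),
    row_keys = row_keys,
    n_components = keep), class = "traitscape")
}

#' @export
print.traitscape <- function(x, ...) {
  ev <- x$explained_var
  cat(sprintf("traitscape: %d rows x %d traits, %d components retained\n",
              nrow(x$scores), length(x$trait_names), x$n_components))
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of total trait variance\n",
              100 * ev[1], if (length(ev) > 1) 100 * ev[2] else 0))
  invisible(x)
}

.drop_cell_size <- function(tm) {
  drop <- intersect(.cell_size_cols, colnames(tm$traits))
  if (length(drop)) {
    message("excluding cell-size column(s) from the trait-scape: ",
            paste(drop, collapse = ", "))
    keepc <- setdiff(colnames(tm$traits), drop)
    tm <- trait_matrix(tm$keys, tm$traits[, keepc, drop = FALSE],
                       flags = tm$flags)
  }
  tm
}

.fit_traitscape <- function(tm, n_components) {
  tm <- .drop_cell_size(tm)
  st <- standardize_traits(tm)
  fit_pca(st$scaled, n_components = n_components, row_keys = tm$keys,
          trait_means = st$means, trait_sds = st$sds)
}

#' Basal trait-scape: PCA at the maintenance salinity
#'
#' Fits the trait-scape on the subset of rows measured at the basal
#' (stock-maintenance) salinity, representing interspecific trait
#' variability before any salinity treatment effect. Replicates enter as
#' individual rows. Cell-size columns, if present, are excluded.
#'
#' @param tm a `trait_matrix`
#' @param basal_salinity the maintenance salinity, psu (default 5)
#' @param n_components components to retain (default all)
#' @return a `traitscape`
#' @export
basal_traitscape <- function(tm, basal_salinity = 5, n_components = "all") {
  sel <- tm$keys$salinity_psu == basal_salinity
  if (!any(sel)) stop("no rows at the basal salinity ", basal_salinity,
                      call. = FALSE)
  .fit_traitscape(tm[which(sel)], n_components)
}

#' Extended trait-scape: PCA pooling all salinity treatments
#'
#' @inheritParams basal_traitscape
#' @return a `traitscape`
#' @export
extended_traitscape <- function(tm, n_components = "all") {
  .fit_traitscape(tm, n_components)
}

#' Project new trait rows into a fitted trait-scape
#'
#' Standardizes the new rows with the trait-scape's stored means and
#' standard deviations and multiplies by its loadings, so new treatments can
#' be placed in an existing score space.
#'
#' @param scape a fitted `traitscape` (with stored standardization)
#' @param newdata numeric matrix or `trait_matrix` with the same trait set
#' @return score matrix (rows x retained components)
#' @export
project_traitscape <- function(scape, newdata) {
  if (inherits(newdata, "trait_matrix")) newdata <- newdata$traits
  newdata <- as.matrix(newdata)
  if (is.null(scape$trait_means)) {
    stop("trait-scape carries no standardization parameters", call. = FALSE)
  }
  if (!identical(colnames(newdata), scape$trait_names)) {
    if (is.null(colnames(newdata)) ||
        !all(scape$trait_names %in% colnames(newdata))) {
      stop("schema error: trait set does not match the fitted trait-scape",
           call. = FALSE)
    }
    newdata <- newdata[, scape$trait_names, drop = FALSE]
  }
  z <- sweep(sweep(newdata, 2, scape$trait_means, "-"), 2, scape$trait_sds, "/")
  z %*% scape$loadings
}
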