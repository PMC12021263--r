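## Hierarchical clustering on principal components: Ward's minimum-variance
## agglomeration on PC scores, with heights recorded as the within-cluster
## sum-of-squares increase (dSS) of each merge. The Lance-Williams update is
## implemented directly so that merge heights are dSS (not a rescaled
## distance) and ties are broken deterministically by smallest original row
## index — both part of this module's contract; stats::hclust serves as an
## independent cross-check in the test suite.

#' Ward minimum-variance linkage
#'
#' Agglomerates the rows of a score matrix, at each step merging the pair of
#' clusters whose union increases the total within-cluster sum of squares
#' the least. Heights are that increase (dSS). Ties are broken by the
#' smallest original row index contained in the candidate pair, then by the
#' second-smallest.
#'
#' @param scores numeric matrix, rows = observations (>= 2)
#' @return object of class `ward_tree`: `merge` (hclust-style two-column
#'   matrix; negative entries are singletons, positive entries earlier
#'   merges), `height` (dSS per merge, non-decreasing), `size` (cluster size
#'   created by each merge), `n`, `labels`
#' @export
ward_linkage <- function(scores) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (n < 2L) stop("Ward linkage requires at least 2 rows", call. = FALSE)
  labels <- rownames(x)
  ## dSS of merging two singletons i,j is ||x_i - x_j||^2 / 2
  D <- as.matrix(stats::dist(x))^2 / 2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1, n)
  node <- -seq_len(n)            # hclust-style node label of each slot
  rep1 <- seq_len(n)             # smallest original index in each slot
  rep2 <- rep(Inf, n)            # second-smallest original index
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    mn <- min(D[active, active])
    cand <- which(D == mn & upper.tri(D), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      ## order candidate pairs by (smallest, second-smallest) original index
      k1 <- pmin(rep1[cand[, 1]], rep1[cand[, 2]])
      k2 <- pmin(pmax(rep1[cand[, 1]], rep1[cand[, 2]]),
                 rep2[cand[, 1]], rep2[cand[, 2]])
      cand <- cand[order(k1, k2), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    if (rep1[j] < rep1[i]) { tmp <- i; i <- j; j <- tmp }
    height[m] <- mn
    merge[m, ] <- c(node[i], node[j])
    msize[m] <- size[i] + size[j]
    ## Lance-Williams update of dSS costs for the merged cluster
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      newd <- ((size[i] + size[ks]) * D[i, ks] +
               (size[j] + size[ks]) * D[j, ks] -
               size[ks] * mn) / (size[i] + size[j] + size[ks])
      D[i, ks] <- newd; D[ks, i] <- newd
    }
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    size[i] <- size[i] + size[j]
    reps <- sort(c(rep1[i], rep2[i], rep1[j], rep2[j]))
    rep1[i] <- reps[1]; rep2[i] <- reps[2]
    node[i] <- m
  }
  structure(list(merge = merge, height = height, size = msize, n = n,
                 labels = labels), class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("ward_tree: %d observations, %d merges, total within-SS %.4g\n",
              x$n, x$n - 1L, sum(x$height)))
  invisible(x)
}

#' Convert a Ward tree to a stats::hclust object
#'
#' Heights are kept as dSS; note `stats::hclust(method = "ward.D2")` reports
#' heights on the sqrt(2 dSS) scale instead.
#'
#' @param x a `ward_tree`
#' @param ... ignored
#' @return an object of class `hclust`
#' @export
as.hclust.ward_tree <- function(x, ...) {
  ord <- integer(0)
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(x$merge[node, 1]), expand(x$merge[node, 2]))
  }
  ord <- expand(x$n - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "ward-dSS",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

.merge_members <- function(tree) {
  n <- tree$n
  members <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[m]] <- c(get(tree$merge[m, 1]), get(tree$merge[m, 2]))
  }
  members
}

#' Cut a Ward tree into k clusters
#'
#' @param tree a `ward_tree`
#' @param k number of clusters, 1 <= k <= n
#' @return integer vector of cluster labels, renumbered in order of first
#'   row occurrence
#' @export
cut_ward <- function(tree, k) {
  n <- tree$n
  if (k < 1 || k > n) stop("k must be between 1 and the number of rows",
                           call. = FALSE)
  comp <- seq_len(n)
  if (k < n) {
    members <- .merge_members(tree)
    for (m in seq_len(n - k)) comp[members[[m]]] <- n + m
  }
  match(comp, unique(comp))
}

#' Between-cluster inertia gains along the merge sequence
#'
#' The gain of allowing k clusters instead of k - 1 equals the dSS height of
#' the merge that would have fused them.
#'
#' @param tree a `ward_tree`
#' @return numeric vector indexed by k = 2..n: `gains[k - 1]` is the
#'   between-inertia increase from k - 1 to k clusters
#' @export
inertia_gains <- function(tree) {
  rev(tree$height)
}

#' Suggest a cluster count from the merge tree
#'
#' Picks the k in `[k_min, k_max]` maximizing the ratio of successive
#' between-inertia gains gain(k) / gain(k + 1) — the conventional elbow
#' heuristic of hierarchical clustering on principal components. Always
#' user-overridable.
#'
#' @param tree a `ward_tree`
#' @param k_min smallest candidate (>= 2)
#' @param k_max largest candidate (< number of rows)
#' @return suggested k
#' @export
suggest_k <- function(tree, k_min = 2L, k_max = min(10L, tree$n - 2L)) {
  n <- tree$n
  if (k_min < 2L) stop("k_min must be >= 2", call. = FALSE)
  if (k_max >= n) stop("k_max must be below the number of rows", call. = FALSE)
  if (k_max < k_min) stop("empty candidate range for k", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  gain <- function(k) tree$height[n - k + 1L]
  ratio <- vapply(ks, function(k) {
    g1 <- gain(k); g2 <- gain(k + 1L)
    if (g2 <= 0) {
      if (g1 <= 0) -Inf else Inf
    } else g1 / g2
  }, numeric(1))
  ks[which.max(ratio)]
}

.wss <- function(x, assign) {
  sum(vapply(split(seq_len(nrow(x)), assign), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs), "-")^2)
  }, numeric(1)))
}

#' Consolidate a partition by centroid reassignment
#'
#' Iteratively reassigns every row to its nearest cluster centroid (the
#' refinement step of hierarchical clustering on principal components) until
#' the partition is stable or `max_iter` passes. Each pass cannot increase
#' the within-cluster sum of squares.
#'
#' @param scores numeric score matrix
#' @param assignments integer cluster labels
#' @param max_iter maximum passes (default 100)
#' @return consolidated labels, renumbered by first occurrence
#' @export
consolidate <- function(scores, assignments, max_iter = 100L) {
  x <- as.matrix(scores)
  a <- match(assignments, unique(assignments))
  for (it in seq_len(max_iter)) {
    cents <- t(vapply(split(seq_len(nrow(x)), a),
                      function(idx) colMeans(x[idx, , drop = FALSE]),
                      numeric(ncol(x))))
    d2 <- outer(rowSums(x^2), rep(1, nrow(cents))) -
      2 * x %*% t(cents) + outer(rep(1, nrow(x)), rowSums(cents^2))
    newa <- max.col(-d2, ties.method = "first")
    newa <- as.integer(sort(unique(a))[newa])
    if (all(newa == a)) break
    a <- newa
  }
  match(a, unique(a))
}

#' Describe clusters by standardized trait deviations
#'
#' For every cluster and trait, the standardized difference
#' (cluster mean - grand mean) / grand sd, ranked within cluster by absolute
#' size: the traits that most characterize each cluster come first.
#'
#' @param tm a `trait_matrix` (or numeric matrix with column names)
#' @param assignments one cluster label per row
#' @return data frame with columns cluster, trait, cluster_mean, grand_mean,
#'   std_diff, ordered by cluster then decreasing |std_diff|
#' @export
describe_clusters <- function(tm, assignments) {
  x <- if (inherits(tm, "trait_matrix")) tm$traits else as.matrix(tm)
  if (nrow(x) != length(assignments)) {
    stop("assignments length must match the number of rows", call. = FALSE)
  }
  gm <- colMeans(x)
  gs <- apply(x, 2, stats::sd)
  gs[gs <= 0] <- 1  # constant trait: deviation is 0 anyway
  out <- do.call(rbind, lapply(sort(unique(assignments)), function(cl) {
    cm <- colMeans(x[assignments == cl, , drop = FALSE])
    d <- (cm - gm) / gs
    df <- data.frame(cluster = cl, trait = colnames(x), cluster_mean = cm,
                     grand_mean = gm, std_diff = d, row.names = NULL)
    df[order(-abs(df$std_diff)), ]
  }))
  rownames(out) <- NULL
  out
}

#' Cluster a trait-scape (HCPC)
#'
#' Runs Ward linkage on the trait-scape scores — either one point per
#' replicate, or (the default, matching how species/treatment groupings are
#' usually displayed) on group centroids: mean scores per species, or per
#' species-by-salinity treatment.
#'
#' @param scape a `traitscape`
#' @param level `"centroid"` (cluster group mean scores) or `"replicate"`
#' @param group `"species"` or `"treatment"` (species x salinity); ignored
#'   at replicate level
#' @param k cluster count, or `"auto"` to use [suggest_k()]
#' @param n_dims number of leading PCs to cluster on, or `"all"`
#' @param do_consolidate apply [consolidate()] after cutting (default FALSE
#'   for determinism of the tree-based partition)
#' @param tm optional `trait_matrix` aligned with the scape rows; when given
#'   (replicate level) or aggregable (centroid level), per-cluster trait
#'   descriptions are attached
#' @return object of class `cluster_solution`: the tree, `k`, `assignments`
#'   (named by group label), `inertia_gains`, `units` (data frame of
#'   clustered units), and optional `descriptions`
#' @export
cluster_traitscape <- function(scape, level = c("centroid", "replicate"),
                               group = c("treatment", "species"),
                               k = "auto", n_dims = "all",
                               do_consolidate = FALSE, tm = NULL) {
  level <- match.arg(level)
  group <- match.arg(group)
  sc <- scape$scores
  if (!identical(n_dims, "all")) {
    sc <- sc[, seq_len(min(as.integer(n_dims), ncol(sc))), drop = FALSE]
  }
  keys <- scape$row_keys
  if (level == "centroid") {
    glab <- if (group == "species") keys$species else {
      paste(keys$species, keys$salinity_psu, sep = "@")
    }
    idx <- split(seq_len(nrow(sc)), glab)
    pts <- t(vapply(idx, function(ii) colMeans(sc[ii, , drop = FALSE]),
                    numeric(ncol(sc))))
    units <- data.frame(unit = names(idx), n = lengths(idx),
                        row.names = NULL)
  } else {
    pts <- sc
    units <- data.frame(unit = paste(keys$species, keys$salinity_psu,
                                     keys$replicate, sep = "@"),
                        n = 1L, row.names = NULL)
    rownames(pts) <- NULL
  }
  tree <- ward_linkage(pts)
  kk <- if (identical(k, "auto")) suggest_k(tree) else as.integer(k)
  a <- cut_ward(tree, kk)
  if (do_consolidate) a <- consolidate(pts, a)
  names(a) <- units$unit
  desc <- NULL
  if (!is.null(tm)) {
    if (level == "replicate") {
      desc <- describe_clusters(tm, a)
    } else {
      glab_tm <- if (group == "species") tm$keys$species else {
        paste(tm$keys$species, tm$keys$salinity_psu, sep = "@")
      }
      gidx <- split(seq_len(nrow(tm$traits)), glab_tm)
      gmat <- t(vapply(gidx, function(ii) {
        colMeans(tm$traits[ii, , drop = FALSE])
      }, numeric(ncol(tm$traits))))
      gmat <- gmat[units$unit, , drop = FALSE]
      desc <- describe_clusters(gmat, a)
    }
  }
  structure(list(tree = tree, k = kk, assignments = a,
                 inertia_gains = inertia_gains(tree), units = units,
                 level = level, group = group, descriptions = desc),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: %d %ss in %d clusters (Ward on PC scores)\n",
              length(x$assignments), x$level, x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}
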