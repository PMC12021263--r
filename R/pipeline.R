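## End-to-end orchestration: (optional) simulation -> trait derivation ->
## basal and extended trait-scapes -> Ward clustering -> plasticity metrics,
## with every artifact written as delimited text and listed, content-hashed,
## in a JSON manifest. Identical configuration + seed gives identical
## manifest hashes.

#' Default pipeline configuration
#'
#' A flat list of options governing every stage. Either `input` points at a
#' long-form culture table, or (default) the synthetic generator supplies
#' the records.
#'
#' @param out_dir output directory for all artifacts
#' @param input optional path to a culture table; `NULL` simulates instead
#' @param seed seed forwarded to the synthetic generator
#' @param synthetic a [synthetic_config()] (used when `input` is `NULL`)
#' @param trait_opts a [trait_spec()]
#' @param medium a [medium_spec()]
#' @param basal_salinity maintenance salinity for the basal trait-scape
#' @param cluster_level,cluster_group,cluster_k,consolidate clustering
#'   options, see [cluster_traitscape()]
#' @param n_dims,variant plasticity options, see [plasticity_metrics()]
#' @param figures write diagnostic figures (requires ggplot2)
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("traitscape_run_"),
                            input = NULL, seed = 1L,
                            synthetic = NULL,
                            trait_opts = trait_spec(),
                            medium = medium_spec(),
                            basal_salinity = 5,
                            cluster_level = "centroid",
                            cluster_group = "treatment",
                            cluster_k = "auto",
                            consolidate = FALSE,
                            n_dims = 2L,
                            variant = "replicate_based",
                            figures = FALSE) {
  if (is.null(synthetic)) {
    synthetic <- synthetic_config(seed = seed, medium = medium)
  }
  structure(list(out_dir = out_dir, input = input, seed = as.integer(seed),
                 synthetic = synthetic, trait_opts = trait_opts,
                 medium = medium, basal_salinity = basal_salinity,
                 cluster_level = cluster_level, cluster_group = cluster_group,
                 cluster_k = cluster_k, consolidate = consolidate,
                 n_dims = n_dims, variant = variant, figures = figures),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirroring [pipeline_config()] arguments; nested `synthetic`,
#' `medium` and `trait_opts` blocks override the corresponding defaults.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  medium <- if (is.null(y$medium)) medium_spec() else
    do.call(medium_spec, y$medium)
  trait_opts <- if (is.null(y$trait_opts)) trait_spec() else
    do.call(trait_spec, y$trait_opts)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    args <- y$synthetic
    args$medium <- medium
    syn <- do.call(synthetic_config, args)
  }
  args <- y[setdiff(names(y), c("medium", "trait_opts", "synthetic"))]
  args$medium <- medium
  args$trait_opts <- trait_opts
  args$synthetic <- syn
  do.call(pipeline_config, args)
}

.scape_tables <- function(scape, prefix, out_dir, paths) {
  sc <- cbind(scape$row_keys, as.data.frame(scape$scores))
  ld <- data.frame(trait = rownames(scape$loadings),
                   as.data.frame(scape$loadings), row.names = NULL)
  va <- data.frame(component = paste0("PC", seq_along(scape$explained_var)),
                   eigenvalue = scape$eigenvalues,
                   explained_var = scape$explained_var)
  for (nm in c("scores", "loadings", "variance")) {
    obj <- switch(nm, scores = sc, loadings = ld, variance = va)
    f <- file.path(out_dir, paste0(prefix, "_", nm, ".csv"))
    write_matrix(obj, f)
    paths <- c(paths, f)
  }
  paths
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> derive traits -> basal + extended trait-scapes ->
#' Ward clustering of the extended trait-scape -> plasticity metrics and
#' the across-salinity ANOVA. Every artifact is written under
#' `cfg$out_dir` and listed with an md5 content hash in `manifest.json`.
#' On a stage failure a `MANIFEST.partial` marker naming the stage is left
#' behind and the error is re-raised.
#'
#' @param cfg a [pipeline_config()] (or a path to a YAML config)
#' @return invisibly, a list with the in-memory results (`records`,
#'   `truth`, `tm`, `basal`, `extended`, `clusters`, `plasticity`) and the
#'   `manifest` data frame
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stage <- "setup"
  res <- tryCatch({
    stage <- "simulate"
    truth <- NULL
    if (is.null(cfg$input)) {
      sim <- generate_experiment(cfg$synthetic)
      records <- sim$records
      truth <- sim$truth
      f <- file.path(cfg$out_dir, "records.csv")
      write_culture_table(records, f); paths <- c(paths, f)
      f <- file.path(cfg$out_dir, "truth.csv")
      write_matrix(truth, f); paths <- c(paths, f)
    } else {
      if (!file.exists(cfg$input)) {
        stop("input table not found: ", cfg$input, call. = FALSE)
      }
      records <- read_culture_table(cfg$input)
    }

    stage <- "derive-traits"
    tm <- build_trait_matrix(records, cfg$medium, cfg$trait_opts)
    f <- file.path(cfg$out_dir, "traits.csv")
    write_matrix(tm, f); paths <- c(paths, f)

    stage <- "traitscape"
    basal <- basal_traitscape(tm, cfg$basal_salinity)
    extended <- extended_traitscape(tm)
    paths <- .scape_tables(basal, "basal", cfg$out_dir, paths)
    paths <- .scape_tables(extended, "extended", cfg$out_dir, paths)

    stage <- "cluster"
    clusters <- cluster_traitscape(extended, level = cfg$cluster_level,
                                   group = cfg$cluster_group,
                                   k = cfg$cluster_k,
                                   do_consolidate = cfg$consolidate, tm = tm)
    f <- file.path(cfg$out_dir, "clusters.csv")
    write_matrix(data.frame(unit = names(clusters$assignments),
                            cluster = unname(clusters$assignments)), f)
    paths <- c(paths, f)
    if (!is.null(clusters$descriptions)) {
      f <- file.path(cfg$out_dir, "cluster_descriptions.csv")
      write_matrix(clusters$descriptions, f); paths <- c(paths, f)
    }

    stage <- "plasticity"
    pl <- plasticity_metrics(extended, n_dims = cfg$n_dims,
                             variant = cfg$variant)
    f <- file.path(cfg$out_dir, "plasticity.csv")
    write_matrix(data.frame(species = names(pl$species_plasticity),
                            plasticity = unname(pl$species_plasticity)), f)
    paths <- c(paths, f)
    f <- file.path(cfg$out_dir, "interspecific_variability.csv")
    write_matrix(data.frame(
      salinity_psu = as.numeric(names(pl$interspecific_variability)),
      variability = unname(pl$interspecific_variability),
      variant = pl$variant), f)
    paths <- c(paths, f)
    f <- file.path(cfg$out_dir, "anova.csv")
    write_matrix(data.frame(ss_between = pl$anova$ss_between,
                            ss_within = pl$anova$ss_within,
                            f = pl$anova$f, p = pl$anova$p,
                            df1 = pl$anova$df[1], df2 = pl$anova$df[2]), f)
    paths <- c(paths, f)

    if (isTRUE(cfg$figures)) {
      stage <- "figures"
      paths <- c(paths, pipeline_figures(cfg$out_dir, tm, basal, extended, pl))
    }
    list(records = records, truth = truth, tm = tm, basal = basal,
         extended = extended, clusters = clusters, plasticity = pl)
  }, error = function(e) {
    writeLines(sprintf("failed at stage: %s\n%s", stage, conditionMessage(e)),
               file.path(cfg$out_dir, "MANIFEST.partial"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         row.names = NULL)
  jsonlite::write_json(list(seed = cfg$seed, files = manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Diagnostic figures for a pipeline run
#'
#' Growth rate vs salinity per species; PC1-PC2 biplots (loading arrows,
#' axes labelled with explained-variance percentages) for the basal and
#' extended trait-scapes; and per-salinity / per-species distance strip
#' plots. Plain ggplot2 styling.
#'
#' @param out_dir directory to write PNG files into
#' @param tm a `trait_matrix`
#' @param basal,extended fitted `traitscape` objects
#' @param pl a `plasticity_result`
#' @return character vector of written file paths
#' @export
pipeline_figures <- function(out_dir, tm, basal, extended, pl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("figure generation requires the ggplot2 package", call. = FALSE)
  }
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  paths <- character(0)
  save <- function(name, plot) {
    f <- file.path(out_dir, name)
    ggplot2::ggsave(f, plot, width = 7, height = 5, dpi = 150)
    paths <<- c(paths, f)
  }
  df <- as.data.frame(tm)
  save("growth_vs_salinity.png",
       gg(df, aes(salinity_psu, growth_rate, colour = species)) +
         ggplot2::stat_summary(fun = mean, geom = "line") +
         ggplot2::geom_point(alpha = 0.6) +
         ggplot2::labs(x = "Salinity (psu)", y = "Growth rate (1/day)"))
  biplot <- function(scape) {
    sc <- cbind(scape$row_keys, as.data.frame(scape$scores[, 1:2]))
    ld <- as.data.frame(scape$loadings[, 1:2])
    ld$trait <- rownames(scape$loadings)
    arrow_scale <- 0.8 * max(abs(sc$PC1), abs(sc$PC2))
    ev <- 100 * scape$explained_var[1:2]
    gg(sc, aes(PC1, PC2, colour = species)) +
      ggplot2::geom_point() +
      ggplot2::geom_segment(data = ld, inherit.aes = FALSE,
        aes(x = 0, y = 0, xend = PC1 * arrow_scale, yend = PC2 * arrow_scale),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "grey40") +
      ggplot2::geom_text(data = ld, inherit.aes = FALSE,
        aes(PC1 * arrow_scale, PC2 * arrow_scale, label = trait),
        size = 2.5, colour = "grey25") +
      ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ev[1]),
                    y = sprintf("PC2 (%.1f%%)", ev[2]))
  }
  save("basal_biplot.png", biplot(basal))
  save("extended_biplot.png", biplot(extended))
  dd <- pl$salinity_distances
  save("distance_distributions.png",
       gg(dd, aes(factor(salinity_psu), distance)) +
         ggplot2::geom_boxplot(outlier.shape = NA) +
         ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
         ggplot2::labs(x = "Salinity (psu)",
                       y = "Distance to salinity centroid"))
  paths
}
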