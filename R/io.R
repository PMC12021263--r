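## Culture-record container and delimited-table I/O.
##
## A culture experiment is stored long-form on disk: one row per monitoring
## day per replicate, with the end-of-incubation measurements repeated on
## every row of the group. In memory the records are split into a per-unit
## `samples` table and a long `fluorescence` table.

## canonical column set (strain is optional on input)
.endpoint_cols <- c(
  "duration_days", "cell_density_per_L", "chla_ugL",
  "poc_ugL", "pon_ugL", "pop_ugL",
  "no3_uM", "nh4_uM", "po4_uM", "si_uM", "tn_uM", "tp_uM"
)
.key_cols <- c("species", "salinity_psu", "replicate")
.numeric_cols <- c("salinity_psu", "replicate", "day", "rfu", .endpoint_cols)

#' Construct a culture-records object
#'
#' @param samples data frame with one row per experimental unit
#'   (species x salinity x replicate) holding the end-of-incubation
#'   measurements; columns `species`, `strain` (optional), `salinity_psu`,
#'   `replicate`, plus the measurement columns documented in
#'   [read_culture_table()].
#' @param fluorescence long data frame of the growth-monitoring series:
#'   `species`, `salinity_psu`, `replicate`, `day`, `rfu`.
#' @return an object of class `culture_records`
#' @export
culture_records <- function(samples, fluorescence) {
  samples <- as.data.frame(samples)
  fluorescence <- as.data.frame(fluorescence)
  key <- interaction(samples$species, samples$salinity_psu, samples$replicate,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (species, salinity, replicate) unit",
         call. = FALSE)
  }
  ## canonical row order so that read/write round-trips are identities
  samples <- samples[order(samples$species, samples$salinity_psu,
                           samples$replicate), , drop = FALSE]
  fl <- fluorescence[order(fluorescence$species, fluorescence$salinity_psu,
                           fluorescence$replicate, fluorescence$day), ,
                     drop = FALSE]
  rownames(fl) <- NULL
  rownames(samples) <- NULL
  ## days strictly increasing within each series
  fkey <- paste(fl$species, fl$salinity_psu, fl$replicate, sep = "\r")
  bad <- unlist(tapply(fl$day, fkey, function(d) any(diff(d) <= 0)),
                use.names = FALSE)
  if (any(bad)) {
    stop("integrity error: non-increasing monitoring days within a series",
         call. = FALSE)
  }
  structure(list(samples = samples, fluorescence = fl),
            class = "culture_records")
}

#' @export
print.culture_records <- function(x, ...) {
  cat(sprintf(
    "culture_records: %d units (%d species x %d salinities), %d fluorescence points\n",
    nrow(x$samples), length(unique(x$samples$species)),
    length(unique(x$samples$salinity_psu)), nrow(x$fluorescence)))
  invisible(x)
}

#' Read a long-form culture-experiment table
#'
#' Reads a comma- or tab-delimited text file with a header row and one row
#' per monitoring day per replicate, and groups it into a
#' [culture_records()] object. Mandatory columns: `species`, `salinity_psu`,
#' `replicate`, `day`, `rfu`, `duration_days`, `cell_density_per_L` (or
#' `cell_density_per_mL`, converted by 1e3), `chla_ugL`, `poc_ugL`,
#' `pon_ugL`, `pop_ugL`, `no3_uM`, `nh4_uM`, `po4_uM`, `si_uM`, `tn_uM`,
#' `tp_uM`. `strain` is optional. End-of-incubation columns must be constant
#' within a replicate group (the first row of the group is used).
#'
#' @param path file path
#' @param schema optional named character vector mapping canonical column
#'   names (names) to the column names used in the file (values)
#' @return a `culture_records` object with densities in cells L^-1
#' @export
read_culture_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      idx <- match(schema[[canon]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canon
    }
  }
  per_mL <- FALSE
  if (!"cell_density_per_L" %in% names(raw) &&
      "cell_density_per_mL" %in% names(raw)) {
    names(raw)[names(raw) == "cell_density_per_mL"] <- "cell_density_per_L"
    per_mL <- TRUE
  }
  needed <- c(.key_cols, "day", "rfu", .endpoint_cols)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in intersect(.numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !(is.na(raw[[cc]]) | raw[[cc]] == ""))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                   cc, bad[1]), call. = FALSE)
    }
    raw[[cc]] <- v
  }
  if (per_mL) raw$cell_density_per_L <- raw$cell_density_per_L * 1e3

  rkey <- paste(raw$species, raw$salinity_psu, raw$replicate, raw$day,
                sep = "\r")
  if (anyDuplicated(rkey)) {
    stop("integrity error: duplicate (species, salinity, replicate, day) row",
         call. = FALSE)
  }
  ukey <- paste(raw$species, raw$salinity_psu, raw$replicate, sep = "\r")
  first <- !duplicated(ukey)
  keep <- c(.key_cols, if ("strain" %in% names(raw)) "strain", .endpoint_cols)
  samples <- raw[first, keep, drop = FALSE]
  fl <- raw[, c(.key_cols, "day", "rfu")]
  culture_records(samples, fl)
}

#' Write culture records back to a long-form delimited file
#'
#' Inverse of [read_culture_table()]: one row per monitoring day with the
#' end-of-incubation columns repeated within each replicate group.
#'
#' @param records a `culture_records` object
#' @param path output file path (`.tsv` extension selects tab delimiting)
#' @export
write_culture_table <- function(records, path) {
  stopifnot(inherits(records, "culture_records"))
  long <- merge(records$fluorescence, records$samples,
                by = .key_cols, sort = FALSE)
  long <- long[order(long$species, long$salinity_psu, long$replicate,
                     long$day), , drop = FALSE]
  write_matrix(long, path)
}

#' Write a matrix or data frame as delimited text
#'
#' Writes with a header row, full double precision (15 significant digits,
#' round-trips through [read_culture_table()]/`read.csv` to below 1e-12
#' relative error) and UTF-8 encoding. Trait matrices are flattened with
#' their row keys and flags.
#'
#' @param x a matrix, data frame, or `trait_matrix`
#' @param path output path; a `.tsv` extension writes tab-separated values
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "trait_matrix")) x <- as.data.frame(x)
  x <- as.data.frame(x)
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop("refusing to write an empty table", call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(x, con, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Flag culture records that violate physical consistency
#'
#' Residual dissolved concentrations should not exceed the initial medium
#' concentration by more than a stated fraction (measurement noise), and the
#' total pools must contain at least the dissolved inorganic fraction.
#'
#' @param records a `culture_records` object
#' @param medium a [medium_spec()]
#' @param tolerance allowed fractional excess of a residual over the initial
#'   medium concentration before flagging (default 0.5)
#' @return character vector of semicolon-joined flags, one per sample row
#'   ("" when clean)
#' @export
validate_culture_records <- function(records, medium = medium_spec(),
                                     tolerance = 0.5) {
  s <- records$samples
  flags <- character(nrow(s))
  add <- function(i, f) flags[i] <<- ifelse(flags[i] == "", f,
                                            paste(flags[i], f, sep = ";"))
  over <- function(resid, init) resid > init * (1 + tolerance) + 1e-9
  add(which(over(s$no3_uM, medium$no3_uM)), "residual_no3_exceeds_medium")
  add(which(over(s$po4_uM, medium$po4_uM)), "residual_po4_exceeds_medium")
  add(which(over(s$si_uM, medium$si_uM)), "residual_si_exceeds_medium")
  add(which(s$tn_uM < s$no3_uM + s$nh4_uM - 1e-9), "tn_below_inorganic_n")
  add(which(s$tp_uM < s$po4_uM - 1e-9), "tp_below_po4")
  flags
}
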