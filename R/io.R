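# Plain-text interchange formats: ESRI ASCII grids for rasters (readable by
# any GIS), CSV for tables and posterior draws, YAML for configuration and
# run manifests.

#' Write a raster matrix as an ESRI ASCII grid
#'
#' Row 1 of the matrix is the northernmost row, matching the grid
#' convention used throughout the package.
#'
#' @param m Numeric matrix.
#' @param path Output path (conventionally `.asc`).
#' @param cellsize Cell edge length (default 1000, metres for 1 km cells).
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1000, nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  ), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  utils::write.table(format(mm, trim = TRUE, digits = 17, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_ascii_grid()] (or
#'   any conforming writer).
#' @return Numeric matrix with attributes `cellsize` and `nodata`; NODATA
#'   cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == h[["nrows"]], ncol(m) == h[["ncols"]])
  m[m == h[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- h[["cellsize"]]
  attr(m, "nodata") <- h[["nodata_value"]]
  m
}

#' Write a property map
#'
#' Emits the per-property attribute table as CSV and the property-ID
#' raster as an ASCII grid (nodata -1 marks protected cells).
#'
#' @param properties A `property_map`.
#' @param table_path CSV path for the attribute table.
#' @param id_path Path for the ID raster.
#' @return Invisibly, the two paths.
#' @export
write_property_map <- function(properties, table_path, id_path) {
  stopifnot(inherits(properties, "property_map"))
  utils::write.csv(properties$table, table_path, row.names = FALSE)
  write_ascii_grid(properties$id, id_path, nodata = -1)
  invisible(c(table_path, id_path))
}

#' Read a property map
#'
#' @param table_path,id_path Paths written by [write_property_map()].
#' @return A `property_map`.
#' @export
read_property_map <- function(table_path, id_path) {
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  required <- c("property_id", "n_cells", "area_ha", "size_class",
                "region", "lr_fraction")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("property table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$extra_protected_fraction)) {
    tab$extra_protected_fraction <- 0
  }
  id <- read_ascii_grid(id_path)
  id[is.na(id)] <- -1
  structure(list(id = matrix(as.integer(id), nrow(id), ncol(id)),
                 table = tab),
            class = "property_map")
}

#' Write posterior draws
#'
#' One CSV row per retained draw (columns `intercept` + subset, plus the
#' log-likelihood trace), with chain metadata as YAML.
#'
#' @param posterior An `nv_posterior`.
#' @param csv_path Draws CSV path.
#' @param meta_path Metadata YAML path.
#' @return Invisibly, the two paths.
#' @export
write_posterior <- function(posterior, csv_path, meta_path) {
  stopifnot(inherits(posterior, "nv_posterior"))
  df <- as.data.frame(posterior$draws)
  df$.loglik <- posterior$loglik
  utils::write.csv(df, csv_path, row.names = FALSE)
  yaml::write_yaml(list(
    subset = as.list(posterior$subset),
    acceptance_rate = posterior$acceptance_rate,
    period = as.list(posterior$period),
    config = unclass(posterior$config)
  ), meta_path)
  invisible(c(csv_path, meta_path))
}

#' Read posterior draws
#'
#' @param csv_path,meta_path Paths written by [write_posterior()].
#' @return An `nv_posterior`.
#' @export
read_posterior <- function(csv_path, meta_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  meta <- yaml::read_yaml(meta_path)
  loglik <- df$.loglik
  df$.loglik <- NULL
  cfg <- meta$config
  structure(list(subset = as.character(unlist(meta$subset)),
                 draws = as.matrix(df), loglik = loglik,
                 acceptance_rate = meta$acceptance_rate,
                 period = unlist(meta$period),
                 config = structure(cfg, class = "mcmc_config")),
            class = "nv_posterior")
}

#' Write a loss ledger as CSV
#'
#' @param ledger data.frame from [loss_ledger()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(all(c("property_id", "class", "region", "year", "loss_ha")
                %in% names(ledger)))
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}

#' Read a loss ledger CSV
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ledger <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Lossless round-trip of numeric config values through YAML: numbers are
# stored as %.17g strings and tagged, so replaying a manifest reproduces
# runs bit for bit.
.num_to_chr <- function(x) {
  if (is.data.frame(x)) {
    list(.df = lapply(as.list(x), .num_to_chr))
  } else if (is.list(x)) {
    lapply(x, .num_to_chr)
  } else if (is.double(x)) {
    out <- list(.num = as.list(sprintf("%.17g", x)))
    if (!is.null(names(x))) out$.names <- as.list(names(x))
    out
  } else {
    x
  }
}

.chr_to_num <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$.num)) {
      v <- as.numeric(unlist(x$.num))
      if (!is.null(x$.names)) names(v) <- unlist(x$.names)
      v
    } else if (!is.null(x$.df)) {
      as.data.frame(lapply(x$.df, .chr_to_num), stringsAsFactors = FALSE)
    } else {
      lapply(x, .chr_to_num)
    }
  } else {
    x
  }
}

#' Write a run manifest
#'
#' Records the full run configuration (numbers stored losslessly), the
#' package version, and MD5 checksums of every output file, so a run can be
#' replayed and verified bit for bit.
#'
#' @param config The `run_config` used.
#' @param out_dir Run directory whose files are checksummed.
#' @param path Manifest path (default `manifest.yaml` inside `out_dir`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, out_dir,
                           path = file.path(out_dir, "manifest.yaml")) {
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   basename(path))
  sums <- tools::md5sum(file.path(out_dir, files))
  yaml::write_yaml(list(
    package = "cerradosim",
    version = as.character(utils::packageVersion("cerradosim")),
    config = .num_to_chr(unclass_recursive(config)),
    checksums = stats::setNames(as.list(unname(sums)), files)
  ), path)
  invisible(path)
}

# strip S3 classes recursively so YAML serialisation is plain
unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else {
    x
  }
}

#' Read a run manifest
#'
#' @param path Manifest path.
#' @return List with `config` (reconstructed, numerics exact) and
#'   `checksums`.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  list(config = .chr_to_num(m$config),
       checksums = unlist(m$checksums),
       version = m$version)
}
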