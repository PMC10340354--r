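CONTAINER_VERSION <- "1.0"

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Read / write RF and image containers
#'
#' Single-file hierarchical containers (R serialization) holding the data
#' cube or image together with its acquisition metadata, a schema version,
#' and the hash of the producing configuration. Readers reject unknown
#' major schema versions.
#'
#' @param x An `rf_data`, `bf_image` or `raster_image` object.
#' @param path File path.
#' @param config Optional configuration list; its hash is embedded.
#' @return `write_container()` returns `path` invisibly;
#'   `read_container()` the stored object (with `container_meta` attribute).
#' @export
write_container <- function(x, path, config = NULL) {
  payload <- list(schema_version = CONTAINER_VERSION,
                  class = class(x)[1],
                  config_hash = if (is.null(config)) NA_character_
                                else config_hash(config),
                  object = x)
  saveRDS(payload, path, version = 2)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$schema_version))
    stop_flexbeam("not a flexbeam container", "io_error")
  major <- strsplit(payload$schema_version, ".", fixed = TRUE)[[1]][1]
  if (major != strsplit(CONTAINER_VERSION, ".", fixed = TRUE)[[1]][1])
    stop_flexbeam(sprintf("unsupported container schema version %s",
                          payload$schema_version), "io_error")
  obj <- payload$object
  attr(obj, "container_meta") <- payload[c("schema_version", "config_hash")]
  obj
}

#' Export a log-compressed B-mode image as PNG
#'
#' @param img A `bf_image` or `raster_image`.
#' @param path Output path.
#' @param dynamic_range_db Display dynamic range, dB.
#' @return `path`, invisibly.
#' @export
write_bmode_png <- function(img, path, dynamic_range_db = 60) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_flexbeam("the png package is required for PNG export", "io_error")
  obj <- envelope_display(img, dynamic_range_db)
  db <- obj$display
  g <- (db + dynamic_range_db) / dynamic_range_db
  g[is.na(g)] <- 0                      # out-of-region: display floor
  # image rows = axial depth, columns = lateral
  png::writePNG(t(g)[, , drop = FALSE], path)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML configuration with sections `probe`, `phantom`, `markers`,
#' `grid`, `optimize`, `output`. Unknown fields are rejected; physical
#' quantities use the package-wide units (mm, rad, Hz, m/s).
#'
#' @param path YAML file path.
#' @return Named list of class `run_config` with a `hash` attribute.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("probe", "phantom", "markers", "grid", "entropy", "optimize",
             "simulate", "output", "seed", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_flexbeam(paste("unknown config field(s):",
                        paste(bad, collapse = ", ")), "io_error")
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

probe_from_config <- function(cfg) {
  p <- cfg$probe
  if (is.null(p)) return(probe_spec())
  do.call(probe_spec, p)
}

phantom_from_config <- function(cfg) {
  ph <- cfg$phantom
  if (is.null(ph)) stop_flexbeam("config has no phantom section", "io_error")
  phantom_spec(
    point_targets = if (!is.null(ph$point_targets))
      do.call(rbind.data.frame, ph$point_targets),
    speckle = ph$speckle,
    inclusions = if (!is.null(ph$inclusions))
      do.call(rbind.data.frame, ph$inclusions))
}
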