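#' Read and validate a pipeline configuration file
#'
#' A single declarative YAML (or JSON) file drives a run: input paths, the
#' water year, the classification thresholds and the seed.  Unknown keys are
#' rejected by name, threshold ranges are checked, and defaults fill any
#' omitted threshold, so a run is fully reproducible from its config file.
#'
#' Recognised keys:
#' \describe{
#'   \item{paths}{`ndvi`, `lulc`, `slope`, `zones`, `lookup`, `output_dir`.}
#'   \item{water_year}{label such as `"2000-01"`.}
#'   \item{thresholds}{`slope_pct` (default 20), `min_irclass` (0.2),
#'     `min_separation` (0.15), `min_scm` (0.5), `sample_spacing_m` (4000).}
#'   \item{ag_codes}{LULC codes counting as agriculture.}
#'   \item{seed}{integer seed for any stochastic stage.}
#' }
#'
#' @param path YAML or JSON config file.
#' @return validated configuration list of class `pipeline_config`, with a
#'   `config_md5` attribute identifying the file content.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- validate_pipeline_config(cfg)
  attr(cfg, "config_md5") <- unname(tools::md5sum(path))
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg configuration list to validate.
#' @export
validate_pipeline_config <- function(cfg) {
  known_top <- c("paths", "water_year", "thresholds", "ag_codes", "seed")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  known_paths <- c("ndvi", "lulc", "slope", "zones", "lookup", "output_dir")
  unknown <- setdiff(names(cfg$paths), known_paths)
  if (length(unknown)) {
    stop("unknown config key(s) under paths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  th_defaults <- list(slope_pct = 20, min_irclass = 0.2,
                      min_separation = 0.15, min_scm = 0.5,
                      sample_spacing_m = 4000)
  unknown <- setdiff(names(cfg$thresholds), names(th_defaults))
  if (length(unknown)) {
    stop("unknown config key(s) under thresholds: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  th <- utils::modifyList(th_defaults, cfg$thresholds %||% list())
  stopifnot(th$slope_pct >= 0, th$min_irclass >= 0, th$min_irclass <= 1,
            th$min_separation >= 0, th$min_separation <= 2,
            th$min_scm >= -1, th$min_scm <= 1, th$sample_spacing_m > 0)
  cfg$thresholds <- th
  if (is.null(cfg$ag_codes)) cfg$ag_codes <- c(1L, 2L, 3L, 4L)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Pipeline parameters from a configuration
#'
#' @param cfg a `pipeline_config`.
#' @return a [pipeline_params()] list.
#' @export
config_params <- function(cfg) {
  pipeline_params(ag_codes = cfg$ag_codes,
                  slope_threshold_pct = cfg$thresholds$slope_pct,
                  spacing_m = cfg$thresholds$sample_spacing_m,
                  min_scm = cfg$thresholds$min_scm,
                  min_irclass = cfg$thresholds$min_irclass,
                  min_separation = cfg$thresholds$min_separation)
}
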