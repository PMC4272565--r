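# Key-value run configuration, validation, and run manifests.

# schema: known keys and their coercions
.CONFIG_SCHEMA <- list(
  w = as.integer, theta_sim = as.integer, filter_radius = as.integer,
  theta_dec = as.numeric, count_mode = as.character, allow_self = as.logical,
  m = as.numeric, g = as.numeric, a = as.numeric,
  switch_count = as.integer, target_count = as.integer,
  min_clique_size = as.integer,
  packet_size = as.integer, n_workers = as.integer,
  time_budget_s = as.numeric,
  seed = as.integer, target_specificity = as.numeric,
  target_ratio = as.numeric, matrix = as.character
)

#' Default run configuration
#'
#' @return Named list of every supported configuration key with its default.
#' @export
default_config <- function() {
  list(w = 20L, theta_sim = 35L, filter_radius = 1L, theta_dec = 0.005,
       count_mode = "per_edge", allow_self = FALSE,
       m = 0.5, g = 0.5, a = 0.5, switch_count = 20000L, target_count = 0L,
       min_clique_size = 3L,
       packet_size = 64L, n_workers = 1L, time_budget_s = Inf,
       seed = 1L, target_specificity = 0.9995, target_ratio = 100,
       matrix = "PAM120")
}

#' Read a key-value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Unknown keys are rejected; values are coerced to the schema type.
#'
#' @param path Path to the config file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!(key %in% names(.CONFIG_SCHEMA))) stop("unknown config key: ", key)
    out[[key]] <- .CONFIG_SCHEMA[[key]](val)
  }
  out
}

#' Merge configuration layers
#'
#' Later layers override earlier ones: defaults < config file < command-line
#' flags.
#'
#' @param ... Named lists of configuration values, lowest precedence first.
#' @return Merged named list (validated keys).
#' @export
merge_config <- function(...) {
  layers <- list(...)
  out <- list()
  for (layer in layers) {
    for (key in names(layer)) {
      if (!(key %in% names(.CONFIG_SCHEMA))) stop("unknown config key: ", key)
      out[[key]] <- layer[[key]]
    }
  }
  out
}

#' Write a run manifest
#'
#' Echoes the effective (merged) configuration plus the command so a run is
#' reproducible from its manifest alone. Deterministic output: no
#' timestamps.
#'
#' @param config Named list of effective configuration values.
#' @param command Character description of the subcommand and inputs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, command, path) {
  lines <- c(paste0("command = ", command),
             paste0("package_version = ", as.character(utils::packageVersion("pipeppi"))),
             vapply(sort(names(config)), function(k) {
               paste0(k, " = ", paste(format(config[[k]]), collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
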