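CONFIG_SCHEMA_VERSION <- "1.0"

.config_keys <- c("scenario", "params", "design", "model", "sweep", "output_prefix")
.params_keys <- c("r", "K", "a", "Z0")
.design_keys <- c("method", "fractions", "incubation", "P0")
.sweep_keys <- c("points", "from", "to")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    abort(sprintf("Unknown %s key(s): %s. Allowed: %s.", where,
                  paste(extra, collapse = ", "), paste(allowed, collapse = ", ")))
  }
}

#' Assemble and validate a run configuration
#'
#' A `run_config` bundles everything one invocation of the tool needs: the
#' ecological parameters, the experiment design, the bottle model, an
#' optional grazing-pressure sweep grid and an output prefix. A named
#' `scenario` preset ("low", "intermediate", "high") expands to the standard
#' Table-of-parameters values (r = 1, K = 2.2e7, a = 4.8e-5, Z0 =
#' 1000/10000/20000); explicit `params` entries override preset fields.
#'
#' @param scenario Optional scenario preset name.
#' @param params Named list with any of `r`, `K`, `a`, `Z0`. `Z0` is
#'   required when no scenario is given.
#' @param design Named list with any of `method`, `fractions`,
#'   `incubation` (days; default 1, a 24 h incubation), `P0`.
#' @param model `"logistic"` (default) or `"exponential"`.
#' @param sweep Optional named list with `points`, `from`, `to` describing
#'   an evenly spaced delta_Z grid (defaults 200 points in \[0.005, 0.995\]).
#' @param output_prefix Path prefix for files written by the CLI.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, params = list(), design = list(),
                       model = "logistic", sweep = NULL,
                       output_prefix = "zdilution") {
  check_keys(params, .params_keys, "params")
  check_keys(design, .design_keys, "design")
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, names(.scenario_Z0))
    base <- scenario_params(scenario)
    for (k in .params_keys) if (is.null(params[[k]])) params[[k]] <- base[[k]]
  }
  if (is.null(params$Z0)) {
    abort("Config must provide `params$Z0` or a `scenario` preset.")
  }
  p <- do.call(ecosystem_params, params)
  d <- do.call(experiment_design, design)
  model <- match.arg(model, c("logistic", "exponential"))
  if (!is.null(sweep)) {
    check_keys(sweep, .sweep_keys, "sweep")
    sweep <- list(points = sweep$points %||% 200,
                  from = sweep$from %||% 0.005,
                  to = sweep$to %||% 0.995)
    if (sweep$points < 2) abort("`sweep$points` must be at least 2.")
    if (sweep$from <= 0 || sweep$to >= 1 || sweep$from >= sweep$to) {
      abort("Sweep grid must satisfy 0 < from < to < 1.")
    }
  }
  structure(list(scenario = scenario, params = p, design = d, model = model,
                 sweep = sweep, output_prefix = output_prefix),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' Parses and fully validates a YAML configuration (see [run_config()] for
#' the schema). Unknown keys at any level are rejected with a message naming
#' them. Omitted fields take their documented defaults (e.g. a 1-day
#' incubation and the steady-state initial density).
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @seealso [write_config()]; floats survive the round trip to 15
#'   significant digits.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(sprintf("Cannot parse %s: %s", path,
                                                    conditionMessage(e))))
  if (!is.list(raw)) abort(sprintf("Config %s must be a YAML mapping.", path))
  check_keys(raw, .config_keys, "config")
  do.call(run_config, raw)
}

#' Write a run configuration to a YAML file
#'
#' Serialises a fully resolved `run_config` so that [load_config()]
#' reproduces it. Output is deterministic: the same configuration always
#' yields byte-identical files.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    scenario = config$scenario,
    params = unclass(config$params),
    design = unclass(config$design),
    model = config$model,
    sweep = config$sweep,
    output_prefix = config$output_prefix
  )
  x <- x[!vapply(x, is.null, logical(1))]
  atomic_write(path, yaml::as.yaml(x, precision = 15))
  invisible(path)
}

# write-to-temp-then-rename so readers never observe a partial file
atomic_write <- function(path, text) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(text, con, sep = "")
  close(con)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    abort(sprintf("Could not write %s", path))
  }
  invisible(path)
}

#' Generate the standard scenario configuration fixtures
#'
#' Writes YAML configurations for the three grazing-pressure scenarios
#' (low / intermediate / high, logistic model) plus an exponential-model
#' control in which the classical theory is exact. Regeneration is
#' deterministic and byte-identical.
#'
#' @param output_dir Directory to write into (created if needed).
#' @return Character vector of the four file paths, invisibly.
#' @export
make_fixtures <- function(output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) {
    abort(sprintf("Cannot create fixture directory: %s", output_dir))
  }
  paths <- character(0)
  for (sc in names(.scenario_Z0)) {
    path <- file.path(output_dir, paste0(sc, ".yaml"))
    write_config(run_config(scenario = sc, output_prefix = sc), path)
    paths <- c(paths, path)
  }
  path <- file.path(output_dir, "exponential-control.yaml")
  write_config(run_config(scenario = "intermediate", model = "exponential",
                          output_prefix = "exponential-control"), path)
  invisible(c(paths, path))
}
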