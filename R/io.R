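# Config parsing, CSV round-tripping and run metadata.

#' Load a run configuration
#'
#' Configurations are flat YAML: top-level run parameters plus either an
#' explicit `scenarios` list (each entry `n`, `p_treat`, `p_outcome`,
#' `true_or`, optional `seed`) or a `grid` block whose entries are vectors
#' of design levels to cross. Unknown keys are rejected with their key
#' path; invalid values (prevalences outside (0,1), non-positive odds
#' ratios) are rejected by scenario validation.
#'
#' Recognized top-level keys: `reps`, `master_seed`, `algorithms`,
#' `caliper_multipliers`, `n_cal`, `scenarios`, `grid`.
#'
#' @param path path to a YAML config file.
#' @return A list with `scenarios` (list of [scenario()] objects), `reps`,
#'   `master_seed`, `algorithms`, `caliper_multipliers`.
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yaml",
#'                                package = "matchvar"))
#' length(cfg$scenarios)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep YAML-1.1 boolean-ish scalars ("n", "y", ...) as literal strings so
  # the design key `n` survives as a key name
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) x, "bool#yes" = function(x) x))
  if (!is.list(raw)) stop("config must be a YAML mapping")
  allowed <- c("reps", "master_seed", "algorithms", "caliper_multipliers",
               "n_cal", "scenarios", "grid")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(reps = 1000, master_seed = 1L,
                   algorithms = c("caliper_random", "nn_caliper"),
                   caliper_multipliers = c(0.2, 0.01), n_cal = 1e6)
  cfg <- modifyList(defaults, raw[setdiff(names(raw), c("scenarios", "grid"))])
  for (key in c("reps", "master_seed", "caliper_multipliers", "n_cal")) {
    cfg[[key]] <- as.numeric(cfg[[key]])
    if (anyNA(cfg[[key]])) stop("config key '", key, "' must be numeric")
  }
  cfg$algorithms <- match.arg(cfg$algorithms,
                              c("caliper_random", "nn_caliper"),
                              several.ok = TRUE)
  if (!is.null(raw$scenarios) && !is.null(raw$grid)) {
    stop("config keys 'scenarios' and 'grid' are mutually exclusive")
  }
  if (!is.null(raw$grid)) {
    g <- raw$grid
    bad <- setdiff(names(g), c("n", "p_treat", "p_outcome", "true_or"))
    if (length(bad) > 0) {
      stop("unknown config key(s): ", paste0("grid.", bad, collapse = ", "))
    }
    cfg$scenarios <- scenario_grid(
      n = g$n %||% c(500, 2500, 10000),
      p_treat = g$p_treat %||% c(0.2, 0.5),
      p_outcome = g$p_outcome %||% c(0.1, 0.5),
      true_or = g$true_or %||% c(0.75, 1.0, 1.5),
      master_seed = cfg$master_seed, n_cal = cfg$n_cal
    )
  } else if (!is.null(raw$scenarios)) {
    cfg$scenarios <- lapply(seq_along(raw$scenarios), function(i) {
      s <- raw$scenarios[[i]]
      bad <- setdiff(names(s), c("n", "p_treat", "p_outcome", "true_or",
                                 "seed", "id"))
      if (length(bad) > 0) {
        stop("unknown config key(s): ",
             paste0("scenarios[", i, "].", bad, collapse = ", "))
      }
      need <- setdiff(c("n", "p_treat", "p_outcome", "true_or"), names(s))
      if (length(need) > 0) {
        stop("scenarios[", i, "] missing key(s): ",
             paste(need, collapse = ", "))
      }
      scenario(n = s$n, p_treat = s$p_treat, p_outcome = s$p_outcome,
               true_or = s$true_or, n_cal = cfg$n_cal,
               seed = s$seed %||% as.integer(cfg$master_seed + 7919L * i),
               id = s$id %||% NULL)
    })
  } else {
    stop("config must provide either 'scenarios' or 'grid'")
  }
  cfg[c("scenarios", "reps", "master_seed", "algorithms",
        "caliper_multipliers")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest
#'
#' Captures everything needed to reproduce a run: master seed, repetitions,
#' algorithms, caliper multipliers, quantile convention and a digest of the
#' scenario grid. Output files written with a manifest reference it in
#' their comment header.
#'
#' @param master_seed,R,algorithms,caliper_multipliers run parameters.
#' @param scenarios list of scenarios in the run.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(master_seed, R, algorithms, caliper_multipliers,
                         scenarios) {
  ids <- vapply(scenarios, function(s) s$id, character(1))
  structure(
    list(master_seed = as.integer(master_seed), R = as.integer(R),
         algorithms = algorithms,
         caliper_multipliers = caliper_multipliers,
         quantile_convention = "type7-linear-interpolation",
         calibration_seed = scenarios[[1]]$cal_seed,
         scenario_digest = paste(ids, collapse = ";"),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

manifest_header <- function(manifest) {
  if (is.null(manifest)) return(character(0))
  vapply(names(unclass(manifest)), function(k) {
    sprintf("# %s: %s", k, paste(format(manifest[[k]]), collapse = ","))
  }, character(1))
}

# CSV writer with full-precision floats ("%.17g"), so numeric round trips
# are bit-exact. Optional '#' comment header carries the run manifest.
write_numeric_csv <- function(df, path, manifest = NULL) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- manifest_header(manifest)
  if (length(hdr) > 0) writeLines(hdr, con)
  write.table(fmt, con, sep = ",", row.names = FALSE, quote = TRUE,
              qmethod = "double")
  invisible(path)
}

#' Write and read summary tables
#'
#' Serializes [run_grid()] / [run_scenario()] summary rows as CSV with a
#' `#`-comment metadata header (the manifest) and 17-significant-digit
#' floats, so `read_summary(write_summary(x))` reproduces every field,
#' including logical flags and `NA` markers for undefined estimates,
#' bit-exactly.
#'
#' @param rows summary data.frame (possibly zero rows).
#' @param path file path.
#' @param manifest optional [run_manifest()] recorded in the header.
#' @return `read_summary()` returns the data.frame.
#' @export
write_summary <- function(rows, path, manifest = NULL) {
  stopifnot(is.data.frame(rows))
  write_numeric_csv(rows, path, manifest = manifest)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in intersect(c("defined", "significant_low", "significant_high",
                          "successful", "valid"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname write_summary
#' @param reps per-repetition data.frame from [run_scenario()].
#' @export
write_replications <- function(reps, path, manifest = NULL) {
  stopifnot(is.data.frame(reps))
  write_numeric_csv(reps, path, manifest = manifest)
}

#' @rdname write_summary
#' @export
read_replications <- function(path) {
  read_summary(path)
}
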