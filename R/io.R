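# Plain-text input/output: choice sets and parameter configs in, study
# results and run manifests out. CSV is comma-separated with a header row;
# floats are written at full precision so round trips are exact.

#' Read a choice set from CSV
#'
#' The CSV has one row per alternative and one column per attribute.
#' Weights (and optionally availability) come either from the arguments or
#' from a sidecar JSON config with fields `weights` and `available`.
#'
#' @param path CSV file of attribute values.
#' @param weights attribute weights; overrides the config when both given.
#' @param available logical availability mask.
#' @param config optional path to a JSON sidecar config.
#' @return a [choice_set()]. Open-interval violations are reported with the
#'   offending row and column.
#' @export
read_choice_set <- function(path, weights = NULL, available = NULL,
                            config = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, header = TRUE)
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    stop(sprintf("%s: all cells must be numeric", path), call. = FALSE)
  }
  if (!is.null(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(weights)) weights <- cfg$weights
    if (is.null(available)) available <- cfg$available
  }
  if (is.null(weights)) {
    stop("attribute weights must be supplied (argument or config)",
         call. = FALSE)
  }
  choice_set(values, weights = weights, available = available)
}

#' Write a choice set's values to CSV
#'
#' @param choice_set a [choice_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_choice_set <- function(choice_set, path) {
  stopifnot(inherits(choice_set, "choice_set"))
  df <- as.data.frame(choice_set$values)
  names(df) <- paste0("attr_", seq_len(choice_set$n_attributes))
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read network parameters from a JSON or YAML config
#'
#' Recognized keys: `s_P`, `l_P`, `s_A`, `l_A`, `Q`, `T_max`,
#' `sampling_probs` (and optionally `seed`, returned as an attribute).
#'
#' @param path config file; format chosen by extension (`.json`, `.yml`,
#'   `.yaml`).
#' @return a [network_params()] with attribute `seed` when present.
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("s_P", "l_P", "s_A", "l_A", "Q")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop(sprintf("%s: missing config keys: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  p <- network_params(s_P = cfg$s_P, l_P = cfg$l_P, s_A = cfg$s_A,
                      l_A = cfg$l_A, Q = cfg$Q,
                      T_max = if (is.null(cfg$T_max)) 10000L else cfg$T_max,
                      sampling_probs = cfg$sampling_probs)
  if (!is.null(cfg$seed)) attr(p, "seed") <- cfg$seed
  p
}

#' Write study results (and a reproducibility manifest) to disk
#'
#' Writes the tabular content of a study result as CSV next to a JSON
#' manifest recording the configuration, the seed (when supplied) and the
#' package version, so the run can be reproduced from its outputs alone.
#'
#' @param x an `identification_study`, `recovery_study`,
#'   `choice_probabilities` object, or a plain data frame.
#' @param path output CSV path; the manifest goes to `<path>.manifest.json`.
#' @param seed the seed used for the run, echoed into the manifest.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NULL) {
  UseMethod("write_results")
}

write_manifest <- function(x, path, seed, extra = list()) {
  manifest <- c(list(class = class(x)[1L],
                     package_version = as.character(packageVersion("lcanet")),
                     seed = seed, written = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                extra)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' @export
write_results.identification_study <- function(x, path, seed = NULL) {
  df <- as.data.frame.table(x$accuracy, responseName = "accuracy")
  names(df)[1:2] <- c("implemented", "idealized")
  df$evaluated_sets <- x$evaluated_sets[as.character(df$idealized)]
  write.csv(df, path, row.names = FALSE)
  write_manifest(x, path, seed,
                 list(n_sets = x$n_sets, n_reps = x$n_reps, config = x$config))
  invisible(path)
}

#' @export
write_results.recovery_study <- function(x, path, seed = NULL) {
  write.csv(x$uniqueness, path, row.names = FALSE)
  write_manifest(x, path, seed,
                 list(n_reps = x$n_reps, n_combos = nrow(x$grid),
                      config = x$config))
  invisible(path)
}

#' @export
write_results.choice_probabilities <- function(x, path, seed = NULL) {
  df <- data.frame(alternative = seq_along(x$prob), probability = x$prob)
  write.csv(df, path, row.names = FALSE)
  write_manifest(x, path, seed,
                 list(n_reps = x$n_reps,
                      mean_decision_time = x$mean_decision_time,
                      censor_rate = x$censor_rate))
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, seed = NULL) {
  write.csv(x, path, row.names = FALSE)
  write_manifest(x, path, seed, list())
  invisible(path)
}

#' Write the canonical demo fixtures
#'
#' Emits the worked-example inputs used throughout the documentation and
#' tests: the canonical attribute vector (0.75, 0.5, 0.25), the study weight
#' sets (0.03, 0.015, 0.01) and (0.01, 0.01, 0.01), and a seeded batch of
#' uniform random choice sets. Byte-identical for a given seed.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the random choice-set batch.
#' @param n_sets number of random sets in the batch.
#' @return named list of written file paths, invisibly.
#' @export
make_fixtures <- function(dir = tempdir(), seed = 1L, n_sets = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  canonical <- file.path(dir, "canonical_inputs.csv")
  write.csv(data.frame(attr_1 = c(0.75, 0.5, 0.25)), canonical,
            row.names = FALSE, quote = FALSE)
  weights <- file.path(dir, "weights.json")
  jsonlite::write_json(list(proportional = c(0.03, 0.015, 0.01),
                            equal = c(0.01, 0.01, 0.01)),
                       weights, digits = NA, pretty = TRUE)
  set.seed(seed)
  sets <- generate_choice_sets(n_sets, 3, 3, weights = c(0.03, 0.015, 0.01))
  set_paths <- vapply(seq_along(sets), function(i) {
    p <- file.path(dir, sprintf("choice_set_%02d.csv", i))
    write_choice_set(sets[[i]], p)
    p
  }, character(1))
  invisible(list(canonical = canonical, weights = weights,
                 choice_sets = set_paths))
}
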