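#' Write and read tabular results
#'
#' CSV round trip at 15 significant digits. `write_results()` accepts any
#' data.frame (trajectories, response curves, velocity scans, survey
#' tables); `read_results()` reads it back, reporting the offending line
#' on a parse failure.
#'
#' @param tab a data.frame.
#' @param path file path.
#' @return `write_results()` the path, invisibly; `read_results()` a
#'   data.frame.
#' @export
write_results <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tryCatch(read.csv(path, stringsAsFactors = FALSE),
           error = function(e) {
             stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
           })
}

#' Write a JSON summary
#'
#' @param x a named list of summary quantities (scalars, vectors, tables).
#' @param path file path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# Allowed keys of the YAML run configuration, per block.
config_schema <- function() {
  list(model = NA,
       seed = NA,
       output_dir = NA,
       params = names(formals(feedback_params)),
       modulation = names(formals(switch_modulation)),
       mitotic = names(formals(mitotic_params)),
       experiment = c("k_X", "t_end", "dt_out", "sigma", "dt", "omega",
                      "replicates", "delta_a_values", "kappa_values",
                      "tau", "delta", "full_model", "a_values", "X_T",
                      "D_X", "D_Y", "L", "dx", "n_sets", "k_X_grid",
                      "delta_a_grid", "a_bar", "kappa", "high_a", "low_a",
                      "flip_time", "what", "range", "vary", "a_grid"))
}

#' Read and validate a run configuration
#'
#' The configuration is a single YAML file with blocks `model`, `params`,
#' `modulation`, `mitotic`, `experiment`, plus `seed` and `output_dir`.
#' Unknown keys are rejected, naming the first violation.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stop(sprintf("config error: unknown top-level key '%s'", bad[1]))
  for (blk in names(cfg)) {
    allowed <- schema[[blk]]
    if (length(allowed) == 1 && is.na(allowed[1])) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad))
      stop(sprintf("config error: unknown key '%s' in block '%s'",
                   bad[1], blk))
  }
  cfg
}
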