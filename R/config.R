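#' Run configuration with the framework's canonical thresholds
#'
#' Every tunable threshold lives in one declarative configuration: the strain
#' gate (ANI >= 99.8, CI lower >= 99.5), the ground-truth alignment filter
#' (identity >= 99, length within 99-101% of the contig), the recoverable
#' gates (recall >= 0.7, precision >= 0.9), the expected-coverage filter
#' (>= 2.5x), the strain-cluster cap (3), sketching parameters (k = 21,
#' sketch size 1000), and the partial multi-sample context size (D = 20).
#' Overrides are recorded in the returned object.
#'
#' @param ... Named overrides of any default, e.g. `ani_gate = 99.9` or
#'   `binning_mode = "multi"`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    ani_gate = 99.8, ci_gate = 99.5,
    identity_gate = 99, length_gate = c(0.99, 1.01),
    recall_gate = 0.7, precision_gate = 0.9,
    coverage_gate = 2.5, max_strains = 3L,
    k = 21L, sketch_size = 1000L, hash_seed = 42L, D = 20L,
    read_length = 126L, insert_mean = 300L, insert_sd = 25L,
    error_rate = 0, count_mode = "pairs", length_weighted = FALSE,
    binning_mode = "single", seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  if (!cfg$binning_mode %in% c("single", "multi", "partial_multi")) {
    stop("binning_mode must be single, multi, or partial_multi")
  }
  structure(c(cfg, list(.overridden = names(overrides))), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), ".overridden")) {
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "),
        if (nm %in% x$.overridden) "  [override]" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' The effective configuration (defaults merged with the file) is fully
#' serializable, so a run's output directory can carry its exact thresholds.
#'
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @return The path (write) or a `run_config` (read).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[setdiff(names(cfg), ".overridden")], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$length_gate)) vals$length_gate <- as.numeric(vals$length_gate)
  do.call(run_config, vals)
}

#' Declare an external pipeline task
#'
#' Task interfaces describe how an external assembler, binner, or QC tool
#' would be invoked: a command template with `{placeholder}` fields plus its
#' declared inputs and outputs. Templates are rendered, never executed, by
#' this package; the corresponding adapter validates the tool's outputs.
#'
#' @param kind `"assembly"`, `"binning"`, or `"qc"`.
#' @param name Tool label.
#' @param command_template Command string with `{placeholders}`.
#' @param inputs,outputs Character vectors of placeholder names.
#' @return A `task_interface`.
#' @export
task_interface <- function(kind = c("assembly", "binning", "qc"), name,
                           command_template, inputs = character(0),
                           outputs = character(0)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, name = name,
                 command_template = command_template,
                 inputs = inputs, outputs = outputs),
            class = "task_interface")
}

#' Render a task command from parameters
#'
#' @param task A `task_interface`.
#' @param params Named list of placeholder values.
#' @return The command string.
#' @export
render_task <- function(task, params) {
  cmd <- task$command_template
  for (nm in names(params)) {
    cmd <- gsub(paste0("{", nm, "}"), params[[nm]], cmd, fixed = TRUE)
  }
  left <- regmatches(cmd, gregexpr("\\{[a-zA-Z0-9_]+\\}", cmd))[[1]]
  if (length(left) > 0) {
    stop("unfilled placeholder(s) in task command: ", paste(left, collapse = ", "))
  }
  cmd
}
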