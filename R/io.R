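# Batch-run glue: config files, TSV outputs, run manifests, and the
# function surface behind the thin command-line wrapper in inst/cli/.
# All tables are tab-delimited with a header row and "." for missing.

#' Read and write run configurations
#'
#' Configurations round-trip losslessly through a YAML file; reading
#' re-validates every field and errors with the offending field's name.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("model", "L", "n_landscapes", "master_seed")
  for (f in required) {
    if (is.null(raw[[f]])) {
      stop("config file is missing required field `", f, "`", call. = FALSE)
    }
  }
  do.call(run_config, raw)
}

write_tsv_dot <- function(x, path) {
  readr::write_tsv(x, path, na = ".")
}

#' Simulate a batch run and write its result files
#'
#' Runs [simulate_walk_ensemble()] and writes `walks.tsv`, `records.tsv`,
#' `controls.tsv`, and a `manifest.yaml` recording the configuration, the
#' master seed, the package version, and a timestamp (the only
#' non-deterministic output byte). With `n_landscapes = 0` the tables are
#' empty but carry valid headers.
#'
#' @param config A [run_config()].
#' @param output_dir Directory to create/write into.
#' @return The `walk_ensemble`, invisibly.
#' @export
cmd_simulate <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ens <- simulate_walk_ensemble(config)
  write_tsv_dot(dplyr::relocate(ens$walks, "landscape", "walk"),
                file.path(output_dir, "walks.tsv"))
  write_tsv_dot(dplyr::relocate(ens$records, "landscape", "walk", "step"),
                file.path(output_dir, "records.tsv"))
  write_tsv_dot(ens$controls, file.path(output_dir, "controls.tsv"))
  write_manifest(config, output_dir)
  invisible(ens)
}

#' Sample stratified quadruples and write them
#'
#' Draws `n_per_stratum` walk-convention quadruples per fitness quartile
#' across the configured landscape ensemble and writes `quadruples.tsv`
#' plus a manifest.
#'
#' @inheritParams cmd_simulate
#' @param n_per_stratum Quadruples per quartile.
#' @return The `quartile_freq` table, invisibly.
#' @export
cmd_sample_quadruples <- function(config, output_dir, n_per_stratum = 2000) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  qf <- epistasis_by_quartile(config, n_per_stratum, scale = config$scale)
  write_tsv_dot(qf, file.path(output_dir, "quadruples.tsv"))
  write_manifest(config, output_dir)
  invisible(qf)
}

write_manifest <- function(config, output_dir) {
  yaml::write_yaml(
    list(config = unclass(config),
         package = "epiwalk",
         version = as.character(utils::packageVersion("epiwalk")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(output_dir, "manifest.yaml"))
}

#' Summarize batch-run outputs
#'
#' Dispatches to the aggregation analyses on files written by
#' [cmd_simulate()]: `"by_step"` tabulates epistasis frequencies per walk
#' step from `records.tsv`; `"intervals"` computes the early/late
#' percentile intervals from `records.tsv` + `controls.tsv`; `"by_quartile"`
#' re-emits a `quadruples.tsv` produced by [cmd_sample_quadruples()].
#'
#' @param input_dir Directory holding the simulate outputs.
#' @param experiment `"by_step"`, `"by_quartile"`, or `"intervals"`.
#' @param scale Epsilon scale for labels.
#' @param output Optional path for the summary TSV.
#' @return The summary tibble.
#' @export
cmd_summarize <- function(input_dir,
                          experiment = c("by_step", "by_quartile", "intervals"),
                          scale = "multiplicative", output = NULL) {
  experiment <- match.arg(experiment)
  read_records <- function() {
    path <- file.path(input_dir, "records.tsv")
    rec <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
    lv <- c("sign", "synergistic", "antagonistic", "none", "degenerate")
    rec$label_mult <- factor(rec$label_mult, levels = lv)
    rec$label_add <- factor(rec$label_add, levels = lv)
    rec
  }
  out <- switch(
    experiment,
    by_step = epistasis_by_step(read_records(), scale = scale),
    by_quartile = {
      path <- file.path(input_dir, "quadruples.tsv")
      if (!file.exists(path)) {
        stop("no quadruples.tsv in ", input_dir,
             "; run cmd_sample_quadruples() first", call. = FALSE)
      }
      readr::read_tsv(path, na = ".", show_col_types = FALSE)
    },
    intervals = {
      rec <- read_records()
      ctrl <- readr::read_tsv(file.path(input_dir, "controls.tsv"), na = ".",
                              show_col_types = FALSE)
      ens <- structure(list(records = rec, controls = ctrl), class = "walk_ensemble")
      dplyr::bind_rows(
        dplyr::mutate(mean_regression_intervals(ens, "early"), window = "early"),
        tryCatch(
          dplyr::mutate(mean_regression_intervals(ens, "late"), window = "late"),
          error = function(e) tibble::tibble())
      )
    }
  )
  if (!is.null(output)) write_tsv_dot(out, output)
  out
}
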