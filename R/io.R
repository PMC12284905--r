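# Configuration loading/validation and structured output.

.campaign_keys <- c("replicates", "years", "carryover", "base_seed")

#' Load a scenario configuration
#'
#' Reads a YAML or JSON file whose keys mirror the [model_params()] field
#' names one-to-one, applies command-line style overrides, validates the
#' result, and splits off campaign-level keys (`replicates`, `years`,
#' `carryover`, `base_seed`). An empty or missing file yields the defaults.
#'
#' If `sigma_fm + sigma_md` does not match a supplied `sigma_total`, the two
#' components are rescaled to the new total keeping their proportions (e.g.
#' total 1 with components 0.9/0.1 moved to total 0.5 becomes 0.45/0.05);
#' components summing to zero cannot be rescaled and raise an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL`.
#' @param overrides named list applied on top of the file values.
#' @return list with `params` (a `wolb_params`) and `campaign` (named list of
#'   campaign keys present).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    cfg <- switch(ext,
                  yaml = , yml = yaml::read_yaml(path),
                  json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                  stop("unsupported config format: .", ext, call. = FALSE))
    if (is.null(cfg)) cfg <- list()
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  known <- c(names(formals(model_params)), .campaign_keys)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  campaign <- cfg[intersect(names(cfg), .campaign_keys)]
  cfg <- cfg[setdiff(names(cfg), .campaign_keys)]
  # rescale CI components to a requested total, keeping proportions
  if (!is.null(cfg$sigma_total) &&
      (!is.null(cfg$sigma_fm) || !is.null(cfg$sigma_md))) {
    fm <- if (is.null(cfg$sigma_fm)) 0 else cfg$sigma_fm
    md <- if (is.null(cfg$sigma_md)) 0 else cfg$sigma_md
    tot <- fm + md
    if (abs(tot - cfg$sigma_total) > 1e-8) {
      if (tot <= 0)
        stop("cannot rescale sigma_fm/sigma_md summing to 0 to a non-zero sigma_total",
             call. = FALSE)
      cfg$sigma_fm <- cfg$sigma_total * fm / tot
      cfg$sigma_md <- cfg$sigma_total * md / tot
    }
  }
  params <- do.call(model_params, cfg)
  list(params = params, campaign = campaign)
}

#' Write simulation records as CSV (with an optional JSON manifest)
#'
#' Writes a data frame of records with a fixed header order and full float
#' precision; when a manifest is supplied it is written alongside as
#' `<path>.manifest.json`.
#'
#' @param records non-empty data frame (e.g. per-day records of a campaign).
#' @param path output CSV path.
#' @param manifest optional named list (see [run_manifest()]).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, manifest = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame", call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reproducibility manifest of a run
#'
#' Captures everything needed to reproduce a campaign bit-for-bit: the
#' resolved parameters, package version, base seed and the derived
#' per-replicate seeds, timestamps and the output file inventory.
#'
#' @param params the resolved [model_params()].
#' @param base_seed integer base seed.
#' @param replicates number of replicates.
#' @param outputs character vector of output files.
#' @return a named list.
#' @export
run_manifest <- function(params, base_seed, replicates, outputs = character()) {
  list(package = "wolbsim",
       version = as.character(utils::packageVersion("wolbsim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       base_seed = base_seed,
       replicate_seeds = base_seed + seq_len(replicates),
       params = unclass(params)[!vapply(unclass(params), is.null, logical(1))],
       outputs = outputs)
}
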