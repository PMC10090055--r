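#' @name table_io
#' @title Delimited-table readers and writers
#' @description Readers check the exact header of each table type before
#'   parsing; writers emit plain CSV without quoting or row names. Synthetic
#'   tables are written together with a ground-truth JSON sidecar.
NULL

table_headers <- list(
  traps = c("deployment_id", "cruise", "depth_m", "flux_mean_mmolC_m2_d",
            "flux_sd_mmolC_m2_d", "n_reps", "euphotic_depth_m"),
  tows = c("experiment_id", "taxon", "size_bin", "stratum_top_m",
           "stratum_bottom_m", "day_night", "biomass_mgC_m3", "temperature_C"),
  fish = c("experiment_id", "total_respiration_mmolC_m2_d"),
  subduction = c("experiment_id", "depth_m", "flux_mmolC_m2_d",
                 "euphotic_depth_m"),
  fates = c("release_depth_m", "fate", "elapsed_time_yr", "final_depth_m",
            "cohort"),
  metrics = c("experiment_id", "sst_C", "surface_nitrate_uM",
              "surface_chl_mg_m3", "npp_mmolC_m2_d", "euphotic_depth_m"))

read_table_checked <- function(path, type) {
  expected <- table_headers[[type]]
  got <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(got, expected))
    stopf("%s: expected header '%s' but found '%s'", path,
          paste(expected, collapse = ","), paste(got, collapse = ","))
  read.csv(path, check.names = FALSE)
}

#' @rdname table_io
#' @param path file path.
#' @export
read_trap_csv <- function(path) read_table_checked(path, "traps")

#' @rdname table_io
#' @export
read_tow_csv <- function(path) read_table_checked(path, "tows")

#' @rdname table_io
#' @export
read_fish_csv <- function(path) read_table_checked(path, "fish")

#' @rdname table_io
#' @export
read_subduction_csv <- function(path) read_table_checked(path, "subduction")

#' @rdname table_io
#' @export
read_fates_csv <- function(path) read_table_checked(path, "fates")

#' @rdname table_io
#' @export
read_metrics_csv <- function(path) read_table_checked(path, "metrics")

#' @rdname table_io
#' @param x data frame to write.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate input tables against their schemas
#'
#' Checks headers, non-negativity of flux and biomass columns, monotone
#' depth grids and fate labels, returning a machine-readable violation list
#' rather than erroring.
#'
#' @param paths named list/vector of file paths; names among `traps`,
#'   `tows`, `fish`, `subduction`, `fates`, `metrics`.
#' @return data frame `table`, `row`, `field`, `message` (zero rows when
#'   everything is well-formed).
#' @export
validate_tables <- function(paths) {
  violations <- list()
  note <- function(table, row, field, msg)
    violations[[length(violations) + 1L]] <<- data.frame(
      table = table, row = row, field = field, message = msg)
  for (nm in names(paths)) {
    if (!nm %in% names(table_headers)) {
      note(nm, NA, NA, sprintf("unknown table type '%s'", nm))
      next
    }
    if (!file.exists(paths[[nm]])) {
      note(nm, NA, NA, sprintf("file '%s' does not exist", paths[[nm]]))
      next
    }
    got <- names(read.csv(paths[[nm]], nrows = 1, check.names = FALSE))
    if (!identical(got, table_headers[[nm]])) {
      note(nm, NA, "header",
           sprintf("expected '%s', found '%s'",
                   paste(table_headers[[nm]], collapse = ","),
                   paste(got, collapse = ",")))
      next
    }
    tab <- read.csv(paths[[nm]], check.names = FALSE)
    nonneg <- intersect(names(tab), c("flux_mean_mmolC_m2_d", "flux_sd_mmolC_m2_d",
                                      "flux_mmolC_m2_d", "biomass_mgC_m3",
                                      "total_respiration_mmolC_m2_d"))
    for (col in nonneg) {
      bad <- which(tab[[col]] < 0)
      for (r in bad) note(nm, r, col, "negative value")
    }
    if (nm == "fates") {
      bad <- which(!tab$fate %in% c("mixed_layer", "survived", "boundary"))
      for (r in bad) note(nm, r, "fate", sprintf("unknown fate '%s'", tab$fate[r]))
    }
    if (nm == "subduction") {
      for (e in unique(tab$experiment_id)) {
        z <- tab$depth_m[tab$experiment_id == e]
        if (is.unsorted(z, strictly = TRUE))
          note(nm, NA, "depth_m",
               sprintf("depths not strictly increasing in experiment %s", e))
      }
    }
    if (nm == "tows") {
      bad <- which(!tab$day_night %in% c("day", "night"))
      for (r in bad) note(nm, r, "day_night",
                          sprintf("unknown phase '%s'", tab$day_night[r]))
    }
  }
  if (length(violations)) do.call(rbind, violations)
  else data.frame(table = character(), row = integer(), field = character(),
                  message = character())
}

#' Write synthetic tables and their ground-truth sidecars
#'
#' @param synth output of a generator (list with a table and a `truth`
#'   element) or a full [run_pipeline()] synthetic bundle.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the paths written.
#' @export
write_synthetic_table <- function(synth, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab_name <- setdiff(names(synth), "truth")[1]
  csv <- file.path(dir, paste0(name, ".csv"))
  json <- file.path(dir, paste0(name, "_truth.json"))
  write_table_csv(synth[[tab_name]], csv)
  jsonlite::write_json(synth$truth, json, digits = NA, dataframe = "columns")
  invisible(c(csv, json))
}
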