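# CSV reading/writing for the long measurement-table schema.

measurement_columns <- function() {
  c("participant_id", "t_days", "lesion_id", "d1_cm", "d2_cm",
    "base_volume_cm3", "cyst_in_solid_cm3", "whole_volume_cm3",
    "total_cyst_cm3", "new_lesion", "btrads_reader1", "btrads_reader2")
}

#' Read a long-format measurement table
#'
#' One row per lesion per image. Required columns: `participant_id`, `t_days`,
#' `lesion_id`, `d1_cm`, `d2_cm`, `base_volume_cm3`, `cyst_in_solid_cm3`,
#' `whole_volume_cm3`, `total_cyst_cm3`, `new_lesion`, `btrads_reader1`,
#' `btrads_reader2`. Empty cells are missing values. An optional `volume_unit`
#' column (`"cm3"` or `"mm3"`) triggers conversion of all volume columns to
#' cm^3.
#'
#' @param path Path to a UTF-8 CSV file with header.
#' @return Named list of [participant_series], one per participant.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(measurement_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop_volresp("missing required columns: ",
                 paste(missing_cols, collapse = ", "),
                 class = "malformed_table")
  }
  num_cols <- c("t_days", "d1_cm", "d2_cm", "base_volume_cm3",
                "cyst_in_solid_cm3", "whole_volume_cm3", "total_cyst_cm3")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad) > 0) {
        stop_volresp("non-numeric value in column ", cl, " at data row ",
                     bad[1], class = "malformed_table")
      }
      df[[cl]] <- vn
    }
  }
  if ("volume_unit" %in% names(df)) {
    mm <- !is.na(df$volume_unit) & df$volume_unit == "mm3"
    vol_cols <- c("base_volume_cm3", "cyst_in_solid_cm3",
                  "whole_volume_cm3", "total_cyst_cm3")
    for (cl in vol_cols) df[[cl]][mm] <- df[[cl]][mm] / 1000
  }
  df$new_lesion <- as.logical(df$new_lesion)
  df$new_lesion[is.na(df$new_lesion)] <- FALSE
  key <- paste(df$participant_id, df$t_days, df$lesion_id)
  if (anyDuplicated(key)) {
    stop_volresp("duplicate (participant, t_days, lesion) rows",
                 class = "duplicate_rows")
  }
  ids <- unique(df$participant_id)
  out <- lapply(ids, function(id) {
    participant_series(df[df$participant_id == id, , drop = FALSE])
  })
  names(out) <- ids
  out
}

#' Write participant series back to the measurement CSV schema
#'
#' Numeric values are serialized with 17 significant digits so a write/read
#' round trip reproduces them exactly.
#'
#' @param series_list List of [participant_series] (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series_list, path) {
  if (inherits(series_list, "participant_series")) {
    series_list <- list(series_list)
  }
  df <- do.call(rbind, lapply(series_list, function(s) s$lesions))
  df <- df[, intersect(c(measurement_columns(), "volume_unit"), names(df)),
           drop = FALSE]
  out <- df
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) {
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- ""
      out[[cl]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
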