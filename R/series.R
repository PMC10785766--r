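#' Longitudinal measurement series for one participant
#'
#' Builds the per-participant container the whole pipeline consumes: a
#' time-ordered table of per-image aggregated measurements (2D area, solid
#' volume, whole volume, cyst volume, new-lesion flag, optional BT-RADS reads)
#' plus the lesion-level rows it was built from and the resolved baseline
#' index.
#'
#' Per-image aggregation follows trial practice: the 2D area is the sum over
#' lesions of the diameter products, solid volume the sum over lesions of
#' (base volume - intratumoral cyst volume). Whole-tumor volume and total cyst
#' volume are per-image quantities and must be constant across lesion rows of
#' the same image.
#'
#' @param df Data frame of lesion-level rows for a single participant with the
#'   columns of the measurement CSV schema (see [read_measurements()]).
#' @return An object of class `participant_series` with elements
#'   `participant_id`, `images` (one row per image, ordered by `t_days`),
#'   `lesions` (the input rows), and `baseline_index`.
#' @export
participant_series <- function(df) {
  stopifnot(is.data.frame(df))
  id <- unique(df$participant_id)
  if (length(id) != 1) {
    stop_volresp("a participant_series holds exactly one participant",
                 class = "invalid_series")
  }
  if (anyNA(df$t_days)) {
    stop_volresp("t_days must not be missing", class = "invalid_series")
  }
  key <- paste(df$t_days, df$lesion_id)
  if (anyDuplicated(key)) {
    stop_volresp("duplicate (t_days, lesion_id) rows for participant ", id,
                 class = "duplicate_rows")
  }

  times <- sort(unique(df$t_days))
  one_image <- function(t) {
    rows <- df[df$t_days == t, , drop = FALSE]
    has2d <- !is.na(rows$d1_cm) & !is.na(rows$d2_cm)
    area2d <- if (any(has2d)) {
      aggregate_lesions(bidimensional_area(rows$d1_cm[has2d], rows$d2_cm[has2d]))
    } else NA_real_
    has3d <- !is.na(rows$base_volume_cm3)
    solid <- if (any(has3d)) {
      cyst <- rows$cyst_in_solid_cm3[has3d]
      cyst[is.na(cyst)] <- 0
      sv <- suppressWarnings(solid_volume(rows$base_volume_cm3[has3d], cyst))
      aggregate_lesions(sv)
    } else NA_real_
    per_image <- function(col) {
      v <- unique(rows[[col]][!is.na(rows[[col]])])
      if (length(v) > 1) {
        stop_volresp(col, " differs across lesion rows of one image",
                     class = "invalid_series")
      }
      if (length(v) == 0) NA_real_ else v
    }
    whole <- per_image("whole_volume_cm3")
    cyst_total <- per_image("total_cyst_cm3")
    if (!is.na(whole) && !is.na(cyst_total) && whole < cyst_total) {
      stop_volresp("whole volume smaller than total cyst volume",
                   class = "inconsistent_segmentation")
    }
    if (is.na(area2d) && is.na(solid) && is.na(whole)) {
      stop_volresp("image at t=", t, " has no usable measurement",
                   class = "invalid_series")
    }
    btr <- function(col) {
      if (!col %in% names(rows)) return(NA_character_)
      v <- unique(rows[[col]][!is.na(rows[[col]]) & rows[[col]] != ""])
      if (length(v) == 0) NA_character_ else as.character(v[1])
    }
    data.frame(
      t_days = t, area2d = area2d, solid_volume = solid,
      whole_volume = whole, cyst_volume = cyst_total,
      new_lesion = isTRUE(any(as.logical(rows$new_lesion))),
      btrads_reader1 = btr("btrads_reader1"),
      btrads_reader2 = btr("btrads_reader2"),
      stringsAsFactors = FALSE
    )
  }
  images <- do.call(rbind, lapply(times, one_image))
  structure(
    list(participant_id = id, images = images, lesions = df,
         baseline_index = resolve_baseline(images$t_days)),
    class = "participant_series"
  )
}

#' @export
print.participant_series <- function(x, ...) {
  n_fu <- nrow(x$images) - 1L
  cat("Participant", x$participant_id, "-", nrow(x$images), "images (",
      n_fu, "follow-ups ), baseline at t =",
      x$images$t_days[x$baseline_index], "days\n")
  print(x$images, row.names = FALSE)
  invisible(x)
}

# Aggregated measure vector of a series, baseline included, in time order.
series_measure <- function(series, measure) {
  series$images[[measure]]
}
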