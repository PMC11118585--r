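## Plain-text / TIFF input-output for every modality.

#' Read / write a torsional eye trace (CSV)
#'
#' Two-column CSV with `time_s`, `angle_deg`.
#'
#' @param path File path.
#' @param sampling_rate Nominal rate attached to the returned trace.
#' @return An [eye_trace()].
#' @export
read_eye_trace <- function(path, sampling_rate = 200) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "angle_deg") %in% names(df))) {
    stop_invalid("eye-trace CSV needs columns time_s, angle_deg")
  }
  eye_trace(df$time_s, df$angle_deg, sampling_rate = sampling_rate)
}

#' @rdname read_eye_trace
#' @param trace An [eye_trace()] to write.
#' @export
write_eye_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              angle_deg = trace$angle_deg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a sampled stimulus profile as CSV
#'
#' @param profile Data frame from [trapezoid_profile()] or
#'   [sample_protocol()]`$trace`.
#' @param path Output path.
#' @param velocity Include the velocity column (3-column form) or not
#'   (2-column `time_s`, `angle_deg`).
#' @export
write_profile_csv <- function(profile, path, velocity = TRUE) {
  out <- data.frame(time_s = profile$time, angle_deg = profile$angle)
  if (velocity) out$velocity_dps <- profile$velocity
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read TIPM ROI traces: CSV trial-by-frame matrix plus JSON metadata
#'
#' The CSV holds one trial per row (columns = frames); the JSON metadata
#' carries `volume_rate`, `roi_area` and `event_frames` (`step`, `return`,
#' 1-based).
#'
#' @param traces_csv,meta_json File paths.
#' @return List of [roi_trace()] objects, one per trial row.
#' @export
read_roi_traces <- function(traces_csv, meta_json) {
  mat <- as.matrix(utils::read.csv(traces_csv, header = FALSE))
  meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
  ev <- c(step = as.integer(meta$event_frames$step),
          `return` = as.integer(meta$event_frames$`return`))
  lapply(seq_len(nrow(mat)), function(i) {
    roi_trace(as.numeric(mat[i, ]),
              volume_rate = meta$volume_rate %||% 3,
              roi_area = meta$roi_area %||% 100,
              event_frames = ev,
              roi_id = meta$roi_id %||% NA, trial_id = i)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write TIPM ROI traces and metadata
#'
#' @param traces List of [roi_trace()] objects sharing metadata.
#' @param traces_csv,meta_json Output paths.
#' @export
write_roi_traces <- function(traces, traces_csv, meta_json) {
  mat <- do.call(rbind, lapply(traces, `[[`, "fluorescence"))
  utils::write.table(mat, traces_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  t1 <- traces[[1]]
  jsonlite::write_json(
    list(volume_rate = t1$volume_rate, roi_area = t1$roi_area,
         event_frames = list(step = unname(t1$event_frames[["step"]]),
                             `return` = unname(t1$event_frames[["return"]])),
         roi_id = t1$roi_id),
    meta_json, auto_unbox = TRUE, digits = NA)
  invisible(traces_csv)
}

#' Read / write a muscle ROI polygon (JSON)
#'
#' JSON form `{"vertices": [[x, y], ...], "muscle": "SO"}`, pixel
#' coordinates, 0-based, x = column.
#'
#' @param path File path.
#' @return A [muscle_roi()].
#' @export
read_muscle_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  muscle_roi(j$vertices, muscle = j$muscle %||% NA_character_)
}

#' @rdname read_muscle_roi
#' @param roi A [muscle_roi()] to write.
#' @export
write_muscle_roi <- function(roi, path) {
  jsonlite::write_json(list(vertices = roi$vertices, muscle = roi$muscle),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read / write single-channel TIFF stacks
#'
#' Stacks are stored as (y, x, z) arrays of intensities in \[0, 1\]
#' (16-bit on disk).
#'
#' @param path File path.
#' @return 3-D array (y, x, z); single-plane files give `z = 1`.
#' @export
read_stack_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
}

#' @rdname read_stack_tiff
#' @param stack 2-D matrix or 3-D (y, x, z) array, intensities in \[0, 1\].
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  planes <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  tiff::writeTIFF(planes, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an experiment configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
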