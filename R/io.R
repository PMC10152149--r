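#' Read and write comet-track tables
#'
#' Plain CSV, UTF-8, '.' decimal separator, header required. Columns follow
#' the track schema (`track_id`, `frame`, `time_min`, optional `x_um`,
#' `y_um`, `comet_length_um`, `comet_area_um2`,
#' `bead_velocity_um_per_min`, `actin_intensity_au`); several tracks may be
#' stacked and are told apart by `track_id`.
#'
#' @param path CSV file path.
#' @param tracks data.frame of one or more stacked tracks.
#' @return `read_tracks` returns a list of `comet_track` data.frames, one
#'   per `track_id` (a single unnamed track comes back as a length-1 list).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df))
    stop("track CSV must have a time_min column (found: ",
         paste(names(df), collapse = ", "), ")")
  if (!"track_id" %in% names(df)) df$track_id <- "track1"
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c("comet_track", "data.frame")
    d
  })
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' Columns `time_min, l_um, l_tilde_um, GD_um, GT_um, aged_um,
#' V_um_per_min` plus `conservation_residual_um` (pool sum minus `l_max`),
#' so the conservation invariant is visible in the artifact itself.
#'
#' @param traj a `comet_trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$conservation_residual_um <- rowSums(traj$states) - traj$params$l_max
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
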