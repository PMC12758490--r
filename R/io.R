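# File I/O: feature trajectories as CSV with a YAML sidecar carrying the
# frame interval, temperature tag and segment boundaries; labels as
# single-column CSV aligned to frame order.

#' Write a feature trajectory to CSV
#'
#' The descriptor matrix is written as a headered CSV; frame interval,
#' temperature tag and segment lengths go to a YAML sidecar
#' (`<path>.yml`). Raw coordinates, if present, are written alongside as
#' `<path stem>_coords.csv`.
#'
#' @param traj A [feature_trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(traj, path) {
  stopifnot(inherits(traj, "feature_trajectory"))
  df <- as.data.frame(traj$frames)
  if (is.null(colnames(traj$frames)))
    names(df) <- paste0("f", seq_len(ncol(traj$frames)))
  data.table::fwrite(df, path)
  meta <- list(frame_interval = traj$frame_interval,
               temperature = traj$temperature,
               segments = as.integer(traj$segments))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  if (!is.null(traj$coords))
    data.table::fwrite(as.data.frame(traj$coords), coords_path(path))
  invisible(path)
}

coords_path <- function(path) {
  sub("(\\.[^.]+)?$", "_coords.csv", path)
}

#' Read a feature trajectory from CSV
#'
#' Reads a headered CSV (or TSV) of numeric descriptors plus, if present,
#' the YAML sidecar written by [write_features()]; missing metadata falls
#' back to defaults with a warning. Non-numeric or missing cells are
#' rejected with the offending row/column named.
#'
#' @param path CSV/TSV path.
#' @return A [feature_trajectory()].
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    j <- which(!vapply(df, is.numeric, TRUE))[1]
    i <- which(!vapply(df[[j]], function(v) is.numeric(v) && is.finite(v),
                       TRUE))[1]
    stop(sprintf("non-numeric cell at row %d, column '%s'", i, names(df)[j]))
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite cell at row %d, column '%s'", bad[1],
                 colnames(m)[bad[2]]))
  }
  meta_path <- paste0(path, ".yml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
  } else {
    warning("no metadata sidecar (", meta_path,
            "); using frame_interval = 1, temperature = 1, one segment")
    meta <- list(frame_interval = 1, temperature = 1, segments = nrow(m))
  }
  cp <- coords_path(path)
  coords <- if (file.exists(cp))
    as.matrix(data.table::fread(cp, data.table = FALSE)) else NULL
  feature_trajectory(m, frame_interval = meta$frame_interval,
                     temperature = meta$temperature,
                     segments = meta$segments, coords = coords)
}

#' Write state labels as single-column CSV
#'
#' @param labels Integer labels or a [state_assignment()].
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  data.table::fwrite(data.frame(state = as.integer(labels)), path)
  invisible(path)
}

#' Read state labels from single-column CSV
#'
#' @param path Input path.
#' @return Integer label vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as.integer(data.table::fread(path, data.table = FALSE)[[1]])
}
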