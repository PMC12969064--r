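#' Write a phase trajectory to CSV
#'
#' Columns `t, phi_Ox, phi_Glu, phi_GOa, phi_GO, phi_MO` (radians,
#' unwrapped). Values are written with 17 significant digits so the file
#' round-trips doubles exactly.
#'
#' @param traj An `nvu_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "nvu_trajectory"))
  df <- as.data.frame(lapply(traj, function(col) {
    format(col, digits = 17, scientific = TRUE, trim = TRUE)
  }))
  names(df) <- names(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phase trajectory from CSV
#'
#' Inverse of [write_trajectory_csv()]. Model provenance is not stored in
#' the CSV; the returned trajectory carries grid metadata inferred from the
#' time column.
#'
#' @param path CSV path.
#' @return An `nvu_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("t", paste0("phi_", OSC_IDS))
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("trajectory CSV lacks column ", missing[1])
  df <- tibble::as_tibble(df[need])
  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  new_trajectory(df, model = NULL, dt = dt,
                 duration = df$t[nrow(df)] - df$t[1],
                 seed = NA_integer_, init = "file", noise = NA)
}

#' Write a state map or frequency-curve sweep to CSV
#'
#' Long format, one row per grid cell or curve point, 17 significant
#' digits.
#'
#' @param x An `nvu_state_map` or `nvu_freq_curves` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE) else col
  }))
  names(df) <- names(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
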