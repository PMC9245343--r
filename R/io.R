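#' Read and write spikes and trajectories as TSV
#'
#' The on-disk interchange format is plain TSV in SI units: spikes carry
#' columns `time_s` and `current_A`; trajectories carry `time_s`,
#' `pore_radius_m` and optionally `flag`.
#'
#' @param path File path.
#' @param spike,traj Objects to write.
#' @return Readers return an [as_spike()] / [pore_trajectory()]; writers
#'   return the path invisibly.
#' @name poretrace_io
NULL

#' @rdname poretrace_io
#' @export
read_spike_tsv <- function(path) {
  if (is.null(path) || !file.exists(path)) {
    abort(paste0("no such file: ", path), class = "poretrace_io_error")
  }
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!all(c("time_s", "current_A") %in% names(d))) {
    abort("spike TSV needs columns time_s and current_A",
      class = "poretrace_io_error"
    )
  }
  as_spike(d$time_s, d$current_A)
}

#' @rdname poretrace_io
#' @export
write_spike_tsv <- function(spike, path) {
  utils::write.table(
    data.frame(time_s = spike$time, current_A = spike$current),
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname poretrace_io
#' @export
read_trajectory_tsv <- function(path) {
  if (is.null(path) || !file.exists(path)) {
    abort(paste0("no such file: ", path), class = "poretrace_io_error")
  }
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!all(c("time_s", "pore_radius_m") %in% names(d))) {
    abort("trajectory TSV needs columns time_s and pore_radius_m",
      class = "poretrace_io_error"
    )
  }
  out <- pore_trajectory(d$time_s, d$pore_radius_m)
  if ("flag" %in% names(d)) out$flag <- d$flag
  out
}

#' @rdname poretrace_io
#' @export
write_trajectory_tsv <- function(traj, path) {
  d <- data.frame(time_s = traj$time, pore_radius_m = traj$radius)
  if ("flag" %in% names(traj)) d$flag <- traj$flag
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
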