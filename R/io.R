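#' Write a session to a plain-text container
#'
#' Writes one CSV per array plus the trial table and a YAML metadata file:
#' `spikes.csv` (units x bins), `emg.csv` (muscles x samples),
#' `trials.csv`, `meta.yaml` (bin width, EMG sampling rate).
#'
#' @param session a `neural_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(session$spikes, file.path(dir, "spikes.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(session$emg, file.path(dir, "emg.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(bin_ms = session$bin_ms, emg_fs = session$emg_fs),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a session from the plain-text container
#'
#' @param dir directory written by [write_session()].
#' @return a `neural_session`.
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  spikes <- as.matrix(utils::read.table(file.path(dir, "spikes.csv"),
                                        sep = ","))
  dimnames(spikes) <- NULL
  storage.mode(spikes) <- "integer"
  emg <- as.matrix(utils::read.table(file.path(dir, "emg.csv"), sep = ","))
  dimnames(emg) <- NULL
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  structure(list(spikes = spikes, trials = trials, emg = emg,
                 emg_fs = meta$emg_fs, bin_ms = meta$bin_ms),
            class = "neural_session")
}

#' Write or read a generator configuration as YAML
#'
#' @param config a [synthetic_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   `synthetic_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  drop <- c("d", "bin_ms")
  yaml::write_yaml(unclass(config)[setdiff(names(config), drop)], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$rotated_modes <- if (!is.null(vals$rotated_modes))
    as.integer(unlist(vals$rotated_modes))
  do.call(synthetic_config, vals)
}
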