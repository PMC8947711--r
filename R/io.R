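#' Write / read a trial-set fixture directory
#'
#' The fixture format is a directory with two plain-text files:
#' `signals.txt`, the trial data flattened to `(n_trials * n_channels)`
#' rows of `n_samples` space-separated values (trial-major, channels in
#' stored order, printed with 17 significant digits so doubles round-trip
#' bit-identically), and `meta.json` with fields `n_trials`, `n_channels`,
#' `n_samples`, `labels`, `fs`, `channel_names`, `artifact_flags` and
#' optionally the generating `seed`.
#'
#' @param trials a [raw_trial_set()].
#' @param dir directory to create/fill.
#' @return `read_trial_fixture` returns the reconstructed
#'   [raw_trial_set()]; `write_trial_fixture` returns `dir` invisibly.
#' @export
write_trial_fixture <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(trials$data)
  meta <- list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
               labels = trials$labels, fs = trials$fs,
               channel_names = trials$channel_names,
               artifact_flags = trials$artifact_flags,
               seed = attr(trials, "seed"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(dir, "signals.txt"), "w")
  on.exit(close(con))
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      writeLines(paste(sprintf("%.17g", trials$data[i, c, ]), collapse = " "), con)
    }
  }
  invisible(dir)
}

#' @rdname write_trial_fixture
#' @export
read_trial_fixture <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop(sprintf("no meta.json in %s", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("n_trials", "n_channels", "n_samples", "labels", "fs", "channel_names")) {
    if (is.null(meta[[f]]) && !(f == "labels" && identical(meta$n_trials, 0L))) {
      stop(sprintf("fixture sidecar is missing required field '%s'", f))
    }
  }
  n <- meta$n_trials; nc <- meta$n_channels; ns <- meta$n_samples
  dat <- array(0, dim = c(n, nc, ns))
  if (n > 0) {
    vals <- scan(file.path(dir, "signals.txt"), quiet = TRUE)
    if (length(vals) != n * nc * ns) {
      stop("signals.txt size does not match the sidecar dimensions")
    }
    m <- matrix(vals, nrow = n * nc, byrow = TRUE)
    for (i in seq_len(n)) {
      dat[i, , ] <- m[(i - 1) * nc + seq_len(nc), , drop = FALSE]
    }
  }
  ts <- raw_trial_set(dat, meta$labels %||% character(0), meta$fs,
                      meta$channel_names, meta$artifact_flags)
  if (!is.null(meta$seed)) attr(ts, "seed") <- meta$seed
  ts
}

#' Epoch a continuous recording fixture into labeled trials
#'
#' Reads a plain-text continuous recording (`continuous.txt`: one row per
#' channel; `recording.json`: `fs`, `channel_names`, and an event table
#' with 0-based sample `positions` and string `codes`) and cuts one trial
#' per cue event according to `event_map`, which must name the `left` and
#' `right` cue codes and may name an `artifact` code (trials whose window
#' contains an artifact event are flagged, mirroring the "1023" convention
#' of the BCI competition IV 2b recordings, and kept). A recording whose
#' sampling rate differs from `expected_fs` is read as-is with a warning.
#'
#' @param dir fixture directory.
#' @param event_map named list/vector with entries `left`, `right` and
#'   optionally `artifact`.
#' @param epoch_window seconds relative to the cue, half-open
#'   `[start, end)` as in [extract_epoch()].
#' @param expected_fs sampling rate the caller expects (250 Hz for the
#'   motor-imagery protocol this package targets).
#' @return a [raw_trial_set()] with `artifact_flags` set.
#' @export
read_recording <- function(dir, event_map, epoch_window = c(0, 4.5),
                           expected_fs = 250) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  for (f in c("fs", "channel_names", "events")) {
    if (is.null(meta[[f]])) stop(sprintf("recording.json is missing field '%s'", f))
  }
  for (f in c("left", "right")) {
    if (is.null(event_map[[f]])) stop(sprintf("event_map is missing the '%s' cue code", f))
  }
  if (!is.null(expected_fs) && meta$fs != expected_fs) {
    warning(sprintf("recording sampling rate is %g Hz (expected %g); no resampling applied",
                    meta$fs, expected_fs))
  }
  sig <- as.matrix(utils::read.table(file.path(dir, "continuous.txt")))
  if (nrow(sig) != length(meta$channel_names)) {
    stop("continuous.txt row count does not match channel_names")
  }
  codes <- as.character(meta$events$codes)
  pos <- as.numeric(meta$events$positions)
  cue <- which(codes %in% c(event_map$left, event_map$right))
  if (length(cue) == 0) stop("recording contains no cue events")
  i0 <- round(epoch_window[1] * meta$fs)
  i1 <- round(epoch_window[2] * meta$fs)
  len <- i1 - i0
  labels <- ifelse(codes[cue] == event_map$left, "left", "right")
  dat <- array(0, dim = c(length(cue), nrow(sig), len))
  flags <- logical(length(cue))
  art_pos <- if (!is.null(event_map$artifact)) {
    pos[codes == as.character(event_map$artifact)]
  } else numeric(0)
  for (k in seq_along(cue)) {
    start <- pos[cue[k]] + i0              # 0-based
    if (start < 0 || start + len > ncol(sig)) {
      stop(sprintf("trial %d (cue at sample %d) exceeds the recording", k, pos[cue[k]]))
    }
    dat[k, , ] <- sig[, (start + 1):(start + len)]
    flags[k] <- any(art_pos >= pos[cue[k]] & art_pos < pos[cue[k]] + i1)
  }
  raw_trial_set(dat, labels, meta$fs, meta$channel_names, flags)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(variant = report$variant,
              fold_accuracy = report$fold_accuracy,
              accuracy = report$accuracy,
              kappa = report$kappa,
              confusion = unclass(report$confusion),
              recall = as.list(report$recall),
              precision = as.list(report$precision),
              n = report$n, seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
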