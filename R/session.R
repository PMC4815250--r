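#' Raw synchronized EEG/EMG/kinematics session
#'
#' The in-memory container shared by every pipeline stage: multichannel EEG
#' (microvolts), two bipolar EMG channels (millivolts), elbow kinematics at
#' their native rate, and trigger events. EEG and EMG are recorded by the
#' same amplifier and therefore share a sampling rate and sample count;
#' kinematics come from the exoskeleton encoders at their own rate.
#'
#' @param eeg channels x samples numeric matrix, microvolts.
#' @param eeg_labels character vector of unique channel labels (10-20 names).
#' @param fs_eeg EEG/EMG sampling rate in Hz (500 native).
#' @param emg optional 2 x samples matrix, millivolts.
#' @param emg_labels labels for the EMG rows, default biceps/triceps.
#' @param fs_emg EMG sampling rate; must equal `fs_eeg` when both present.
#' @param kin optional list with `position` (degrees), `velocity` (deg/s)
#'   and `fs` (Hz, 1000 native).
#' @param events data.frame with columns `kind` (one of `target_onset`,
#'   `movement_onset`, `target_reached`, `catch_target_onset`), `sample`
#'   (1-based index at `fs_eeg`), `trial_id`, and optionally `block`.
#' @param meta free-form provenance list.
#' @return object of class `raw_session`.
#' @export
raw_session <- function(eeg, eeg_labels, fs_eeg = 500, emg = NULL,
                        emg_labels = c("biceps", "triceps"), fs_emg = fs_eeg,
                        kin = NULL, events = empty_events(), meta = list()) {
  eeg <- as.matrix(eeg)
  if (length(eeg_labels) != nrow(eeg)) stop("eeg_labels must match nrow(eeg)")
  if (anyDuplicated(eeg_labels)) stop("channel labels must be unique")
  if (fs_eeg <= 0) stop("fs_eeg must be positive")
  if (!is.null(emg)) {
    emg <- as.matrix(emg)
    if (fs_emg != fs_eeg) stop("EEG and EMG must share the amplifier rate")
    if (ncol(emg) != ncol(eeg)) stop("EEG and EMG must share the sample count")
    if (nrow(emg) != length(emg_labels)) stop("emg_labels must match nrow(emg)")
  }
  events <- validate_events(events, ncol(eeg))
  rownames(eeg) <- eeg_labels
  structure(list(eeg = eeg, eeg_labels = eeg_labels, fs_eeg = fs_eeg,
                 emg = emg, emg_labels = if (is.null(emg)) NULL else emg_labels,
                 fs_emg = if (is.null(emg)) NULL else fs_emg,
                 kin = kin, events = events, meta = meta),
            class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %d EEG ch x %d samples @ %g Hz", nrow(x$eeg),
              ncol(x$eeg), x$fs_eeg))
  if (!is.null(x$emg)) cat(sprintf(", %d EMG ch", nrow(x$emg)))
  if (!is.null(x$kin)) cat(sprintf(", kinematics @ %g Hz", x$kin$fs))
  cat(sprintf(", %d events\n", nrow(x$events)))
  invisible(x)
}

event_kinds <- function() {
  c("target_onset", "movement_onset", "target_reached", "catch_target_onset")
}

#' @rdname raw_session
#' @export
empty_events <- function() {
  data.frame(kind = character(), sample = integer(), trial_id = integer(),
             block = integer(), stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples) {
  if (nrow(events) == 0) return(empty_events())
  stopifnot(all(c("kind", "sample", "trial_id") %in% names(events)))
  bad <- setdiff(unique(events$kind), event_kinds())
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  if (any(events$sample < 1 | events$sample > n_samples))
    stop("event sample index out of bounds")
  if (is.null(events$block)) events$block <- NA_integer_
  events$sample <- as.integer(events$sample)
  events[order(events$sample), c("kind", "sample", "trial_id", "block"),
         drop = FALSE]
}

#' Compute epoch sample ranges around events
#'
#' Returns half-open sample ranges `[start, end)` of length
#' `round(diff(t_range) * fs)` around every event of the requested kind, at
#' the session's current sampling rate. Events whose window would leave the
#' recording are skipped with a warning rather than clamped.
#'
#' @param session a `raw_session` (any sampling rate).
#' @param kind event kind to align on.
#' @param t_range window in seconds relative to the event, default
#'   `c(-2.5, 1)`.
#' @return data.frame with columns `trial_id`, `start`, `end` (end exclusive),
#'   `event_sample`, `block`.
#' @export
epoch_slices <- function(session, kind, t_range = c(-2.5, 1)) {
  fs <- session$fs_eeg
  n <- ncol(session$eeg)
  ev <- session$events[session$events$kind == kind, , drop = FALSE]
  len <- round(diff(t_range) * fs)
  start <- ev$sample + round(t_range[1] * fs)
  end <- start + len
  ok <- start >= 1 & (end - 1) <= n
  if (any(!ok))
    warning(sum(!ok), " ", kind, " event(s) too close to the record edge; skipped")
  data.frame(trial_id = ev$trial_id[ok], start = start[ok], end = end[ok],
             event_sample = ev$sample[ok], block = ev$block[ok])
}

#' Write a session to the portable container or BrainVision format
#'
#' The portable container is a directory holding a JSON sidecar (labels,
#' rates, events, metadata) plus raw little-endian float64 arrays; it round
#' trips bit-exactly. BrainVision export writes the classic
#' `.vhdr`/`.vmrk`/`.eeg` triplet with 16-bit scaled integers (0.1 uV per
#' bit for EEG, 0.01 mV per bit for EMG, matching a +/-3.2768 mV and
#' +/-327.68 mV dynamic range) and is therefore documented as lossy to one
#' quantization step; kinematics, which have their own sampling rate, are
#' not representable in the triplet and are dropped with a warning.
#'
#' @param session a `raw_session`.
#' @param path directory (container) or file stem (BrainVision).
#' @param format `"container"` or `"brainvision"`.
#' @param marker_map named character vector mapping event kinds to marker
#'   descriptions, default [default_marker_map()].
#' @return invisibly, the paths written.
#' @export
write_session <- function(session, path, format = c("container", "brainvision"),
                          marker_map = default_marker_map()) {
  format <- match.arg(format)
  if (format == "container") write_container(session, path)
  else write_brainvision(session, path, marker_map)
}

write_container <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "mrcpbmi-session", version = 1L,
    fs_eeg = session$fs_eeg, eeg_labels = session$eeg_labels,
    n_samples = ncol(session$eeg),
    emg_labels = session$emg_labels, fs_emg = session$fs_emg,
    kin_fs = if (is.null(session$kin)) NULL else session$kin$fs,
    kin_n = if (is.null(session$kin)) NULL else length(session$kin$position),
    events = session$events, meta = session$meta)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_f64 <- function(x, file) {
    con <- file(file.path(path, file), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  write_f64(session$eeg, "eeg.bin")
  if (!is.null(session$emg)) write_f64(session$emg, "emg.bin")
  if (!is.null(session$kin)) {
    write_f64(session$kin$position, "kin_position.bin")
    write_f64(session$kin$velocity, "kin_velocity.bin")
  }
  invisible(path)
}

#' Read a session from the portable container
#'
#' @param path container directory written by [write_session()].
#' @return a `raw_session`.
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  read_f64 <- function(file, n) {
    con <- file(file.path(path, file), "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = n, size = 8, endian = "little")
  }
  nch <- length(meta$eeg_labels)
  eeg <- matrix(read_f64("eeg.bin", nch * meta$n_samples), nrow = nch)
  emg <- NULL
  if (!is.null(meta$emg_labels) && length(meta$emg_labels)) {
    emg <- matrix(read_f64("emg.bin", length(meta$emg_labels) * meta$n_samples),
                  nrow = length(meta$emg_labels))
  }
  kin <- NULL
  if (!is.null(meta$kin_fs)) {
    kin <- list(position = read_f64("kin_position.bin", meta$kin_n),
                velocity = read_f64("kin_velocity.bin", meta$kin_n),
                fs = meta$kin_fs)
  }
  events <- if (length(meta$events)) as.data.frame(meta$events) else empty_events()
  raw_session(eeg, meta$eeg_labels, meta$fs_eeg, emg = emg,
              emg_labels = meta$emg_labels, fs_emg = meta$fs_eeg,
              kin = kin, events = events,
              meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Default mapping from event kinds to BrainVision marker descriptions
#'
#' The original rig's marker codes are not published, so the map is
#' user-configurable; these defaults are used for round-trip testing.
#' @return named character vector.
#' @export
default_marker_map <- function() {
  c(target_onset = "S  1", movement_onset = "S  2", target_reached = "S  3",
    catch_target_onset = "S  4")
}

#' Read a user-supplied marker map from a JSON file
#'
#' The file holds one flat object mapping event kinds to the rig's marker
#' descriptions, e.g. `{"target_onset": "S  1", ...}`.
#'
#' @param path JSON file.
#' @return named character vector usable as `marker_map`.
#' @export
read_marker_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(x), event_kinds())
  if (length(bad)) stop("marker map names unknown event kind(s): ",
                        paste(bad, collapse = ", "))
  unlist(x)
}

bv_resolutions <- function(session) {
  # 16-bit @ +/-3.2768 mV -> 0.1 uV per bit; EMG +/-327.68 mV -> 0.01 mV
  c(rep(0.1, nrow(session$eeg)),
    if (is.null(session$emg)) NULL else rep(0.01, nrow(session$emg)))
}

write_brainvision <- function(session, stem, marker_map = default_marker_map()) {
  if (!is.null(session$kin))
    warning("kinematics are not representable in BrainVision; dropped")
  dat <- rbind(session$eeg, if (is.null(session$emg)) NULL else session$emg)
  labels <- c(session$eeg_labels, session$emg_labels)
  units <- c(rep("µV", nrow(session$eeg)),
             rep("mV", if (is.null(session$emg)) 0 else nrow(session$emg)))
  res <- bv_resolutions(session)
  base <- basename(stem)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Written by mrcpbmi", "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(dat)),
    paste0("SamplingInterval=", format(1e6 / session$fs_eeg, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,%s", seq_len(nrow(dat)), labels,
            format(res, scientific = FALSE, trim = TRUE), units))
  writeLines(hdr, paste0(stem, ".vhdr"))

  ev <- session$events
  unmapped <- setdiff(unique(ev$kind), names(marker_map))
  if (length(unmapped)) {
    warning("event kind(s) without marker code dropped on export: ",
            paste(unmapped, collapse = ", "))
    ev <- ev[ev$kind %in% names(marker_map), , drop = FALSE]
  }
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0", "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (nrow(ev)) sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(ev)) + 1L,
                          marker_map[ev$kind], ev$sample))
  writeLines(mrk, paste0(stem, ".vmrk"))

  scaled <- round(dat / res)  # res recycles down columns (channel-major)
  scaled <- pmin(pmax(scaled, -32768), 32767)
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.integer(scaled), con, size = 2, endian = "little")
  invisible(paste0(stem, c(".vhdr", ".vmrk", ".eeg")))
}

parse_ini <- function(lines) {
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  section <- NA_character_
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("^\\[|\\]\\s*$", "", ln)
      out[[section]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[section]][key] <- val
    }
  }
  out
}

#' Read a BrainVision triplet into a raw session
#'
#' Parses the `.vhdr` header, `.vmrk` markers and 16-bit binary data file.
#' Channels whose labels appear in `emg_labels` are split out as EMG; marker
#' descriptions are translated back to event kinds through `marker_map`, and
#' unmapped codes are dropped with a warning (the session still loads).
#'
#' @param header_path path to the `.vhdr` file.
#' @param marker_map named character vector, kind -> marker description.
#' @param emg_labels labels to treat as EMG channels.
#' @return a `raw_session` (kinematics absent).
#' @export
read_brainvision <- function(header_path, marker_map = default_marker_map(),
                             emg_labels = c("biceps", "triceps")) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci[["DataFile"]])
  mrk_path <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(data_path)) stop("missing data file: ", data_path)
  if (!file.exists(mrk_path)) stop("missing marker file: ", mrk_path)
  if (!identical(ci[["DataFormat"]], "BINARY") ||
      !identical(ci[["DataOrientation"]], "MULTIPLEXED"))
    stop("only multiplexed binary BrainVision data are supported")
  if (!identical(hdr[["Binary Infos"]][["BinaryFormat"]], "INT_16"))
    stop("only INT_16 BrainVision data are supported")
  nch <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])

  chinfo <- hdr[["Channel Infos"]]
  parts <- strsplit(unname(chinfo), ",")
  labels <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p) as.numeric(p[3]), 0)

  sz <- file.info(data_path)$size
  if (sz %% (2 * nch) != 0)
    stop("data file size is not a whole number of ", nch, "-channel frames")
  n <- sz / (2 * nch)
  con <- file(data_path, "rb")
  raw <- readBin(con, "integer", n = nch * n, size = 2, endian = "little",
                 signed = TRUE)
  close(con)
  dat <- matrix(raw, nrow = nch) * res

  mrk <- parse_ini(readLines(mrk_path, warn = FALSE))[["Marker Infos"]]
  ev <- empty_events()
  if (length(mrk)) {
    parts <- strsplit(unname(mrk), ",")
    type <- vapply(parts, `[`, "", 1)
    desc <- vapply(parts, `[`, "", 2)
    pos <- suppressWarnings(vapply(parts, function(p) as.integer(p[3]), 0L))
    keep <- type == "Stimulus"
    desc <- desc[keep]; pos <- pos[keep]
    inv <- stats::setNames(names(marker_map), marker_map)
    kind <- unname(inv[desc])
    if (anyNA(kind)) {
      warning("unmapped marker code(s) dropped: ",
              paste(unique(desc[is.na(kind)]), collapse = ", "))
      pos <- pos[!is.na(kind)]; kind <- kind[!is.na(kind)]
    }
    if (length(kind)) {
      trial <- integer(length(kind))
      tid <- 0L
      for (i in order(pos)) {
        if (kind[i] %in% c("target_onset", "catch_target_onset")) tid <- tid + 1L
        trial[i] <- tid
      }
      ev <- data.frame(kind = kind, sample = pos, trial_id = trial,
                       block = NA_integer_)
    }
  }

  is_emg <- labels %in% emg_labels
  raw_session(dat[!is_emg, , drop = FALSE], labels[!is_emg], fs,
              emg = if (any(is_emg)) dat[is_emg, , drop = FALSE] else NULL,
              emg_labels = labels[is_emg], fs_emg = fs, events = ev,
              meta = list(source = header_path))
}
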