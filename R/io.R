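# Serialisation: CSV tables for designs/outcomes/metrics, and a BrainVision
# (.vhdr/.vmrk + binary float32 or ASCII data) writer/reader for EEG
# exchange. Array artefacts (epoch sets, coupling maps) persist to RDS.

#' Write / read a session design as CSV
#'
#' One row per trial. Column dictionary: `block` (block number), `trial`
#' (session-wide trial index), `control` (solo/joint), `target_index` /
#' `distractor_index` (1-8, opposite pairs), `target_freq_hz` /
#' `distractor_freq_hz` (17/19), `cue_colour` (red/green), `delay_ms`
#' (variable pre-action delay).
#'
#' @param design a `session_design`; @param path CSV path.
#' @return `read_design_csv` returns the `session_design`.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("session_design", "data.frame"),
            blocks = length(unique(d$block)),
            block_size = sum(d$block == d$block[1]))
}

#' Write an EEG recording in BrainVision format
#'
#' Produces the `.vhdr` text header, `.vmrk` text marker file, and the data
#' file -- multiplexed IEEE float32 (`.eeg`) or ASCII (`.dat`). Amplitude
#' resolution is 1 uV.
#'
#' @param rec an `eeg_recording`; @param basename path without extension;
#' @param format `"float32"` or `"ascii"`.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename, format = c("float32", "ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  data_ext <- if (format == "float32") ".eeg" else ".dat"
  base <- basename(basename)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, data_ext),
    paste0("MarkerFile=", base, ".vmrk"),
    paste0("DataFormat=", if (format == "float32") "BINARY" else "ASCII"),
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ncol(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate_hz, scientific = FALSE)),
    if (format == "float32") c("[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32")
    else c("[ASCII Infos]", "DecimalSymbol=.", "SkipLines=0", "SkipColumns=0"),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(rec$labels), rec$labels))
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = TRUE)
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, data_ext),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(rec$markers)) + 1L,
            rec$markers$label, rec$markers$sample))
  writeLines(mrk, paste0(basename, ".vmrk"), useBytes = TRUE)
  if (format == "float32") {
    con <- file(paste0(basename, data_ext), "wb")
    writeBin(as.numeric(t(rec$data)), con, size = 4L)
    close(con)
  } else {
    utils::write.table(format(rec$data, trim = TRUE, digits = 10),
                       paste0(basename, data_ext),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(paste0(basename, ".vhdr"))
}

# parse one Key=Value ini-ish section body
.bv_fields <- function(lines) {
  kv <- lines[grepl("=", lines, fixed = TRUE)]
  parts <- regmatches(kv, regexpr("=", kv), invert = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2L),
                  trimws(vapply(parts, `[`, "", 1L)))
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr`/`.vmrk`/data triplet written by [write_brainvision()]
#' (multiplexed, float32 or ASCII).
#'
#' @param vhdr_path path to the `.vhdr` header.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, encoding = "UTF-8", warn = FALSE)
  f <- .bv_fields(lines)
  nchan <- as.integer(f[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(f[["SamplingInterval"]])
  dirn <- dirname(vhdr_path)
  labels <- vapply(seq_len(nchan), function(i)
    strsplit(f[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]][1], "")
  data_file <- file.path(dirn, f[["DataFile"]])
  if (identical(f[["DataFormat"]], "BINARY")) {
    n <- file.info(data_file)$size / 4L
    con <- file(data_file, "rb")
    v <- readBin(con, "numeric", n = n, size = 4L)
    close(con)
    data <- matrix(v, ncol = nchan, byrow = TRUE)
  } else {
    data <- as.matrix(utils::read.table(data_file))
    dimnames(data) <- NULL
  }
  mlines <- readLines(file.path(dirn, sub("\\.[^.]+$", ".vmrk",
                                          basename(vhdr_path))),
                      encoding = "UTF-8", warn = FALSE)
  mk <- grep("^Mk[0-9]+=", mlines, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",", fixed = TRUE)
  keep <- vapply(parts, function(p) p[1] == "Stimulus", logical(1))
  markers <- data.frame(
    label = vapply(parts[keep], `[`, "", 2L),
    sample = as.integer(vapply(parts[keep], `[`, "", 3L)),
    trial = NA_integer_, stringsAsFactors = FALSE)
  structure(list(data = data, rate_hz = rate, labels = labels,
                 markers = markers, participant = NA_integer_,
                 pair = NA_integer_),
            class = "eeg_recording")
}

#' Write per-trial outcome / metric tables
#'
#' Plain CSV, one row per trial x cursor owner, keyed by `pair`, `trial`,
#' `owner`, `visible`.
#'
#' @param outcomes outcomes data.frame (see [simulate_pair_session()]);
#' @param path CSV path; @param pair pair id stamped on the rows.
#' @export
write_outcomes_csv <- function(outcomes, path, pair = 1L) {
  out <- cbind(pair = pair, outcomes)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
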