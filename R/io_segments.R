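#' Read and write paired waveform records
#'
#' Two on-disk formats are supported: a plain two-column CSV with a small
#' commented header (the package's native fixture format), and WFDB-style
#' records (text `.hea` header plus 16-bit interleaved `.dat`), the layout
#' used by ICU waveform databases.  Records are read untouched — no
#' filtering, no resampling.
#'
#' @name record_io
NULL

EXPECTED_FS <- 125

#' Write a paired segment as a two-column CSV record
#'
#' @param segment A `paired_segment` (or any list with `ppg`, `abp`,
#'   `sampling_rate_hz`, `subject_id`, `segment_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(segment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ppg2abp segment v1",
               sprintf("# sampling_rate_hz: %g", segment$sampling_rate_hz),
               sprintf("# subject_id: %s", segment$subject_id),
               sprintf("# segment_id: %s", segment$segment_id)), con)
  writeLines("ppg,abp", con)
  # 17 significant digits round-trip IEEE doubles exactly
  writeLines(paste(sprintf("%.17g", segment$ppg),
                   sprintf("%.17g", segment$abp), sep = ","), con)
  invisible(path)
}

read_csv_record <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  dat <- read.csv(path, comment.char = "#")
  fs <- suppressWarnings(as.numeric(get("sampling_rate_hz", EXPECTED_FS)))
  list(data = dat, fs = fs,
       subject_id = get("subject_id", "unknown"),
       segment_id = get("segment_id", basename(path)))
}

# Minimal WFDB reader: text header + format-16 little-endian interleaved
# samples, physical value = (adc - baseline) / gain.
read_wfdb_record <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (f[2] != "16")
      stop("only WFDB format 16 is supported, got format ", f[2],
           call. = FALSE)
    gain_spec <- f[3]  # e.g. "100(0)/mmHg" or "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
    list(file = f[1], gain = gain, baseline = baseline,
         name = f[length(f)])
  }
  sigs <- lapply(sig, parse_sig)
  dat_path <- file.path(dirname(hea_path), sigs[[1]]$file)
  raw <- readBin(dat_path, integer(), n = n_sig * n_samp, size = 2,
                 signed = TRUE, endian = "little")
  m <- matrix(raw, ncol = n_sig, byrow = TRUE)
  phys <- vapply(seq_len(n_sig), function(j)
    (m[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain, numeric(nrow(m)))
  colnames(phys) <- vapply(sigs, `[[`, "", "name")
  list(signals = phys, fs = fs, n = nrow(phys))
}

#' Write a two-channel WFDB-style record (format 16)
#'
#' @param segment A `paired_segment`.
#' @param record_path Path without extension; `.hea` and `.dat` are written.
#' @param ppg_name,abp_name Channel descriptions in the header.
#' @param ppg_gain,abp_gain ADC gains (units per physical unit).
#' @return The `.hea` path, invisibly.
#' @export
write_record_wfdb <- function(segment, record_path, ppg_name = "PLETH",
                              abp_name = "ABP", ppg_gain = 1000,
                              abp_gain = 100) {
  rec <- basename(record_path)
  n <- length(segment$ppg)
  hea <- file.path(dirname(record_path), paste0(rec, ".hea"))
  dat <- paste0(rec, ".dat")
  writeLines(c(sprintf("%s 2 %g %d", rec, segment$sampling_rate_hz, n),
               sprintf("%s 16 %g(0)/NU 16 0 0 0 0 %s", dat, ppg_gain,
                       ppg_name),
               sprintf("%s 16 %g(0)/mmHg 16 0 0 0 0 %s", dat, abp_gain,
                       abp_name)), hea)
  adc <- as.integer(round(rbind(segment$ppg * ppg_gain,
                                segment$abp * abp_gain)))
  if (any(abs(adc) > 32767))
    stop("signal exceeds 16-bit ADC range at the chosen gain", call. = FALSE)
  writeBin(as.vector(adc), file.path(dirname(record_path), dat), size = 2,
           endian = "little")
  invisible(hea)
}

#' Read a paired record
#'
#' Dispatches on file extension (`.csv` or `.hea`).  Both requested channels
#' must exist and the sampling rate must be 125 Hz; other rates are rejected
#' (no silent resampling).
#'
#' @param path Record path (`.csv`, or WFDB `.hea`).
#' @param ppg_channel,abp_channel Channel names to extract.
#' @return A continuous `paired_segment` with the raw channels untouched.
#' @export
read_record <- function(path, ppg_channel = "ppg", abp_channel = "abp") {
  if (!file.exists(path)) stop("record not found: ", path, call. = FALSE)
  if (grepl("\\.hea$", path)) {
    rec <- read_wfdb_record(path)
    chans <- colnames(rec$signals)
    for (ch in c(ppg_channel, abp_channel))
      if (!ch %in% chans)
        stop(sprintf("channel '%s' not found in %s (available: %s)", ch,
                     path, paste(chans, collapse = ", ")), call. = FALSE)
    if (rec$fs != EXPECTED_FS)
      stop(sprintf("record sampling rate is %g Hz; only %d Hz is supported",
                   rec$fs, EXPECTED_FS), call. = FALSE)
    ppg <- rec$signals[, ppg_channel]
    abp <- rec$signals[, abp_channel]
    sid <- sub("\\.hea$", "", basename(path))
    return(structure(list(ppg = ppg, abp = abp,
                          sampling_rate_hz = rec$fs, subject_id = sid,
                          segment_id = sid, meta = NULL),
                     class = "paired_segment"))
  }
  rec <- read_csv_record(path)
  for (ch in c(ppg_channel, abp_channel))
    if (!ch %in% names(rec$data))
      stop(sprintf("channel '%s' not found in %s (available: %s)", ch, path,
                   paste(names(rec$data), collapse = ", ")), call. = FALSE)
  if (is.na(rec$fs) || rec$fs != EXPECTED_FS)
    stop(sprintf("record sampling rate is %g Hz; only %d Hz is supported",
                 rec$fs, EXPECTED_FS), call. = FALSE)
  if (length(rec$data[[ppg_channel]]) != length(rec$data[[abp_channel]]))
    stop("channel lengths differ", call. = FALSE)
  structure(list(ppg = rec$data[[ppg_channel]],
                 abp = rec$data[[abp_channel]],
                 sampling_rate_hz = rec$fs, subject_id = rec$subject_id,
                 segment_id = rec$segment_id, meta = NULL),
            class = "paired_segment")
}

#' Cut a continuous record into fixed-length segments
#'
#' Emits `floor((n - segment_len) / stride) + 1` half-open windows
#' `[start, start + segment_len)`; any tail shorter than `segment_len` is
#' dropped.  Non-overlapping segmentation (`stride = segment_len`) is the
#' default.
#'
#' @param record A continuous `paired_segment`.
#' @param segment_len Window length in samples.
#' @param stride Hop between window starts (samples, at least 1).
#' @return A list of `paired_segment`s (empty, with a warning, when the
#'   record is shorter than one window).
#' @export
segment_record <- function(record, segment_len = 1024, stride = segment_len) {
  stopifnot(stride >= 1, segment_len >= 1)
  n <- length(record$ppg)
  if (segment_len > n) {
    warning(sprintf("record (%d samples) shorter than segment_len (%d); %s",
                    n, segment_len, "no segments emitted"))
    return(list())
  }
  n_seg <- (n - segment_len) %/% stride + 1
  lapply(seq_len(n_seg), function(k) {
    start <- (k - 1) * stride  # 0-based start
    idx <- (start + 1):(start + segment_len)
    structure(list(ppg = record$ppg[idx], abp = record$abp[idx],
                   sampling_rate_hz = record$sampling_rate_hz,
                   subject_id = record$subject_id,
                   segment_id = sprintf("%s_%04d", record$segment_id, k),
                   meta = list(start = start, parent = record$segment_id)),
              class = "paired_segment")
  })
}

#' Write a dataset as per-segment CSV records plus an index manifest
#'
#' @param dataset A `paired_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in dataset$segments)
    write_record_csv(s, file.path(dir, paste0(s$segment_id, ".csv")))
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A `paired_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  segments <- lapply(manifest$segment_id, function(id)
    read_record(file.path(dir, paste0(id, ".csv"))))
  for (i in seq_along(segments)) {
    segments[[i]]$subject_id <- manifest$subject_id[i]
  }
  structure(list(segments = segments, manifest = manifest),
            class = "paired_dataset")
}
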