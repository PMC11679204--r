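# Minimal GDF 2.20 reader/writer for cue-annotated motor-imagery
# recordings. Supports the subset of the format needed for benchmark-style
# sessions: a fixed 256-byte header, one 256-byte channel-header block,
# int16/float32/float64 data records, and a mode-1/mode-3 event table with
# trial-start (768) and cue (769..772) annotations. write_gdf_session()
# and load_gdf_session() round-trip exactly.

GDF_EVT_TRIAL_START <- 768L
GDF_EVT_CUE_BASE <- 768L   # cue codes 769..772 encode classes 1..4

pad_string <- function(s, n) {
  raw <- charToRaw(substr(s, 1, n))
  c(raw, raw(n - length(raw)))
}

#' Write a trial set as a GDF recording
#'
#' Trials are concatenated into one continuous recording (one data record
#' per trial); a trial-start event (code 768) is placed at each trial
#' onset and a cue event (codes 769-772 for classes 1-4) two seconds
#' later, following the benchmark trial timing.
#'
#' @param trials A [trial_set()] of full trials (window starting at 0).
#' @param path Output file path.
#' @param gdftyp Sample encoding: `"float32"` (default), `"float64"` or
#'   `"int16"` (int16 quantizes to the data range).
#' @return `path`, invisibly.
#' @export
write_gdf_session <- function(trials, path, gdftyp = c("float32", "float64", "int16")) {
  gdftyp <- match.arg(gdftyp)
  d <- dim(trials$data)
  nt <- d[1]; ns <- d[2]; spr <- d[3]
  fs <- trials$fs
  typ_code <- switch(gdftyp, int16 = 3L, float32 = 16L, float64 = 17L)
  dmax <- max(abs(trials$data), 1e-9)
  phys_min <- -dmax; phys_max <- dmax
  if (gdftyp == "int16") {
    dig_min <- -32767; dig_max <- 32767
  } else {
    dig_min <- phys_min; dig_max <- phys_max
  }

  con <- file(path, "wb")
  on.exit(close(con))
  # --- fixed header (256 bytes)
  writeBin(pad_string("GDF 2.20", 8), con)
  writeBin(pad_string("X X", 66), con)                      # patient id
  writeBin(raw(10 + 1 + 1 + 1 + 1), con)                    # reserved/patient fields
  writeBin(pad_string(sprintf("session %s subject %s",
                              trials$session_id, trials$subject_id), 80), con)
  writeBin(raw(200 - 168), con)                             # location/dates
  writeBin(as.integer((256 + 256 * ns) / 256), con, size = 2, endian = "little")
  writeBin(raw(236 - 202), con)                             # ICD, equipment, ...
  writeBin(c(nt, 0L), con, size = 4, endian = "little")     # NRec (int64 LE)
  writeBin(as.integer(c(spr, fs)), con, size = 4, endian = "little") # duration p/q
  writeBin(as.integer(ns), con, size = 2, endian = "little")
  writeBin(raw(2), con)
  # --- channel headers (grouped by field)
  labels <- if (ns == 22) montage_info(fs)$channel_names else
    sprintf("CH%02d", seq_len(ns))
  for (i in seq_len(ns)) writeBin(pad_string(paste0("EEG ", labels[i]), 16), con)
  for (i in seq_len(ns)) writeBin(pad_string("EEG electrode", 80), con)
  for (i in seq_len(ns)) writeBin(pad_string("uV", 6), con)
  writeBin(rep(4275L, ns), con, size = 2, endian = "little") # dim code for uV
  writeBin(rep(phys_min, ns), con, size = 8, endian = "little")
  writeBin(rep(phys_max, ns), con, size = 8, endian = "little")
  writeBin(rep(dig_min, ns), con, size = 8, endian = "little")
  writeBin(rep(dig_max, ns), con, size = 8, endian = "little")
  for (i in seq_len(ns)) writeBin(raw(68), con)             # legacy prefiltering
  writeBin(rep(0, 3 * ns), con, size = 4, endian = "little") # LP/HP/notch
  writeBin(rep(as.integer(spr), ns), con, size = 4, endian = "little")
  writeBin(rep(typ_code, ns), con, size = 4, endian = "little")
  for (i in seq_len(ns)) writeBin(raw(32), con)             # position, impedance, reserved
  # --- data records: one per trial, channel-major within record
  for (tr in seq_len(nt)) {
    x <- t(trials$data[tr, , ])                             # samples x channels -> per channel
    if (gdftyp == "int16") {
      q <- round((as.vector(x) - phys_min) / (phys_max - phys_min) *
                   (dig_max - dig_min) + dig_min)
      writeBin(as.integer(q), con, size = 2, endian = "little")
    } else {
      writeBin(as.vector(x), con,
               size = if (gdftyp == "float32") 4 else 8, endian = "little")
    }
  }
  # --- event table (mode 1): trial starts + cues
  pos <- integer(0); typ <- integer(0)
  for (tr in seq_len(nt)) {
    onset <- (tr - 1L) * spr + 1L
    pos <- c(pos, onset, onset + as.integer(round(2 * fs)))
    typ <- c(typ, GDF_EVT_TRIAL_START, GDF_EVT_CUE_BASE + trials$labels[tr])
  }
  nev <- length(pos)
  writeBin(as.raw(c(1L, nev %% 256L, (nev %/% 256L) %% 256L, nev %/% 65536L)), con)
  writeBin(fs, con, size = 4, endian = "little")            # event sample rate
  writeBin(as.integer(pos), con, size = 4, endian = "little")
  writeBin(as.integer(typ), con, size = 2, endian = "little")
  invisible(path)
}

read_gdf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- rawToChar(readBin(con, "raw", 8))
  assert_that(startsWith(version, "GDF"),
              sprintf("'%s' is not a GDF file (magic '%s')", path, version))
  seek(con, 200)
  head_len <- readBin(con, "integer", 1, size = 2, endian = "little",
                      signed = FALSE) * 256L
  seek(con, 236)
  nrec_lo <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")
  dur <- readBin(con, "integer", 2, size = 4, endian = "little")
  ns <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  nrec <- nrec_lo
  # channel headers
  seek(con, 256)
  labels <- vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, "raw", 16))), "")
  seek(con, 256 + ns * (16 + 80 + 6 + 2))
  phys_min <- readBin(con, "numeric", ns, size = 8, endian = "little")
  phys_max <- readBin(con, "numeric", ns, size = 8, endian = "little")
  dig_min <- readBin(con, "numeric", ns, size = 8, endian = "little")
  dig_max <- readBin(con, "numeric", ns, size = 8, endian = "little")
  seek(con, 256 + ns * (16 + 80 + 6 + 2 + 32 + 68 + 12))
  spr <- readBin(con, "integer", ns, size = 4, endian = "little")
  gdftyp <- readBin(con, "integer", ns, size = 4, endian = "little")
  assert_that(length(unique(spr)) == 1 && length(unique(gdftyp)) == 1,
              "channels with differing sampling or types are not supported")
  spr <- spr[1]; gdftyp <- gdftyp[1]
  fs <- spr * dur[2] / dur[1]
  assert_that(gdftyp %in% c(3L, 16L, 17L),
              sprintf("unsupported GDF sample type %d", gdftyp))
  # data records
  seek(con, head_len)
  nsamp_tot <- nrec * spr * ns
  raw_dat <- switch(as.character(gdftyp),
    "3" = readBin(con, "integer", nsamp_tot, size = 2, endian = "little"),
    "16" = readBin(con, "numeric", nsamp_tot, size = 4, endian = "little"),
    "17" = readBin(con, "numeric", nsamp_tot, size = 8, endian = "little"))
  assert_that(length(raw_dat) == nsamp_tot, "truncated GDF data section")
  # records are (samples x channels) per record, channel-major
  dat <- array(raw_dat, c(spr, ns, nrec))            # within record: samples fastest? see writer
  # writer emits per record: for each channel, spr samples -> dims (spr? no:
  # t(trials$data[tr, , ]) is samples x channels written column-major ->
  # samples fastest within channel: dims (spr, ns) per record.
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  if (gdftyp == 3L) {
    for (ch in seq_len(ns)) {
      dat[, ch, ] <- (dat[, ch, ] - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  # event table
  ev_head <- readBin(con, "raw", 8)
  events <- list(pos = integer(0), typ = integer(0))
  if (length(ev_head) == 8) {
    mode <- as.integer(ev_head[1])
    nev <- as.integer(ev_head[2]) + 256L * as.integer(ev_head[3]) +
      65536L * as.integer(ev_head[4])
    pos <- readBin(con, "integer", nev, size = 4, endian = "little")
    typ <- readBin(con, "integer", nev, size = 2, endian = "little",
                   signed = FALSE)
    events <- list(pos = pos, typ = typ, mode = mode)
  }
  list(data = dat, fs = fs, ns = ns, spr = spr, nrec = nrec,
       labels = labels, events = events)
}

#' Load a GDF session as full trials
#'
#' Reads a cue-annotated GDF recording and cuts one 7 s trial per cue
#' event (codes 769-772 mapping to classes 1-4), aligned to trial onset
#' (2 s before the cue). Recordings with more than 22 channels keep the
#' first 22 (the EEG montage); fewer than 22 is a format error, as is a
#' recording without any cue events.
#'
#' @param path GDF file path.
#' @param montage A [montage_info()] describing the expected montage.
#' @param trial_s Trial length in seconds (default 7).
#' @param cue_offset_s Cue latency within the trial (default 2).
#' @return A [trial_set()] of full trials with labels 1-4.
#' @export
load_gdf_session <- function(path, montage = montage_info(), trial_s = 7,
                             cue_offset_s = 2) {
  g <- read_gdf_raw(path)
  n_ch <- length(montage$channel_ids)
  assert_that(g$ns >= n_ch,
              sprintf("GDF file has %d channels; montage expects %d",
                      g$ns, n_ch))
  fs <- g$fs
  cont <- matrix(aperm(g$data[, seq_len(n_ch), , drop = FALSE], c(1, 3, 2)),
                 g$spr * g$nrec, n_ch)                # samples x channels
  cues <- which(g$events$typ %in% (GDF_EVT_CUE_BASE + 1:4))
  assert_that(length(cues) > 0, "no trials: the recording has no cue events")
  nsamp <- as.integer(round(trial_s * fs))
  off <- as.integer(round(cue_offset_s * fs))
  keep <- list(); labels <- integer(0)
  for (j in cues) {
    onset <- g$events$pos[j] - off                    # 1-based sample index
    if (onset < 1 || onset + nsamp - 1 > nrow(cont)) next
    keep[[length(keep) + 1L]] <- t(cont[onset:(onset + nsamp - 1L), ])
    labels <- c(labels, g$events$typ[j] - GDF_EVT_CUE_BASE)
  }
  assert_that(length(keep) > 0, "no trials: all cue events fall outside the recording")
  dat <- array(0, c(length(keep), n_ch, nsamp))
  for (i in seq_along(keep)) dat[i, , ] <- keep[[i]]
  trial_set(dat, labels, fs, window = c(0, nsamp / fs))
}
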