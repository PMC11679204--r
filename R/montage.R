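# Montage description and binary channel masks over the 22-electrode
# 10-20 layout used by four-class motor-imagery recordings.

#' Standard 22-channel motor-imagery montage
#'
#' Returns the montage used throughout the package: 22 electrodes placed
#' according to the international 10-20 system, indexed 1..22 in the order
#' they are conventionally printed, sampled at `fs` Hz.
#'
#' @param fs Sampling rate in Hz (default 250).
#' @return An object of class `montage_info` with fields `channel_ids`,
#'   `channel_names` and `fs`.
#' @export
montage_info <- function(fs = 250) {
  assert_that(is.numeric(fs) && fs > 0, "fs must be a positive number")
  names22 <- c(
    "Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    "P1", "Pz", "P2", "POz"
  )
  structure(
    list(channel_ids = 1:22, channel_names = names22, fs = fs),
    class = "montage_info"
  )
}

#' @export
print.montage_info <- function(x, ...) {
  cat(sprintf(
    "<montage_info> %d channels @ %g Hz: %s\n",
    length(x$channel_ids), x$fs, paste(x$channel_names, collapse = " ")
  ))
  invisible(x)
}

#' Create a binary channel mask
#'
#' A channel mask selects a subset of the 22 montage channels by their
#' 1-based printed indices. At least one channel must be selected.
#'
#' @param channels Integer vector of selected 1-based channel indices, or a
#'   logical vector of length `n_channels`.
#' @param n_channels Montage size (default 22).
#' @return Object of class `channel_mask`: logical vector with attribute.
#' @export
channel_mask <- function(channels, n_channels = 22) {
  if (is.logical(channels)) {
    assert_that(length(channels) == n_channels,
                "logical mask length must equal n_channels")
    bits <- channels
  } else {
    channels <- as.integer(channels)
    assert_that(length(channels) >= 1 && !anyNA(channels),
                "channels must be a non-empty integer vector")
    assert_that(all(channels >= 1 & channels <= n_channels),
                sprintf("channel indices must lie in 1..%d", n_channels))
    bits <- rep(FALSE, n_channels)
    bits[channels] <- TRUE
  }
  assert_that(any(bits), "a channel mask must select at least one channel")
  structure(bits, class = "channel_mask")
}

#' Parse a printed channel list
#'
#' Parses the compact notation used in published channel-selection tables,
#' e.g. `"3,8,10,11,13,15,16,18-22"`, into a [channel_mask()]. Ranges are
#' inclusive; an en-dash is accepted in place of a hyphen.
#'
#' @param text Character scalar.
#' @param n_channels Montage size (default 22).
#' @return A `channel_mask`.
#' @export
parse_channel_list <- function(text, n_channels = 22) {
  assert_that(is.character(text) && length(text) == 1L,
              "text must be a single string")
  s <- gsub("[][ ]", "", text)
  s <- gsub("–", "-", s) # en-dash as printed in tables
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  assert_that(length(parts) > 0, "empty channel list")
  ids <- integer(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      assert_that(length(ab) == 2 && !anyNA(ab) && ab[1] <= ab[2],
                  sprintf("malformed range '%s'", p))
      ids <- c(ids, seq(ab[1], ab[2]))
    } else {
      v <- suppressWarnings(as.integer(p))
      assert_that(!is.na(v), sprintf("malformed channel index '%s'", p))
      ids <- c(ids, v)
    }
  }
  channel_mask(sort(unique(ids)), n_channels = n_channels)
}

#' Format a channel mask in printed notation
#'
#' Inverse of [parse_channel_list()]: consecutive runs are collapsed with a
#' hyphen (`"18-22"`).
#'
#' @param mask A `channel_mask`.
#' @return Character scalar such as `"3,8,10,11,13,15,16,18-22"`.
#' @export
format_channel_mask <- function(mask) {
  ids <- which(unclass(mask))
  runs <- split(ids, cumsum(c(1L, diff(ids) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = ",")
}

#' Number of selected channels in a mask
#' @param mask A `channel_mask`.
#' @return Integer popcount.
#' @export
mask_popcount <- function(mask) sum(unclass(mask))

#' Write / read a channel mask file
#'
#' Masks are exchanged as one line of printed notation so that files are
#' interoperable with published channel lists.
#'
#' @param mask A `channel_mask`.
#' @param path File path.
#' @return `read_channel_mask` returns a `channel_mask`.
#' @export
write_channel_mask <- function(mask, path) {
  writeLines(format_channel_mask(mask), path)
  invisible(path)
}

#' @rdname write_channel_mask
#' @param n_channels Montage size (default 22).
#' @export
read_channel_mask <- function(path, n_channels = 22) {
  parse_channel_list(readLines(path, n = 1L), n_channels = n_channels)
}
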