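# GDF subset reader/writer: fixtures are written by the suite itself.

make_session <- function(n = 6, fs = 50, trial_s = 7, seed = 21) {
  withr::with_seed(seed, {
    ns <- trial_s * fs
    dat <- array(rnorm(n * 22 * ns, sd = 10), c(n, 22, ns))
    trial_set(dat, sample(rep_len(1:4, n)), fs,
              subject_id = 1, session_id = 1)
  })
}

test_that("a written session round-trips trials, labels and data", {
  ts <- make_session()
  path <- tempfile(fileext = ".gdf")
  write_gdf_session(ts, path)
  back <- load_gdf_session(path, montage_info(fs = ts$fs), trial_s = 7)
  expect_equal(n_trials(back), n_trials(ts))
  expect_equal(back$labels, ts$labels)
  expect_equal(back$fs, ts$fs)
  expect_equal(back$data, ts$data, tolerance = 1e-6)  # float32 storage
})

test_that("float64 storage round-trips exactly; int16 approximately", {
  ts <- make_session(n = 4, seed = 22)
  p64 <- tempfile(fileext = ".gdf")
  write_gdf_session(ts, p64, gdftyp = "float64")
  expect_identical(load_gdf_session(p64, montage_info(fs = ts$fs))$data,
                   ts$data)
  p16 <- tempfile(fileext = ".gdf")
  write_gdf_session(ts, p16, gdftyp = "int16")
  back <- load_gdf_session(p16, montage_info(fs = ts$fs))
  expect_equal(back$data, ts$data, tolerance = 1e-3)
  expect_equal(back$labels, ts$labels)
})

test_that("recordings without cue annotations raise a 'no trials' error", {
  ts <- make_session(n = 2, seed = 23)
  path <- tempfile(fileext = ".gdf")
  write_gdf_session(ts, path)
  # surgically zero the event count in the event-table header
  sz <- file.size(path)
  con <- file(path, "r+b")
  nev_offset <- sz - (8 + 2 * 2 * 4 + 2 * 2 * 2) + 1  # mode byte precedes NEV
  seek(con, nev_offset, rw = "write")
  writeBin(as.raw(c(0, 0, 0)), con)
  close(con)
  expect_error(load_gdf_session(path, montage_info(fs = ts$fs)), "no trials")
})

test_that("non-GDF files are rejected with a format error", {
  path <- tempfile()
  writeLines("definitely not EEG", path)
  expect_error(load_gdf_session(path), "not a GDF")
})

test_that("montages wider than the recording are rejected", {
  ts <- make_session(n = 2, seed = 24)
  sub <- trial_set(ts$data[, 1:8, , drop = FALSE], ts$labels, ts$fs)
  path <- tempfile(fileext = ".gdf")
  write_gdf_session(sub, path)
  expect_error(load_gdf_session(path, montage_info(fs = ts$fs)), "22")
})
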