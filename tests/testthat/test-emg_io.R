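test_that("channel labels parse case-insensitively and round-trip", {
  p <- parse_channel("sol-l")
  expect_equal(p$muscle, "Sol")
  expect_equal(p$side, "L")
  expect_equal(channel_name("ta-R"), "TA-R")
  expect_equal(channel_name("EMG_aux"), "EMG_aux")
  expect_equal(parse_channel("EMG_aux")$muscle, "other")
})

test_that("recording construction enforces the container invariants", {
  sig <- matrix(rnorm(100), ncol = 2)
  expect_s3_class(make_rec(sig, channels = c("Sol-L", "Sol-R")), "emg_recording")
  expect_error(make_rec(sig, channels = c("Sol-L", "Sol-L")), "duplicate")
  expect_error(make_rec(matrix(c(1, NA), ncol = 1), channels = "Sol-L"),
               "non-finite")
  expect_error(
    emg_recording(sig, channels = c("Sol-L", "Sol-R"), sampling_rate = -5,
                  animal_id = "x", group = "TTnoEB"),
    "sampling_rate")
  expect_error(
    emg_recording(sig, channels = c("Sol-L", "Sol-R"), sampling_rate = 2000,
                  animal_id = "x", group = "bogus"),
    "unknown group")
  # duration arithmetic: 2000 rows at 2 kHz = 1 s
  rec <- make_rec(matrix(rnorm(8000), ncol = 4))
  expect_equal(rec_duration(rec), 1.0)
})

test_that("write -> load round-trips metadata exactly and amplitudes to 1e-9", {
  set.seed(42)
  for (nsamp in c(1, 7, 400)) {
    rec <- make_rec(matrix(rnorm(nsamp * 4, sd = 10^runif(1, -3, 3)), ncol = 4),
                    group = "TTx2EB", condition = "pre_drug",
                    animal_id = "rat-7", t0 = 0.25)
    stem <- file.path(withr::local_tempdir(), "rec")
    write_recording(rec, stem)
    back <- load_recording(paste0(stem, ".csv"))
    expect_identical(back$animal_id, rec$animal_id)
    expect_identical(back$group, rec$group)
    expect_identical(back$condition, rec$condition)
    expect_identical(back$channels, rec$channels)
    expect_equal(back$sampling_rate, rec$sampling_rate)
    expect_equal(back$t0, rec$t0, tolerance = 1e-9)
    expect_equal(back$signal, rec$signal, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("loader rejects malformed files", {
  td <- withr::local_tempdir()
  rec <- make_rec(matrix(rnorm(40), ncol = 4))
  stem <- file.path(td, "rec")
  write_recording(rec, stem)

  # metadata field removed -> format error
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"))
  meta$group <- NULL
  jsonlite::write_json(meta, paste0(stem, ".meta.json"), auto_unbox = TRUE)
  expect_error(load_recording(paste0(stem, ".csv")), "metadata missing 'group'")

  # NaN cell -> data error
  write_recording(rec, stem)
  lines <- readLines(paste0(stem, ".csv"))
  lines[3] <- sub("^([^,]*),[^,]*", "\\1,NaN", lines[3])
  writeLines(lines, paste0(stem, ".csv"))
  expect_error(load_recording(paste0(stem, ".csv")), "non-finite")

  # non-uniform time column -> data error
  write_recording(rec, stem)
  lines <- readLines(paste0(stem, ".csv"))
  lines[4] <- sub("^[^,]*", "99.9", lines[4])
  writeLines(lines, paste0(stem, ".csv"))
  expect_error(load_recording(paste0(stem, ".csv")), "not uniform")

  # missing sidecar -> format error
  file.remove(paste0(stem, ".meta.json"))
  expect_error(load_recording(paste0(stem, ".csv")), "sidecar")
})

test_that("write_results emits tidy CSV plus JSON for tables and circ lists", {
  td <- withr::local_tempdir()
  tab <- data.frame(animal_id = c("a", "b"), group = "TTnoEB",
                    muscle = "Sol-L", cycle_s = c(1.0, 1.1))
  paths <- write_results(tab, file.path(td, "cycles"))
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[1])
  expect_equal(back$cycle_s, tab$cycle_s)

  # empty results -> header-only CSV
  write_results(tab[0, ], file.path(td, "empty"))
  expect_equal(nrow(read.csv(file.path(td, "empty.results.csv"))), 0)

  # circ_stat list -> JSON carrying mean_angle_deg, r, n
  cs <- list(mean_vector(c(10, 20, 30)), mean_vector(c(170, 180, 190)))
  class(cs) <- "circ_stat_list"
  write_results(cs, file.path(td, "coord"))
  js <- jsonlite::read_json(file.path(td, "coord.results.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_rows, 2)
  expect_true(all(c("mean_angle_deg", "r", "n") %in% js$columns))

  expect_error(write_results(list(1, 2), file.path(td, "x")), "unsupported")
})
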