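test_that("recording validation catches bad inputs", {
  expect_s3_class(recording(list(rnorm(100), rnorm(100)), 32000),
                  "bs_recording")
  expect_error(recording(list(rnorm(100), rnorm(99)), 32000),
               "length mismatch")
  expect_error(recording(rnorm(10), 0), "rate")
  x <- rnorm(50)
  x[17] <- NaN
  expect_error(recording(list(a = x), 1000, channel_ids = "micro3"),
               "micro3")
})

test_that("recording round-trips losslessly through float64", {
  rec <- recording(list(rnorm(5000, sd = 30), rnorm(5000, sd = 12)),
                   rate = 32000, channel_ids = c("A", "B"),
                   start_time = 2.5)
  path <- withr::local_tempdir()
  write_recording(rec, file.path(path, "rec"))
  back <- read_recording(file.path(path, "rec"))
  expect_identical(back$samples, rec$samples)
  expect_identical(back$rate, rec$rate)
  expect_identical(back$channel_ids, rec$channel_ids)
  expect_identical(back$start_time, rec$start_time)
})

test_that("int16 container scales with the sidecar gain", {
  x <- rnorm(2000, sd = 100)
  rec <- recording(list(x), 24000)
  path <- file.path(withr::local_tempdir(), "rec16")
  write_recording(rec, path, dtype = "int16")
  back <- read_recording(path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  # oracle: manual gain multiplication of the raw int16 payload
  con <- file(file.path(path, "samples.bin"), "rb")
  raw <- readBin(con, "integer", n = 2000, size = 2L, signed = TRUE,
                 endian = "little")
  close(con)
  expect_equal(back$samples[[1]], raw * meta$gain_uv[1])
  # quantization error bounded by half a bit
  expect_lt(max(abs(back$samples[[1]] - x)), meta$gain_uv[1])
})

test_that("unknown container formats are rejected", {
  path <- withr::local_tempdir()
  dir.create(file.path(path, "bogus"))
  jsonlite::write_json(list(container = "something_else"),
                       file.path(path, "bogus", "meta.json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(file.path(path, "bogus")),
               "unknown container")
  expect_error(read_recording(file.path(path, "missing")), "meta.json")
})

test_that("spike sets round-trip including the empty set", {
  sp <- make_toy_spikes(25)
  path <- file.path(withr::local_tempdir(), "sp")
  write_spikes(sp, path)
  back <- read_spikes(path)
  expect_equal(back$waveforms, sp$waveforms)
  expect_equal(back$times, sp$times)
  expect_identical(back$sign, sp$sign)

  empty <- spike_set(matrix(numeric(0), 0, 48), numeric(0),
                     rate_eff = 24000)
  p2 <- file.path(withr::local_tempdir(), "empty")
  write_spikes(empty, p2)
  back2 <- read_spikes(p2)
  expect_equal(n_spikes(back2), 0L)
  expect_equal(ncol(back2$waveforms), 48L)
})

test_that("sorting containers round-trip and validate their schema", {
  sp <- data.frame(time = c(1, 2, 5), cluster_id = c(1L, 1L, 0L),
                   original_cluster_id = c(1L, 1L, 0L),
                   block_index = c(1L, 1L, 1L),
                   assign_stage = c("SPC", "TM_within", "residual"))
  cl <- data.frame(cluster_id = 1L, block_index = 1L, size = 2L,
                   artifact = FALSE, criteria = "", group_id = 1L)
  srt <- sorting_result(sp, cl, matrix(rnorm(48), 1), "ch7", 24000)
  path <- file.path(withr::local_tempdir(), "srt")
  write_sorting(srt, path)
  back <- read_sorting(path)
  expect_equal(back$spikes, srt$spikes)
  expect_equal(back$clusters, srt$clusters)
  expect_equal(back$templates, srt$templates)
  expect_identical(back$channel_id, "ch7")

  # dropping a required column must fail loudly, not default silently
  broken <- data.table::fread(file.path(path, "spikes.csv"))
  broken$assign_stage <- NULL
  data.table::fwrite(broken, file.path(path, "spikes.csv"))
  expect_error(read_sorting(path), "assign_stage")

  # zero-spike container is valid
  e <- sorting_result(empty_spike_table(), empty_cluster_table(),
                      matrix(numeric(0), 0, 48))
  p2 <- file.path(withr::local_tempdir(), "e")
  write_sorting(e, p2)
  expect_equal(nrow(read_sorting(p2)$spikes), 0L)
})

test_that("config files reject unknown sections and keys", {
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  writeLines(c("sort:", "  N_block: 5000", "  C_max: 7"), path)
  cfg <- read_config(path)
  expect_equal(cfg$sort$N_block, 5000)
  expect_equal(cfg$sort$C_max, 7)
  expect_equal(cfg$sort$S_min, 15)   # untouched default

  writeLines(c("sort:", "  N_blok: 5000"), path)
  expect_error(read_config(path), "N_blok")
  writeLines(c("sorting:", "  N_block: 5000"), path)
  expect_error(read_config(path), "unknown config section")
})

test_that("parameter defaults match the framework's standard table", {
  p <- sort_params()
  expect_equal(p$N_block, 20000)
  expect_equal(p$C_max, 5)
  expect_equal(p$S_min, 15)
  expect_equal(p$R_min, 2000)
  expect_equal(p$N_rep, 1)
  expect_equal(p$f1, 0.75)
  expect_equal(p$f2, 3)
  expect_equal(p$C_stop, 1.8)
  expect_equal(p$n_T, 21)
  expect_equal(p$T_range, c(0, 0.2))
  a <- artifact_params()
  expect_equal(a$rate_bin, 500)
  expect_equal(a$rate_max_events, 100)
  expect_equal(a$amp_limit, 1000)
  expect_equal(a$double_window, 1.5)
  expect_equal(a$conc_bin, 3)
  expect_equal(a$conc_frac, 0.5)
  expect_equal(a$sem_limit, 2)
})

test_that("ungrouping reverts merges exactly", {
  cl <- data.frame(cluster_id = 1:3, block_index = c(1L, 1L, 2L),
                   size = c(10L, 12L, 9L),
                   artifact = c(FALSE, FALSE, TRUE),
                   criteria = c("", "", "sem"),
                   group_id = c(1L, 1L, NA))
  sp <- data.frame(time = 1:3, cluster_id = 1:3,
                   original_cluster_id = 1:3, block_index = c(1L, 1L, 2L),
                   assign_stage = "SPC")
  srt <- sorting_result(sp, cl, matrix(0, 3, 8))
  un <- ungroup_sorting(srt)
  expect_equal(un$clusters$group_id, c(1L, 2L, NA))
  expect_equal(un$spikes$original_cluster_id, srt$spikes$cluster_id)
})
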