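test_that("branching units spread round-robin across neurons", {
  b <- generateSurrogate("branching", n_neurons = 10, duration = 50,
                         sigma = 1, seed = 11)
  av_n <- extractAvalanches(b, delta_t = 1, size = "neurons")
  av_s <- extractAvalanches(b, delta_t = 1, size = "spikes")
  expect_true(all(av_n@sizes <= pmin(av_s@sizes, 10)))
  expect_true(any(av_n@sizes < av_s@sizes))  # bursts fold onto neurons
  expect_identical(length(av_n@sizes), length(av_s@sizes))
})

test_that("surrogate generation is seed-deterministic and validated", {
  a <- generateSurrogate("poisson", n_neurons = 5, rate = 10,
                         duration = 5, seed = 1)
  b <- generateSurrogate("poisson", n_neurons = 5, rate = 10,
                         duration = 5, seed = 1)
  expect_identical(spikeTimes(a), spikeTimes(b))
  expect_error(generateSurrogate("poisson", n_neurons = 0), "n_neurons")
  expect_error(generateSurrogate("jittered_sync", c_copy = 1.5), "c_copy")
})

test_that("rasters round-trip losslessly through the text format", {
  r <- generateSurrogate("gamma_renewal", n_neurons = 7, rate = 20,
                         duration = 3, shape = 2, seed = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRaster(r, f)
  r2 <- readRaster(f)
  expect_identical(spikeTimes(r2), spikeTimes(r))
  expect_identical(popLabels(r2), popLabels(r))
  expect_identical(rasterDuration(r2), rasterDuration(r))
})

test_that("the reader normalises, and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# critcap spike raster v1", "# n_E\t2", "# n_I\t0",
               "# duration_ms\t100",
               "1\t30", "1\t10", "2\t5"), f)
  expect_warning(r <- readRaster(f), "unsorted")
  expect_identical(spikeTimes(r)[[1]], c(10, 30))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# critcap spike raster v1", "# n_E\t1", "# n_I\t0",
               "# duration_ms\t100", "1\tnot_a_time"), f2)
  expect_error(readRaster(f2), "malformed raster line 5")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# critcap spike raster v1", "# n_I\t0",
               "# duration_ms\t100", "1\t2.0"), f3)
  expect_error(readRaster(f3), "n_E")
})
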