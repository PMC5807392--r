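test_that("raster CSV round-trips and malformed input is rejected", {
  r <- generate_raster(n_animals = 4, n_stimuli = 10, seed = 42,
                       latencies = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_identical(r2$responses, r$responses)
  expect_identical(r2$group, r$group)
  expect_equal(r2$latency, r$latency, tolerance = 1e-8)

  # a non-binary cell is rejected with row and column named
  df <- read.csv(path)
  df$s03[2] <- 2
  write.csv(df, path, row.names = FALSE)
  expect_error(read_raster(path), "row 2, column s03")

  # unknown group
  df$s03[2] <- 1
  df$group[1] <- "alpha"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_raster(path), "unknown group")

  # empty file is an error, not an empty raster
  writeLines("animal_id,group,frequency_hz,s01", path)
  expect_error(read_raster(path), "no animals")
})

test_that("binned percent response does the stated arithmetic", {
  # all-ones raster: every bin 100%, SEM 0
  r <- response_raster(matrix(1, 3, 8), "communal", 1)
  b <- binned_percent_response(r, 2)
  expect_equal(b$mean_percent, rep(100, 4))
  expect_equal(b$sem, rep(0, 4))

  # 2 animals, bin of 2, responses (1,1) and (1,0) in bin 1: mean 75, SEM 25
  m <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  b <- binned_percent_response(response_raster(m, "dominant", 1), 2)
  expect_equal(b$mean_percent[1], 75)
  expect_equal(b$sem[1], 25)

  # alternating responses with bin 2: all bins 50%
  m <- matrix(rep(c(1, 0), 10), nrow = 2, byrow = TRUE)
  b <- binned_percent_response(response_raster(m, "subordinate", 1), 2)
  expect_equal(b$mean_percent, rep(50, 5))

  # conservation: an all-k raster gives exactly 100k%
  m <- matrix(rep(c(1, 0, 0, 0), 4), nrow = 2, byrow = TRUE)  # k = 1/4
  b <- binned_percent_response(response_raster(m, "communal", 1), 4)
  expect_equal(b$mean_percent, rep(25, 2))

  expect_error(binned_percent_response(r, 3), "divide")
})

test_that("pooled block rates capture habituation", {
  # monotone habituating animal: block rates 1, 0, 0, ...
  m <- matrix(c(rep(1, 5), rep(0, 35)), nrow = 1)
  b <- pooled_block_rates(response_raster(m, "dominant", 1), 5)
  expect_equal(b$rate, c(1, rep(0, 7)))

  # uniform Bernoulli raster at large n: all blocks near 0.5
  pr <- list(communal = list(p0 = 0.5, plateau = 0.5, decay = 5))
  r <- generate_raster(pr, n_animals = 200, n_stimuli = 40, seed = 7)
  b <- pooled_block_rates(r, 5)
  expect_true(all(abs(b$rate - 0.5) < 0.05))

  # generator defaults habituate: block 1 above block 8 for every group
  r <- generate_raster(n_animals = 20, seed = 11)
  b <- pooled_block_rates(r, 5)
  for (g in unique(b$group)) {
    rg <- b$rate[b$group == g]
    expect_gt(rg[1], rg[8])
  }
})

test_that("generator is seeded, ordered by status, and frequency-sensitive", {
  r1 <- generate_raster(n_animals = 10, seed = 3)
  r2 <- generate_raster(n_animals = 10, seed = 3)
  expect_identical(r1$responses, r2$responses)
  r3 <- generate_raster(n_animals = 10, seed = 4)
  expect_false(identical(r1$responses, r3$responses))

  # subordinate-like animals keep responding, dominant-like stop
  r <- generate_raster(n_animals = 20, frequency = 1, seed = 5)
  rate <- tapply(rowMeans(r$responses), r$group, mean)
  expect_gt(rate[["subordinate"]], rate[["dominant"]])

  # the 0.2 Hz profiles respond more than the 1 Hz profiles in every group
  r02 <- generate_raster(default_profiles(0.2), n_animals = 50,
                         frequency = 0.2, seed = 6)
  r10 <- generate_raster(default_profiles(1), n_animals = 50,
                         frequency = 1, seed = 6)
  rate02 <- tapply(rowMeans(r02$responses), r02$group, mean)
  rate10 <- tapply(rowMeans(r10$responses), r10$group, mean)
  expect_true(all(rate02 > rate10))

  expect_error(generate_raster(list(communal = list(p0 = 1.5, plateau = 0,
                                                    decay = 3))),
               "p0 and plateau")
})

test_that("latency summaries pool responded trials per group", {
  m <- rbind(c(1, 1), c(1, 0))
  lat <- rbind(c(4, 6), c(5, NA))
  r <- response_raster(m, c("communal", "dominant"), 1, latency = lat)
  s <- latency_summary(r)
  comm <- s[s$group == "communal", ]
  expect_equal(comm$mean_ms, 5)
  expect_equal(comm$sem, 1)   # sd(c(4,6))/sqrt(2) = 1
  dom <- s[s$group == "dominant", ]
  expect_equal(dom$mean_ms, 5)
  expect_equal(dom$sem, 0)    # single observation, flagged not NaN
  expect_true(dom$single_obs)

  # large-n generator recovers the latency distribution mean
  r <- generate_raster(n_animals = 100, seed = 8, latencies = TRUE)
  s <- latency_summary(r)
  expect_true(all(abs(s$mean_ms - 5.7) < 0.15))

  expect_error(latency_summary(generate_raster(n_animals = 2, seed = 1)),
               "latency")
})

test_that("profile fitting recovers generator parameters", {
  r <- generate_raster(n_animals = 200, seed = 13)
  fit <- fit_habituation_profile(r)
  truth <- default_profiles(1)
  for (g in fit$group) {
    expect_lt(abs(fit$p0[fit$group == g] - truth[[g]]$p0), 0.05)
    expect_lt(abs(fit$plateau[fit$group == g] - truth[[g]]$plateau), 0.05)
  }
})
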