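# Paired-stimulation histogram analysis: background subtraction, percent
# responders, mean/SEM on the background-subtracted data, smoothing.

test_that("subtract_background does bin-by-bin arithmetic and conserves mass", {
  a <- flow_histogram(0:5, c(0, 10, 20, 10, 0), "agonist")
  n <- flow_histogram(0:5, c(5, 20, 10, 5, 0), "null")
  d <- subtract_background(a, n)
  expect_equal(d$diffs, c(-5, -10, 10, 5, 0))
  expect_equal(sum(d$diffs), 0)

  # identity: agonist == null -> all zero
  d0 <- subtract_background(a, flow_histogram(0:5, a$counts, "null"))
  expect_equal(d0$diffs, rep(0, 5))

  # unmatched totals are rescaled to the agonist total (sum still 0)
  n2 <- flow_histogram(0:5, c(10, 40, 20, 10, 0), "null")
  d2 <- subtract_background(a, n2)
  expect_equal(sum(d2$diffs), 0)
  expect_equal(d2$diffs, c(-5, -10, 10, 5, 0))

  # scale guard disabled: all-zero null leaves agonist counts
  nz <- flow_histogram(0:5, rep(0, 5), "null")
  expect_equal(subtract_background(a, nz, rescale = FALSE)$diffs, a$counts)

  expect_error(subtract_background(a, flow_histogram(1:6, n$counts, "null")),
               "bin edges")
  expect_error(
    subtract_background(a, flow_histogram(0:5, n$counts, "null",
                                          channel = "pZAP70")),
    "channels")
})

test_that("percent_responders counts positive-bin mass", {
  a <- flow_histogram(0:5, c(0, 10, 20, 10, 0), "agonist")
  n <- flow_histogram(0:5, c(5, 20, 10, 5, 0), "null")
  d <- subtract_background(a, n)
  expect_equal(percent_responders(d), 100 * 15 / 40)  # 37.5

  # all diffs <= 0 -> 0
  d_neg <- subtract_background(
    flow_histogram(0:5, c(1, 1, 1, 1, 0), "agonist"),
    flow_histogram(0:5, c(1, 1, 1, 1, 0), "null"))
  expect_equal(percent_responders(d_neg), 0)

  # empty null with rescale disabled -> every agonist cell responds
  d_all <- subtract_background(a, flow_histogram(0:5, rep(0, 5), "null"),
                               rescale = FALSE)
  expect_equal(percent_responders(d_all), 100)

  expect_error(percent_responders(
    subtract_background(flow_histogram(0:5, rep(0, 5), "agonist"),
                        flow_histogram(0:5, rep(0, 5), "null"))),
    "zero agonist")
})

test_that("percent_responders is invariant to uniform bin refinement", {
  a <- c(0, 10, 20, 10, 0)
  n <- c(5, 20, 10, 5, 0)
  coarse <- subtract_background(flow_histogram(0:5, a, "agonist"),
                                flow_histogram(0:5, n, "null"))
  fine <- subtract_background(
    flow_histogram(seq(0, 5, by = 0.5), rep(a / 2, each = 2), "agonist"),
    flow_histogram(seq(0, 5, by = 0.5), rep(n / 2, each = 2), "null"))
  expect_equal(percent_responders(fine), percent_responders(coarse))
})

test_that("response_stats computes positive-mass weighted mean and SEM", {
  d <- subtract_background(flow_histogram(0.5:5.5, c(0, 10, 20, 10, 0),
                                          "agonist"),
                           flow_histogram(0.5:5.5, c(5, 20, 10, 5, 0),
                                          "null"))
  # centers 1..5; positives 10 at 3 and 5 at 4
  st <- response_stats(d)
  expect_equal(st$mean_intensity, 10 / 3)
  expect_equal(st$positive_mass, 15)
  v <- (10 * (3 - 10 / 3)^2 + 5 * (4 - 10 / 3)^2) / 15
  expect_equal(st$sem_intensity, sqrt(v / 15))

  # doubling diffs: mean unchanged, SEM / sqrt(2)
  d2 <- d; d2$diffs <- 2 * d$diffs
  st2 <- response_stats(d2)
  expect_equal(st2$mean_intensity, st$mean_intensity)
  expect_equal(st2$sem_intensity, st$sem_intensity / sqrt(2))

  # single positive bin -> SEM 0; no positive bin -> NA stats, 0 responders
  d1 <- d; d1$diffs <- c(0, 0, 7, 0, 0)
  expect_equal(response_stats(d1)$sem_intensity, 0)
  dn <- d; dn$diffs <- c(-3, -2, 0, 0, 0)
  stn <- response_stats(dn)
  expect_equal(stn$percent_responders, 0)
  expect_true(is.na(stn$mean_intensity))
})

test_that("smoothing is a centered, edge-truncated moving average", {
  d <- subtract_background(flow_histogram(0:5, c(0, 0, 9, 0, 0), "agonist"),
                           flow_histogram(0:5, rep(0, 5), "null"),
                           rescale = FALSE)
  expect_equal(smooth_diffs(d, 3)$diffs, c(0, 3, 3, 3, 0))
  expect_equal(smooth_diffs(d, 1)$diffs, d$diffs)       # identity
  dc <- d; dc$diffs <- rep(4, 5)
  expect_equal(smooth_diffs(dc, 3)$diffs, rep(4, 5))    # constant unchanged
  expect_true(smooth_diffs(d, 3)$smoothed)
})

test_that("normalize_to_control divides paired mean intensities", {
  mk <- function(mean) {
    structure(list(percent_responders = 50, mean_intensity = mean,
                   sem_intensity = 1, positive_mass = 100),
              class = "response_stats")
  }
  expect_equal(normalize_to_control(mk(16.0), mk(29.1)), 16 / 29.1)
  expect_equal(normalize_to_control(mk(5), mk(5)), 1.0)
  expect_error(normalize_to_control(mk(5), mk(0)), "positive")
})

test_that("histogram CSV round-trips", {
  h <- flow_histogram(seq(0, 5, length.out = 6), c(1, 5, 9, 2, 0), "agonist")
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, path)
  h2 <- read_histogram_csv(path, label = "agonist")
  expect_equal(h2$bin_edges, h$bin_edges)
  expect_equal(h2$counts, h$counts)
})
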