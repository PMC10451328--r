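test_that("bandpass filter attenuates out-of-band and passes in-band tones", {
  # oracle: frequency response of the designed filter, squared because the
  # filter is applied forward and backward
  filt <- signal::butter(2, c(0.5, 300) / 1000, type = "pass")
  gain_at <- function(f, fs) {
    h <- signal::freqz(filt, Fs = fs, n = 4096)
    idx <- which.min(abs(h$f - f))
    abs(h$h[idx])^2
  }

  rec <- sine_record(500, fs = 2000, seconds = 4)
  out <- bandpass_filter(rec, 0.5, 300, order = 2)
  core <- 1000:7000  # avoid filtfilt edge transients
  ratio <- rms(out$samples[1, core]) / rms(rec$samples[1, core])
  expect_lt(ratio, 0.10)
  expect_equal(ratio, gain_at(500, 2000), tolerance = 0.05)

  rec50 <- sine_record(50, fs = 2000, seconds = 4)
  out50 <- bandpass_filter(rec50, 0.5, 300, order = 2)
  ratio50 <- rms(out50$samples[1, core]) / rms(rec50$samples[1, core])
  expect_gt(ratio50, 0.8)
  expect_lt(abs(ratio50 - 1), 0.2)
})

test_that("bandpass filter maps zeros to zeros, preserves metadata, rejects bad bands", {
  rec <- signal_record(matrix(0, 2, 4000), fs = 1000, subject_id = "rat1",
                       context_id = "running")
  out <- bandpass_filter(rec)
  expect_equal(out$samples, rec$samples)
  expect_identical(dim(out$samples), dim(rec$samples))
  expect_identical(out$subject_id, "rat1")
  expect_identical(out$context_id, "running")

  expect_error(bandpass_filter(signal_record(matrix(0, 1, 100), fs = 500), 0.5, 300),
               "Nyquist")
  expect_error(bandpass_filter(signal_record(matrix(numeric(0), 1, 0), fs = 1000)),
               "empty")
})

test_that("segment_behavior mode=all is the identity", {
  rec <- signal_record(matrix(rnorm(300), 3, 100), fs = 100)
  expect_identical(segment_behavior(rec, "all"), rec)
})

test_that("segment_behavior concatenates annotated intervals in temporal order", {
  samp <- matrix(seq_len(1000), nrow = 1)
  ann <- tibble::tibble(label = c("grab", "grab"),
                        start_sample = c(400L, 100L), end_sample = c(500L, 200L))
  rec <- signal_record(samp, fs = 1000, annotations = ann)
  out <- segment_behavior(rec, "intervals")
  expect_equal(ncol(out$samples), 200L)
  # half-open [100,200) and [400,500), 0-based -> values 101..200 then 401..500
  expect_equal(out$samples[1, ], c(101:200, 401:500))
})

test_that("segment_behavior threshold mode keeps scalar-channel exceedances", {
  samp <- matrix(rnorm(1000), nrow = 1)
  rec <- signal_record(samp, fs = 1000, scalar = 0:999)
  out <- segment_behavior(rec, "threshold", threshold = 900)
  expect_equal(ncol(out$samples), sum(0:999 >= 900))  # brute-force count
  expect_equal(out$samples[1, ], samp[1, which(0:999 >= 900)])
  expect_error(segment_behavior(rec, "threshold"), "threshold")
  expect_error(segment_behavior(rec, "intervals"), "annotations")
})

test_that("empty segmentation errors and names the subject and context", {
  rec <- signal_record(matrix(rnorm(100), 1, 100), fs = 100, subject_id = "rat7",
                       context_id = "pressing", scalar = rep(0, 100))
  expect_error(segment_behavior(rec, "threshold", threshold = 5), "rat7")
  expect_error(segment_behavior(rec, "threshold", threshold = 5), "pressing")
})

test_that("frame_trials cuts non-overlapping trials and discards the remainder", {
  rec <- signal_record(matrix(rnorm(2 * 10000), 2, 10000), fs = 1000)
  ts <- frame_trials(rec, trial_seconds = 2)
  expect_equal(dim(ts$trials), c(2, 2000, 5))
  # trials tile the signal without overlap
  expect_equal(ts$trials[, , 2], rec$samples[, 2001:4000])

  rec2 <- signal_record(matrix(rnorm(9500), 1, 9500), fs = 1000)
  ts2 <- frame_trials(rec2, 2)
  expect_equal(dim(ts2$trials)[3], 4L)

  expect_error(frame_trials(signal_record(matrix(rnorm(1000), 1, 1000), fs = 1000), 2),
               "shorter")
})

test_that("frame_trials count equals floor(total/trial_samples) over random lengths", {
  set.seed(3)
  for (n in sample(200:5000, 25)) {
    rec <- signal_record(matrix(0, 1, n), fs = 100)
    exp_k <- n %/% 200
    if (exp_k == 0L) {
      expect_error(frame_trials(rec, 2))
    } else {
      expect_equal(dim(frame_trials(rec, 2)$trials)[3], exp_k)
    }
  }
})

test_that("interval segmentation output length equals the sum of interval lengths", {
  set.seed(4)
  for (rep in 1:10) {
    n <- 2000
    starts <- sort(sample(0:(n - 100), 4))
    ends <- pmin(starts + sample(10:80, 4), n)
    keep <- ends > starts
    # make intervals disjoint by construction
    ok <- c(TRUE, starts[-1] >= head(ends, -1))
    ann <- tibble::tibble(label = "e", start_sample = starts[ok & keep],
                          end_sample = ends[ok & keep])
    rec <- signal_record(matrix(0, 1, n), fs = 100, annotations = ann)
    out <- segment_behavior(rec, "intervals")
    expect_equal(ncol(out$samples), sum(ann$end_sample - ann$start_sample))
  }
})
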