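sim_session <- function(entries = numeric(), amp = 0, noise = 0,
                        bleach = Inf, duration = 60, raw_rate = 400,
                        seed = 1, ...) {
  tr <- session_truth(entry_times_social = entries,
                      event_response_amplitude = amp, noise_sd = noise,
                      bleach_tau = bleach)
  simulate_photometry(tr, duration, raw_rate = raw_rate, seed = seed, ...)
}

test_that("demultiplexing splits constant channels without cross-talk", {
  s <- sim_session(duration = 5, seed = 1)
  s$f465 <- rep(5, nrow(s)); s$f405 <- rep(2, nrow(s))
  ch <- demultiplex(s)
  expect_true(all(ch$ch465$f == 5))
  expect_true(all(ch$ch405$f == 2))
  # one sample per on-pulse per channel: 40 Hz alternation = 20 Hz each
  expect_equal(1 / median(diff(ch$ch465$t_s)), 20, tolerance = 0.01)
})

test_that("demultiplexed values equal pulse means recomputed from raw", {
  s <- sim_session(entries = c(2, 4), amp = 0.1, noise = 0.02,
                   duration = 8, seed = 3)
  ch <- demultiplex(s, settle_discard = 0.2)
  # independent recomputation straight from raw samples and labels
  r <- rle(s$led_state)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  k <- which(r$values == "465")[3]
  idx <- starts[k]:ends[k]
  keep <- idx[(floor(0.2 * length(idx)) + 1):length(idx)]
  expect_equal(ch$ch465$f[3], mean(s$f465[keep]))
  expect_equal(ch$ch465$t_s[3], mean(s$t_s[idx]))
  expect_error(demultiplex(data.frame(t_s = 1, f465 = 1, f405 = 1)),
               class = "demux_error")
})

test_that("dF/F definition: F == F0 gives 0, F = 2 F0 gives 1", {
  tr <- data.frame(t_s = seq(0, 10, 0.1), f = 50)
  dff <- compute_dff(tr, c(0, 5))
  expect_true(all(dff$dff == 0))
  tr2 <- tr; tr2$f[tr2$t_s > 5] <- 100
  dff2 <- compute_dff(tr2, c(0, 4.9))
  expect_equal(max(dff2$dff), 1)
  expect_error(compute_dff(data.frame(t_s = 1:3, f = c(-5, -5, -5)),
                           c(0, 3)), class = "baseline_error")
})

test_that("dF/F and z-scores are gain-invariant", {
  s <- sim_session(entries = c(10, 25), amp = 0.1, noise = 0.01,
                   duration = 40, seed = 5)
  ch <- demultiplex(s)
  dff1 <- compute_dff(ch$ch465, c(0, 8))
  for (c_gain in c(0.5, 3, 1000)) {
    scaled <- ch$ch465; scaled$f <- scaled$f * c_gain
    dff2 <- compute_dff(scaled, c(0, 8))
    expect_equal(dff2$dff, dff1$dff, tolerance = 1e-12)
  }
  ev <- data.frame(stimulus = "social", t_entry = c(10, 25),
                   included = TRUE)
  p <- build_peth(dff1, ev, window = c(-2, 5))
  ws1 <- peth_zscore_summary(p, dff1)
  scaled <- ch$ch465; scaled$f <- scaled$f * 7
  dffs <- compute_dff(scaled, c(0, 8))
  ws2 <- peth_zscore_summary(build_peth(dffs, ev, window = c(-2, 5)), dffs)
  expect_equal(ws1$per_stimulus$mean_z, ws2$per_stimulus$mean_z,
               tolerance = 1e-9)
})

test_that("isosbestic correction removes a shared artifact", {
  # artifact only: corrected flat, uncorrected shows the artifact
  s <- sim_session(duration = 30, motion_times = c(10, 20),
                   motion_amplitude = 8, motion_dur = 1, seed = 2)
  ch <- demultiplex(s)
  un <- compute_dff(ch$ch465, c(0, 8))
  co <- isosbestic_correct(ch$ch465, ch$ch405)
  expect_gt(max(abs(un$dff)), 0.05)
  # flat away from the square-artifact edges (interpolating the
  # interleaved 405 across a step leaves single-sample edge residue)
  edges <- c(10, 11, 20, 21)
  interior <- sapply(co$t_s, function(x) all(abs(x - edges) > 0.05))
  expect_lt(max(abs(co$dff[interior])), 1e-6)
  expect_lt(max(abs(co$dff)), max(abs(un$dff)))
  # identical channels give identically zero
  co2 <- isosbestic_correct(ch$ch465, ch$ch465)
  expect_true(all(abs(co2$dff) < 1e-12))
  # constant 405 channel: degenerate fit
  s4 <- sim_session(entries = 15, amp = 0.1, duration = 30, seed = 4)
  ch4 <- demultiplex(s4)
  expect_error(isosbestic_correct(ch4$ch465, ch4$ch405),
               class = "correction_error")
  # event-only noisy trace: corrected approximately equals uncorrected
  s3 <- sim_session(entries = 15, amp = 0.1, noise = 0.005,
                    duration = 30, seed = 4)
  ch3 <- demultiplex(s3)
  un3 <- compute_dff(ch3$ch465, c(0, 8))
  co3 <- isosbestic_correct(ch3$ch465, ch3$ch405)
  expect_equal(max(co3$dff), max(un3$dff), tolerance = 0.15)
})

test_that("PETH of a flat trace is zero; rows match the planted kernel", {
  flat <- structure(data.frame(t_s = seq(0, 100, 0.05), dff = 0),
                    class = c("dff_trace", "data.frame"))
  ev <- data.frame(stimulus = "social", t_entry = c(20, 50),
                   included = TRUE)
  p <- build_peth(flat, ev, window = c(-5, 10))
  expect_true(all(p$mat == 0))
  expect_true(0 %in% p$time)
  # noiseless planted transient is recovered on the PETH row
  s <- sim_session(entries = 30, amp = 0.06, duration = 60,
                   raw_rate = 1000, seed = 7)
  ch <- demultiplex(s)
  dff <- compute_dff(ch$ch465, c(0, 10))
  p2 <- build_peth(dff, data.frame(stimulus = "social", t_entry = 30,
                                   included = TRUE), window = c(-2, 8))
  expected <- 0.06 * dexp_kernel(p2$time - 0.2)
  # pulse averaging low-passes the steep rise: allow ~10% of amplitude
  expect_lt(max(abs(p2$mat[1, ] - expected)), 0.007)
  expect_lt(mean(abs(p2$mat[1, ] - expected)), 5e-4)
  # events too close to the edges are dropped; none usable errors
  expect_error(build_peth(dff, data.frame(stimulus = "social",
                                          t_entry = 59, included = TRUE),
                          window = c(-2, 8)),
               class = "empty_peth_error")
})

test_that("PETH mean is invariant to event order", {
  s <- sim_session(entries = c(10, 20, 30), amp = 0.05, noise = 0.02,
                   duration = 50, seed = 9)
  ch <- demultiplex(s)
  dff <- compute_dff(ch$ch465, c(0, 5))
  ev <- data.frame(stimulus = "social", t_entry = c(10, 20, 30),
                   included = TRUE)
  p1 <- build_peth(dff, ev, window = c(-2, 5))
  p2 <- build_peth(dff, ev[c(3, 1, 2), ], window = c(-2, 5))
  expect_equal(p1$mean, p2$mean)
})

test_that("z-normalization identities hold", {
  # peth mean identical to session mean -> z = 0; mu + sigma -> z = 1
  dff <- structure(data.frame(t_s = seq(0, 99.9, 0.1),
                              dff = rep(c(0.1, 0.3), 500)),
                   class = c("dff_trace", "data.frame"))
  mu <- mean(dff$dff); sigma <- sd(dff$dff)
  fake_peth <- list(time = 0:5, mat = matrix(mu, 2, 6),
                    events = data.frame(event_id = 1:2,
                                        stimulus = "social",
                                        t_entry = c(10, 20)),
                    mean = rep(mu, 6))
  class(fake_peth) <- "peth"
  ws <- peth_zscore_summary(fake_peth, dff)
  expect_equal(ws$per_stimulus$mean_z, 0)
  fake_peth$mat[] <- mu + sigma
  ws2 <- peth_zscore_summary(fake_peth, dff)
  expect_equal(ws2$per_stimulus$mean_z, 1)
  const <- dff; const$dff <- 1
  expect_error(peth_zscore_summary(fake_peth, const),
               class = "normalization_error")
})

test_that("session self z-score has mean 0 and SD 1 to 1e-9", {
  s <- sim_session(entries = c(10, 30), amp = 0.08, duration = 60,
                   seed = 11)
  ch <- demultiplex(s)
  dff <- compute_dff(ch$ch465, c(0, 10))
  z <- (dff$dff - mean(dff$dff)) / sd(dff$dff)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
})

test_that("random events on a stationary trace give null mean z", {
  for (seed in c(1, 2, 3)) {
    s <- sim_session(amp = 0, noise = 0.02, duration = 400,
                     raw_rate = 200, seed = seed)
    ch <- demultiplex(s)
    dff <- compute_dff(ch$ch465, c(0, 60))
    set.seed(seed + 100)
    ev <- data.frame(stimulus = "social",
                     t_entry = sort(runif(120, 10, 380)),
                     included = TRUE)
    p <- build_peth(dff, ev, window = c(-2, 6))
    ws <- peth_zscore_summary(p, dff)
    se <- sd(ws$per_event$mean_z) / sqrt(nrow(ws$per_event))
    expect_lt(abs(ws$per_stimulus$mean_z), 3 * se)
  }
})

test_that("planted response amplitude maps monotonically to the z gap", {
  gaps <- vapply(c(0, 0.03, 0.08), function(a) {
    entries_s <- seq(70, 370, by = 20)
    entries_o <- seq(80, 380, by = 20)
    tr <- session_truth(entry_times_social = entries_s,
                        entry_times_object = entries_o,
                        event_response_amplitude = a, noise_sd = 0.01,
                        bleach_tau = Inf)
    s <- simulate_photometry(tr, 400, raw_rate = 200,
                             habituation_dur = 60, seed = 31)
    ch <- demultiplex(s)
    dff <- compute_dff(ch$ch465, c(0, 60))
    ev <- rbind(data.frame(stimulus = "social", t_entry = entries_s),
                data.frame(stimulus = "object", t_entry = entries_o))
    ev$included <- TRUE
    ws <- peth_zscore_summary(build_peth(dff, ev),
                              dff[dff$t_s >= 60, ])
    ps <- ws$per_stimulus
    ps$mean_z[ps$stimulus == "social"] -
      ps$mean_z[ps$stimulus == "object"]
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), 0.5)  # no amplitude: no appreciable gap
})
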