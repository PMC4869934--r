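# Trace feature extraction: peaks, first response, refractory delay,
# half-times, cycle durations.

test_that("detect_peaks finds prominent maxima and honors separation", {
  t <- seq(0, 600, by = 1)
  s <- sin(2 * pi * t / 100)
  pk <- detect_peaks(t, s, min_prominence = 0.5, min_separation = 40)
  expect_equal(nrow(pk), 6)
  expect_true(all(abs(diff(pk$time) - 100) <= 1))
  # strictly monotone series has no peaks
  expect_equal(nrow(detect_peaks(t, t / 600, 0.1, 0)), 0)
  # prominence threshold separates a large and a small bump
  t2 <- seq(0, 100, by = 1)
  s2 <- 1.0 * exp(-(t2 - 30)^2 / 20) + 0.2 * exp(-(t2 - 70)^2 / 20)
  pk2 <- detect_peaks(t2, s2, min_prominence = 0.5,
                      min_separation = 10)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$time, 30)
  # close twin peaks: only the more prominent survives the separation
  s3 <- 1.0 * exp(-(t2 - 40)^2 / 20) + 0.8 * exp(-(t2 - 50)^2 / 20)
  pk3 <- detect_peaks(t2, s3, min_prominence = 0.05,
                      min_separation = 30)
  expect_equal(nrow(pk3), 1)
})

test_that("first_response normalizes to the ratio at treatment", {
  t <- seq(0, 200, by = 5)
  nc <- rep(0.8, length(t))
  nc[t > 100 & t <= 140] <- 0.8 + (t[t > 100 & t <= 140] - 100) * 0.03
  nc[t == 125] <- 2.0
  tr <- list(time = t, nc = nc)
  fr <- first_response(tr, window = 60, t_treat = 100)
  expect_equal(fr$amplitude, 2.0 / 0.8)
  expect_equal(fr$time_to_peak_min, 25)
  expect_false(fr$censored)
  # flat series: amplitude 1, censored time-to-peak
  fl <- first_response(list(time = t, nc = rep(0.5, length(t))),
                       window = 60, t_treat = 100)
  expect_equal(fl$amplitude, 1)
  expect_true(fl$censored)
  # degenerate zero ratio at treatment
  expect_error(first_response(list(time = t, nc = rep(0, length(t))),
                              window = 60, t_treat = 100),
               "degenerate")
})

test_that("refractory_delay reports time to the second peak or censors", {
  t <- seq(0, 300, by = 5)
  nc <- 1 + 2 * exp(-(t - 20)^2 / 50) + 1.5 * exp(-(t - 120)^2 / 50)
  rd <- refractory_delay(list(time = t, nc = nc), t_treat = 0,
                         min_prominence = 0.2, min_separation = 40)
  expect_equal(rd$delay_min, 120)
  expect_false(rd$censored)
  one <- refractory_delay(
    list(time = t, nc = 1 + 2 * exp(-(t - 20)^2 / 50)), t_treat = 0)
  expect_true(one$censored)
  expect_true(is.na(one$delay_min))
})

test_that("refractory delay equals time-to-peak plus peak interval on a
           simulated base-model trace", {
  eq <- base_equilibrium()
  tr <- simulate_nfkb(nfkb_model("base"), state0 = eq,
                      protocol = stimulus_protocol(0, Inf, 1),
                      times = seq(0, 500, by = 2))
  rd <- refractory_delay(tr, t_treat = 0, min_prominence = 1,
                         min_separation = 40)
  fr <- first_response(tr, window = 100, t_treat = 0)
  expect_equal(rd$delay_min,
               fr$time_to_peak_min + diff(rd$peaks$time[1:2]),
               tolerance = 2 / rd$delay_min)
})

test_that("half_times recovers analytic half-lives and censors flats", {
  t <- seq(0, 300, by = 1)
  ht <- half_times(list(time = t, nc = rep(1, length(t)),
                        e2f = exp(-log(2) / 60 * t)))
  expect_equal(ht$t_half_e2f_min, 60, tolerance = 1 / 60)
  expect_true(ht$occupancy_censored)
  # N:C stepping from 3 to plateau 1, crossing 2 at t = 40
  nc <- c(seq(3, 1, length.out = 81), rep(1, length(t) - 81))
  ht2 <- half_times(list(time = t, nc = nc, e2f = NULL))
  expect_equal(ht2$t_half_occupancy_min, 40, tolerance = 1e-6)
  # constant N:C is censored
  ht3 <- half_times(list(time = t, nc = rep(2, length(t)),
                         e2f = NULL))
  expect_true(ht3$occupancy_censored)
})

test_that("cycle_durations computes mitosis differences and exclusions", {
  mk <- function(id, mitoses) structure(
    list(cell_id = id, time_min = seq(0, 3000, 5),
         mitosis_times_min = mitoses,
         treatment_time_min = NA_real_),
    class = "cell_trace")
  d <- cycle_durations(list(mk("a", c(5, 25) * 60),
                            mk("b", c(100)),
                            mk("c", c(2, 20, 41) * 60)))
  expect_equal(d$duration_h[d$cell_id == "a"], 20)
  expect_equal(d$duration_h[d$cell_id == "c"], c(18, 21))
  expect_equal(attr(d, "n_excluded"), 1)
  # spanning selection picks the cycle containing the given time
  ds <- cycle_durations(list(mk("c", c(2, 20, 41) * 60)),
                        spanning_time_min = 30 * 60)
  expect_equal(ds$duration_h, 21)
})

test_that("generator durations recover the programmed mean", {
  pop <- duration_population(200, seed = 5, dose = 0)
  d <- cycle_durations(pop)
  d1 <- d[!duplicated(d$cell_id), ]
  se <- sd(d1$duration_h) / sqrt(nrow(d1))
  expect_lt(abs(mean(d1$duration_h) - 20), 3 * se + 0.05)
})

test_that("features are invariant under common rescaling of channels", {
  pop <- tiny_population(n = 3, seed = 42)
  tr <- pop$traces[[1]]
  f1 <- first_response(tr)
  tr2 <- tr
  tr2$nuc_mean <- tr$nuc_mean * 13.7
  tr2$cyt_mean <- tr$cyt_mean * 13.7
  f2 <- first_response(tr2)
  expect_equal(f1$amplitude, f2$amplitude)
  expect_equal(f1$time_to_peak_min, f2$time_to_peak_min)
})

test_that("first-response amplitude falls monotonically with E2F-4", {
  bg <- 10
  amps <- vapply(c(0, 1, 4), function(e4) {
    m <- nfkb_model("revised", overrides = c(kE4drv = e4, kE1syn = 0))
    st <- simulate_nfkb(m, protocol = NULL,
                        times = seq(0, 60000, 1000))$state
    y <- st[nrow(st), ]; y[y < 0] <- 0
    tr <- simulate_nfkb(m, state0 = y,
                        protocol = stimulus_protocol(0, Inf, 1),
                        times = seq(0, 240, by = 2))
    nuc <- rowSums(tr$state[, c("NFkB_n", "NFkB.IkBa_n",
                                "NFkB.E2F1_n")]) + bg
    cyt <- rowSums(tr$state[, c("NFkB_c", "NFkB.IkBa_c",
                                "NFkB.IkBa.E2F4_c")]) + bg
    nc <- nuc / cyt
    max(nc) / nc[1]
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})
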