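# ODE model family: construction, equilibria, simulation contracts.

test_that("variant species sets are nested and base excludes E2F species", {
  mb <- nfkb_model("base")
  me <- nfkb_model("e2f1")
  mr <- nfkb_model("revised")
  expect_false(any(grepl("E2F", mb$species)))
  expect_true(all(mb$species %in% me$species))
  expect_true(all(me$species %in% mr$species))
  expect_gt(length(me$species), length(mb$species))
  expect_gt(length(mr$species), length(me$species))
  expect_identical(mb$stimulus_coupling, "ka")
})

test_that("model construction validates inputs", {
  expect_error(nfkb_model("bogus"))
  expect_error(nfkb_model("base", overrides = c(nope = 1)), "unknown")
  expect_error(nfkb_model("base", overrides = c(ka = -1)),
               "non-negative")
  expect_error(nfkb_model("base", overrides = c(hN = 0.5)), "Hill")
  expect_error(nfkb_model("base", overrides = c(KN = 0)), "positive")
  # zeroing a coupling rate is allowed
  expect_s3_class(nfkb_model("e2f1", overrides = c(kE1syn = 0)),
                  "nfkb_model")
})

test_that("zeroed E2F couplings reduce each variant to its parent exactly", {
  eq <- base_equilibrium()
  times <- seq(0, 400, by = 4)
  prot <- stimulus_protocol(0, Inf, 1)
  mb <- nfkb_model("base")
  me0 <- nfkb_model("e2f1", overrides = c(kE1syn = 0, kaNE = 0))
  mr0 <- nfkb_model("revised",
                    overrides = c(kE4syn = 0, kE4drv = 0, kaE4 = 0))
  me <- nfkb_model("e2f1")
  tb <- simulate_nfkb(mb, state0 = eq, protocol = prot, times = times)
  te0 <- simulate_nfkb(me0, state0 = eq, protocol = prot, times = times)
  expect_lt(max(abs(tb$state[, mb$species] - te0$state[, mb$species])),
            1e-8)
  te <- simulate_nfkb(me, state0 = eq, protocol = prot, times = times)
  tr0 <- simulate_nfkb(mr0, state0 = eq, protocol = prot, times = times)
  expect_lt(max(abs(te$state[, me$species] - tr0$state[, me$species])),
            1e-8)
})

test_that("unstimulated base equilibrium is cytoplasmic and a fixed point", {
  eq <- base_equilibrium()
  expect_lt(attr(eq, "residual"), 1e-6)
  expect_lt(nc_ratio(eq), 1)
  eq2 <- equilibrate(nfkb_model("base"), init = eq, horizon = 5000,
                     tol = 1e-6)
  expect_equal(unclass(eq2), unclass(eq)[names(eq2)],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("high constitutive E2F-1 shifts RelA nuclear; IkBa restores it", {
  m_hi <- nfkb_model("e2f1", overrides = c(kE1syn = 20))
  tr <- simulate_nfkb(m_hi, protocol = NULL,
                      times = seq(0, 80000, by = 1000))
  st <- tr$state[nrow(tr$state), ]
  st[st < 0] <- 0
  expect_gt(nc_ratio(st), 1)
  m_resc <- nfkb_model("e2f1", overrides = c(kE1syn = 20, ktI0 = 0.2))
  tr2 <- simulate_nfkb(m_resc, protocol = NULL,
                       times = seq(0, 80000, by = 1000))
  st2 <- tr2$state[nrow(tr2$state), ]
  st2[st2 < 0] <- 0
  expect_lt(nc_ratio(st2), 1)
})

test_that("zero dose preserves the equilibrium; sustained TNF oscillates", {
  eq <- base_equilibrium()
  m <- nfkb_model("base")
  flat <- simulate_nfkb(m, state0 = eq,
                        protocol = stimulus_protocol(0, Inf, 0),
                        times = seq(0, 600, by = 5))
  expect_lt(max(abs(flat$nc_ratio - flat$nc_ratio[1])),
            1e-6 * flat$nc_ratio[1])
  osc <- simulate_nfkb(m, state0 = eq,
                       protocol = stimulus_protocol(0, Inf, 1),
                       times = seq(0, 600, by = 2))
  pk <- detect_peaks(osc$time, osc$nc_ratio / osc$nc_ratio[1],
                     min_prominence = 1, min_separation = 40)
  expect_gte(nrow(pk), 3)
})

test_that("total RelA is conserved along stimulated trajectories", {
  eq <- base_equilibrium()
  for (variant in c("base", "e2f1", "revised")) {
    m <- nfkb_model(variant)
    tr <- simulate_nfkb(m, state0 = eq,
                        protocol = stimulus_protocol(0, Inf, 1),
                        times = seq(0, 1000, by = 10))
    expect_lt(tr$rela_drift, 1e-6)
  }
})

test_that("halving solver tolerances leaves the N:C series unchanged", {
  eq <- base_equilibrium()
  m <- nfkb_model("base")
  prot <- stimulus_protocol(0, Inf, 1)
  t1 <- simulate_nfkb(m, state0 = eq, protocol = prot,
                      times = seq(0, 400, by = 4))
  t2 <- simulate_nfkb(m, state0 = eq, protocol = prot,
                      times = seq(0, 400, by = 4),
                      rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(t1$nc_ratio - t2$nc_ratio)) / max(t1$nc_ratio),
            1e-3)
})

test_that("an isolated first-order decay matches the closed form", {
  k <- 0.01
  ov <- nfkb_default_params()
  ov[] <- 0
  ov["hN"] <- 1; ov["KN"] <- 10; ov["KrepN"] <- 10; ov["KrepE"] <- 5
  ov["kdegI"] <- k
  m <- nfkb_model("base", overrides = ov[names(ov) != "TR"])
  y0 <- setNames(numeric(16), c(
    "IKKn", "IKKa", "IKKi", "NFkB_c", "NFkB_n", "IkBa_c", "IkBa_n",
    "NFkB.IkBa_c", "NFkB.IkBa_n", "tIkBa", "tA20", "A20", "E2F1_n",
    "NFkB.E2F1_n", "E2F4_c", "NFkB.IkBa.E2F4_c"))
  y0["IkBa_c"] <- 5
  tr <- simulate_nfkb(m, state0 = y0, protocol = NULL,
                      times = seq(0, 300, by = 5))
  expect_equal(tr$state[, "IkBa_c"], 5 * exp(-k * tr$time),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("grid validation and trajectory interfaces work", {
  m <- nfkb_model("base")
  expect_error(simulate_nfkb(m, times = c(0, 10, 10)), "increasing")
  tr <- simulate_nfkb(m, protocol = NULL, times = seq(0, 50, 10))
  df <- as.data.frame(tr)
  expect_named(df, c("time_min", "species", "compartment", "value_nM"))
  expect_equal(nrow(df), 6 * length(m$species))
  expect_output(print(tr), "nfkb_trajectory")
})

test_that("nuclear-occupancy half-time increases with E2F-1 half-life", {
  m <- nfkb_model("e2f1")
  hl <- c(60, 240, 960)
  th <- vapply(hl, function(h) coexpression_half_time(m, h),
               numeric(1))
  expect_true(all(diff(th) > 0))
  # a sweep of half-lives is strongly rank-correlated with T_half
  hs <- seq(60, 1200, length.out = 8)
  ts <- vapply(hs, function(h) coexpression_half_time(m, h),
               numeric(1))
  expect_gt(cor(hs, ts, method = "spearman"), 0.9)
})
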