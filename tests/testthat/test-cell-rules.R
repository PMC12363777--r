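# Biological rule engine: Hill growth kinetics, mitosis, differentiation,
# sloughing.

test_that("EGF growth response is a Hill function with half-saturation km", {
  expect_equal(growth_egf(0, 0.3), 0)
  expect_equal(growth_egf(0.3, 0.3), 0.5)
  expect_equal(growth_egf(1e9, 0.3), 1, tolerance = 1e-12)
  expect_error(growth_egf(-0.1, 0.3), "non-negative")
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(growth_egf(x, 0.3)) > 0))     # monotone increasing
})

test_that("density inhibition is the inverted Hill response to pressure", {
  expect_equal(growth_density(0, 8), 1)
  expect_equal(growth_density(8, 8), 0.5)
  expect_equal(growth_density(1e9, 8), 0, tolerance = 1e-12)
  expect_error(growth_density(-1, 8), "non-negative")
  p <- seq(0, 30, by = 0.5)
  expect_true(all(diff(growth_density(p, 8)) < 0))    # monotone decreasing
  # combined rate is bounded by the intrinsic maximum
  g <- 0.3125 * growth_egf(runif(50, 0, 2), 0.3) * growth_density(runif(50, 0, 20), 8)
  expect_true(all(g >= 0 & g <= 0.3125))
})

test_that("growth advances stem/basal targets only, at delta when optimal", {
  cfg <- small_config()
  st <- layered_state(cfg)
  st$egf <- matrix(1e6, nrow(st$owner), ncol(st$owner))   # saturating EGF
  # unconstrained cells (volume == target): density term is 1
  st2 <- apply_growth(st, cfg)
  delta <- cfg$rules$delta_max
  expect_equal(delta, 25 / 80)   # 8-hour minimum doubling interval
  grew <- st2$cells$target_volume - st$cells$target_volume[
    match(st2$cells$id, st$cells$id)]
  comp <- st2$cells$type %in% TY[c("STEM", "BASAL")]
  expect_equal(grew[comp], rep(delta, sum(comp)))
  expect_true(all(grew[!comp] == 0))                 # wing/super/others unchanged
  # zero EGF everywhere: no growth at all
  st$egf[] <- 0
  st3 <- apply_growth(st, cfg)
  expect_equal(st3$cells$target_volume, st$cells$target_volume)
})

test_that("mitosis splits at 50 px into equal daughters; below threshold no-op", {
  cfg <- small_config()
  owner <- matrix(0L, 60, 50)
  owner[11:20, 22:26] <- 7L            # 10x5 stem cell, 50 px
  owner[2:59, 21] <- 2L
  owner[2:59, 1:20] <- 4L
  owner[2:59, 27:30] <- 1L
  types <- c(`1` = TY[["TEAR"]], `2` = TY[["LIMB"]], `4` = TY[["STROMA"]],
             `7` = TY[["STEM"]])
  st <- make_state(owner, types, cfg)
  res <- attempt_mitosis(st, cfg, 7L, seed = 1)
  expect_length(res$daughters, 2)
  dv <- res$state$cells$volume[match(res$daughters, res$state$cells$id)]
  expect_equal(sort(dv), c(25, 25))
  dt <- res$state$cells$type[match(res$daughters, res$state$cells$id)]
  expect_equal(dt, rep(TY[["STEM"]], 2))             # type inherited
  # stem division is centripetal: daughters separate along x
  dx <- res$state$cells$comx[match(res$daughters, res$state$cells$id)]
  dy <- res$state$cells$comy[match(res$daughters, res$state$cells$id)]
  expect_gt(abs(diff(dx)), 4)
  expect_lt(abs(diff(dy)), 1e-9)
  # target volumes reset to actual daughter volumes
  expect_equal(res$state$cells$target_volume[
    match(res$daughters, res$state$cells$id)], as.numeric(dv))
  # 49 px: no division
  owner[20, 26] <- 1L
  st49 <- make_state(owner, types, cfg)
  expect_equal(st49$cells$volume[st49$cells$id == 7L], 49L)
  res49 <- attempt_mitosis(st49, cfg, 7L, seed = 1)
  expect_null(res49$daughters)
})

test_that("random-plane divisions conserve volume to one pixel and keep type", {
  cfg <- small_config()
  set.seed(9)
  worst <- 0
  for (rep in 1:250) {
    # irregular basal cell: random blob of ~50-70 px
    owner <- matrix(0L, 60, 50)
    owner[2:59, 1:20] <- 4L
    owner[2:59, 21] <- 3L
    cx <- sample(15:45, 1)
    for (k in 1:60) {
      x <- cx + sample(-5:5, 1); y <- 22 + sample(0:6, 1)
      owner[x, y] <- 7L
    }
    vol <- sum(owner == 7L)
    if (vol < 50) next
    owner[2:59, 30:33] <- 1L
    st <- make_state(owner, c(`1` = TY[["TEAR"]], `3` = TY[["MEMB"]],
                              `4` = TY[["STROMA"]], `7` = TY[["BASAL"]]), cfg)
    res <- attempt_mitosis(st, cfg, 7L, seed = rep)
    if (is.null(res$daughters)) next
    dv <- res$state$cells$volume[match(res$daughters, res$state$cells$id)]
    expect_equal(sum(dv), vol)
    worst <- max(worst, abs(dv[1] - dv[2]))
    expect_equal(res$state$cells$type[match(res$daughters, res$state$cells$id)],
                 rep(TY[["BASAL"]], 2))
  }
  # cleavage through the COM: daughters within a pixel of half for convex
  # shapes; irregular blobs stay within a few pixels
  expect_lt(worst, 12)
})

test_that("differentiation rules fire exactly on their contact conditions", {
  cfg <- small_config()
  g <- cfg$geometry
  memb <- g$stroma_rows + 1L
  owner <- matrix(0L, 60, 50)
  owner[2:59, 1:g$stroma_rows] <- 4L
  owner[2:20, memb] <- 2L                 # LIMB
  owner[21:59, memb] <- 3L                # MEMB
  # id 10: STEM on LIMB (stays); id 11: STEM off membrane row (becomes BASAL)
  owner[4:9, (memb + 1):(memb + 4)] <- 10L
  owner[4:9, (memb + 5):(memb + 8)] <- 11L
  # id 12: BASAL with 7-px membrane contact (stays)
  owner[30:36, (memb + 1):(memb + 4)] <- 12L
  # id 13: BASAL with exactly 5 contact pixels (becomes WING)
  owner[40:44, (memb + 1):(memb + 4)] <- 13L
  # id 14: WING touching tear and wing 15, no basal/memb/stem (becomes SUPER)
  owner[50:55, (memb + 6):(memb + 8)] <- 14L
  owner[50:55, (memb + 3):(memb + 5)] <- 15L   # WING below, touching MEMB
  owner[2:59, (memb + 9):(memb + 12)] <- 1L    # tear blanket
  types <- c(`1` = TY[["TEAR"]], `2` = TY[["LIMB"]], `3` = TY[["MEMB"]],
             `4` = TY[["STROMA"]], `10` = TY[["STEM"]], `11` = TY[["STEM"]],
             `12` = TY[["BASAL"]], `13` = TY[["BASAL"]], `14` = TY[["WING"]],
             `15` = TY[["WING"]])
  st <- make_state(owner, types, cfg)
  st2 <- differentiate(st, cfg)
  ty <- function(s, id) s$cells$type[s$cells$id == id]
  expect_equal(ty(st2, 10), TY[["STEM"]])      # limbal contact retained
  expect_equal(ty(st2, 11), TY[["BASAL"]])     # lost limbal contact
  expect_equal(ty(st2, 12), TY[["BASAL"]])     # A_EpBM = 7 > 5
  expect_equal(ty(st2, 13), TY[["WING"]])      # A_EpBM = 5 <= 5
  expect_equal(ty(st2, 14), TY[["SUPER"]])     # apical wing
  expect_equal(ty(st2, 15), TY[["WING"]])      # touches MEMB: excluded
})

test_that("type transitions only ever run forward over a whole run", {
  cfg <- small_config()
  sim <- simulate_cornea(cfg, days = 2, seed = 4)
  diffs <- sim$events[sim$events$code == 7, ]
  expect_gt(nrow(diffs), 0)
  # a = from, b = to; forward along STEM -> BASAL -> WING -> SUPER
  expect_true(all(diffs$b == diffs$a + 1))
})

test_that("sloughing is tear-contact gated with geometric 720-MCS lifetimes", {
  # many independent superficial cells in contact with tear bands
  cfg <- cornea_config()  # full lattice for a large cohort
  W <- 200; H <- 90
  owner <- matrix(0L, W, H)
  types <- c(`1` = TY[["TEAR"]])
  nid <- 2L
  for (band in 0:13) {
    y0 <- 2 + band * 6
    for (x0 in seq(2, W - 4, by = 3)) {
      owner[x0:(x0 + 2), y0:(y0 + 2)] <- nid
      types[as.character(nid)] <- TY[["SUPER"]]
      nid <- nid + 1L
    }
    owner[2:(W - 1), (y0 + 3):(y0 + 5)] <- 1L    # tear band above the cells
  }
  # one buried control: a superficial cell fully enclosed by a wing cell
  buried <- nid; wrap <- nid + 1L
  owner[100:104, 86:89] <- wrap
  owner[101:103, 87:88] <- buried
  types[as.character(buried)] <- TY[["SUPER"]]
  types[as.character(wrap)] <- TY[["WING"]]
  st <- make_state(owner, types, cfg)
  lifetimes <- c()
  for (seed in 1:3) {
    res <- corneacpm:::engine_call(st, cfg, n_mcs = 6000, seed = seed,
                                   sample_every = 0,
                                   enable = corneacpm:::enable_flags(slough = TRUE))
    ev <- as.data.frame(res$events)
    sl <- ev[ev$code == 2, ]
    expect_false(buried %in% sl$id)              # never in tear contact
    lifetimes <- c(lifetimes, sl$mcs + 1)
  }
  expect_gt(length(lifetimes), 2000)
  expect_equal(mean(lifetimes), 720, tolerance = 0.05)
})

test_that("without tear EGF the epithelium stops growing and shrinks", {
  cfg <- small_config()
  sim <- simulate_cornea(cfg, days = 3, seed = 8)
  cfg0 <- cfg
  cfg0$egf$clamp_value <- 0       # tear supplies no EGF any more
  st <- sim$state; st$config <- cfg0
  sim0 <- simulate_cornea(cfg0, state = st, days = 2, seed = 9)
  m <- metrics_series(sim0)
  # after the residual field decays (minutes), the count never increases
  post <- m[m$mcs > st$mcs + 20, ]
  expect_true(all(diff(post$n_epithelial) <= 0))
  expect_lt(post$n_epithelial[nrow(post)], m$n_epithelial[1])
})
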