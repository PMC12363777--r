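# Measurement procedures: COM thickness, segment tracking, turnover,
# stability and recovery detection.

fake_cells <- function(type, comx, comy) {
  data.frame(id = seq_along(type), type = type, comx = comx, comy = comy)
}

test_that("COM thickness is the superficial-deep difference in micrometres", {
  cells <- fake_cells(c(TY[["SUPER"]], TY[["SUPER"]], TY[["BASAL"]], TY[["STEM"]]),
                      comx = c(10, 30, 10, 30),
                      comy = c(60, 60, 35, 35))
  expect_equal(thickness_com(cells), 50)
  # missing layer: undefined marker, not an error
  expect_true(is.na(thickness_com(cells[cells$type != TY[["SUPER"]], ])))
  expect_true(is.na(thickness_com(cells[cells$type == TY[["SUPER"]], ])))
})

test_that("thickness on a real state matches a cell-registry recomputation", {
  cfg <- small_config()
  sim <- simulate_cornea(cfg, days = 1.5, seed = 6)
  st <- sim$state
  cells <- st$cells
  sup <- cells$comy[cells$type == TY[["SUPER"]]]
  deep <- cells$comy[cells$type %in% TY[c("BASAL", "STEM")]]
  expect_equal(thickness_com(st), (mean(sup) - mean(deep)) * 2)
})

test_that("segments are the ten 20-voxel x-bands with means in micrometres", {
  # supers in a perfectly flat layer at y = 62 px: every segment reads 124 um
  cells <- fake_cells(rep(TY[["SUPER"]], 100), comx = seq(0.5, 199.5, 2),
                      comy = rep(62, 100))
  expect_equal(segment_surface_positions(cells), rep(124, 10))
  # boundary handling: x = 19.9 falls in segment 1, x = 20.1 in segment 2
  c2 <- fake_cells(rep(TY[["SUPER"]], 2), comx = c(19.9, 20.1), comy = c(50, 70))
  pos <- segment_surface_positions(c2)
  expect_equal(pos[1], 100)
  expect_equal(pos[2], 140)
  expect_true(all(is.na(pos[3:10])))
})

test_that("per-segment thickness subtracts the segment's own deep layer", {
  cells <- rbind(
    fake_cells(rep(TY[["SUPER"]], 10), comx = seq(10, 190, 20), comy = rep(60, 10)),
    fake_cells(rep(TY[["BASAL"]], 10), comx = seq(10, 190, 20), comy = rep(35, 10)))
  expect_equal(segment_thickness(cells), rep(50, 10))
})

test_that("turnover follows the surviving fraction of the baseline cohort", {
  # constructed census: 4 peripheral cells; ids die one per day
  mk <- function(mcs, ids) data.frame(mcs = mcs, id = ids,
                                      type = TY[["WING"]],
                                      comx = 100, comy = 50, volume = 25)
  census <- rbind(mk(0, 1:4), mk(240, 1:3), mk(480, 1:2), mk(720, 2), mk(960, 99))
  tt <- turnover_time(census, "peripheral", baseline_mcs = 0, threshold = 0.05)
  expect_equal(tt$days, 4)            # first time fraction <= 5%
  expect_false(tt$censored)
  expect_true(all(diff(tt$curve$fraction) <= 0))   # never resurrects
  # censored: everything still alive
  census2 <- rbind(mk(0, 1:4), mk(240, 1:4))
  t2 <- turnover_time(census2, "peripheral", baseline_mcs = 0)
  expect_true(t2$censored)
  expect_equal(t2$last_fraction, 1)
})

test_that("survival curves from real runs are monotone non-increasing", {
  cfg <- small_config()
  sim <- simulate_cornea(cfg, days = 3, seed = 13)
  tt <- turnover_time(sim, "limbal", baseline_mcs = 240, limbal_width = 20)
  expect_true(all(diff(tt$curve$fraction) <= 1e-12))
})

test_that("recovery time and recurrences are read off the metrics band", {
  mk <- function(day, n, th) data.frame(mcs = day * 240, day = day,
                                        n_epithelial = n, thickness_um = th)
  # never left the band
  m0 <- do.call(rbind, lapply(0:10, function(d) mk(d, 100, 50)))
  r0 <- recovery_time(m0, injury_mcs = 0, 100, 50)
  expect_equal(r0$days, 0)
  expect_equal(r0$recurrences, 0L)
  # drops, re-enters at day 4, stays
  n <- c(100, 60, 70, 85, 95, 98, 100, 99, 100, 101, 100)
  m1 <- do.call(rbind, lapply(0:10, function(d) mk(d, n[d + 1], 50)))
  r1 <- recovery_time(m1, injury_mcs = 0, 100, 50)
  expect_equal(r1$days, 4)
  expect_equal(r1$recurrences, 0L)
  # recurrent collapse after first recovery (series starts post-injury)
  n2 <- c(60, 95, 100, 60, 55, 95, 100, 58, 96, 100)
  m2 <- do.call(rbind, lapply(1:10, function(d) mk(d, n2[d], 50)))
  r2 <- recovery_time(m2, injury_mcs = 0, 100, 50, sustain_days = 0)
  expect_equal(r2$days, 2)
  expect_equal(r2$recurrences, 2L)
  # never recovered: censored
  m3 <- do.call(rbind, lapply(0:10, function(d) mk(d, 50, 20)))
  expect_true(recovery_time(m3, 0, 100, 50)$censored)
})

test_that("stability detector fires when all four counts settle", {
  mk <- function(day, s, b, w, p) data.frame(mcs = day * 240, day = day,
                                             n_stem = s, n_basal = b,
                                             n_wing = w, n_super = p)
  days <- 0:30
  ramp <- pmin(1, days / 12)     # counts grow until day 12, flat after
  m <- do.call(rbind, lapply(seq_along(days), function(i)
    mk(days[i], 8, round(20 * ramp[i]), round(150 * ramp[i]),
       round(60 * ramp[i]))))
  st <- stability_time(m)
  expect_gte(st, 12)
  expect_lte(st, 15)
  # a series in sustained exponential growth never stabilizes
  m2 <- do.call(rbind, lapply(seq_along(days), function(i)
    mk(days[i], round(8 * 1.2^i), 20, 150, 60)))
  expect_true(is.na(stability_time(m2)))
  # a type that vanishes prevents stability
  m3 <- m; m3$n_stem <- 0
  expect_true(is.na(stability_time(m3)))
})
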