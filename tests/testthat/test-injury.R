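# Injury mechanisms: ablation geometry, chemical deposits,
# concentration-triggered death, depth classification.

test_that("zero-radius ablation removes nothing", {
  cfg <- small_config()
  st <- layered_state(cfg)
  res <- ablate(st, injury_spec("ablation", center = c(30, 30), radius = 0))
  expect_equal(sum(res$report$killed_by_type), 0)
  expect_equal(res$report$classification, "none")
  expect_identical(res$state$owner, st$owner)
})

test_that("ablation removes exactly the epithelial cells with COM in the disc", {
  cfg <- small_config()
  for (seed in 1:5) {
    st <- layered_state(cfg, bw = 5 + seed, ch = 3 + seed %% 2)
    center <- c(20 + 3 * seed, 24 + seed)
    radius <- 6 + seed
    cells <- st$cells
    d2 <- (cells$comx - center[1])^2 + (cells$comy - center[2])^2
    expected <- cells$id[cells$type %in% TY[c("STEM", "BASAL", "WING", "SUPER")] &
                           d2 <= radius^2]
    res <- ablate(st, injury_spec("ablation", center = center, radius = radius))
    expect_equal(sum(res$report$killed_by_type), length(expected))
    expect_false(any(expected %in% res$state$cells$id))
    # removed pixels became tear; frozen compartments untouched
    tear_id <- st$cells$id[st$cells$type == TY[["TEAR"]]][1]
    expect_true(all(res$state$owner[st$owner %in% expected] == tear_id))
    frozen <- st$cells$id[st$cells$type %in% TY[c("LIMB", "MEMB", "STROMA", "WALL")]]
    expect_identical(matrix(res$state$owner %in% frozen, nrow(st$owner)),
                     matrix(st$owner %in% frozen, nrow(st$owner)))
  }
  expect_error(ablate(layered_state(cfg),
                      injury_spec("ablation", center = c(500, 500), radius = 3)),
               "outside")
})

test_that("a shallow ablation disc is classified slight", {
  cfg <- small_config()
  st <- layered_state(cfg)
  # disc centred on the superficial layer, small enough to spare basal cells
  sup_y <- mean(st$cells$comy[st$cells$type == TY[["SUPER"]]])
  res <- ablate(st, injury_spec("ablation", center = c(30, sup_y), radius = 5))
  expect_gt(res$report$killed_by_type[["SUPER"]], 0)
  expect_equal(res$report$killed_by_type[["BASAL"]], 0)
  expect_equal(res$report$classification, "slight")
})

test_that("chemical deposits add the right mass to the toxicant field", {
  cfg <- small_config()
  st <- layered_state(cfg)
  # zero amplitude: no-op
  st0 <- apply_chemical(st, injury_spec("chemical_droplet", center = c(30, 40),
                                        amplitude = 0))
  expect_true(is.null(st0$tox) || all(st0$tox == 0))
  # point deposit: full amplitude lands in the centre pixel
  st1 <- apply_chemical(st, injury_spec("chemical_droplet", center = c(30, 40),
                                        amplitude = 750, sigma = 0))
  expect_equal(st1$tox[31, 41], 750)
  expect_equal(sum(st1$tox), 750)
  # Gaussian droplet: total mass ~ amplitude * 2 pi sigma^2
  st2 <- apply_chemical(st, injury_spec("chemical_droplet", center = c(30, 25),
                                        amplitude = 10, sigma = 3))
  expect_equal(sum(st2$tox), 10 * 2 * pi * 9, tolerance = 0.01)
  # uniform exposure hits every surface tear pixel equally
  st3 <- apply_chemical(st, injury_spec("chemical_uniform", amplitude = 5))
  expect_true(all(st3$tox %in% c(0, 5)))
  expect_gt(sum(st3$tox > 0), nrow(st$owner) / 2)
})

test_that("cells die above the kill threshold; membrane damage is permanent", {
  cfg <- small_config()
  st <- layered_state(cfg)
  st$tox <- matrix(0, nrow(st$owner), ncol(st$owner))
  res0 <- kill_by_concentration(st, cfg)
  expect_equal(sum(res0$report$killed_by_type), 0)

  # dose one superficial cell above threshold, one wing just below
  sup <- st$cells[st$cells$type == TY[["SUPER"]], ][1, ]
  wing <- st$cells[st$cells$type == TY[["WING"]], ][1, ]
  st$tox[st$owner == sup$id] <- 2 * cfg$tox$kill_threshold
  st$tox[st$owner == wing$id] <- 0.5 * cfg$tox$kill_threshold
  res <- kill_by_concentration(st, cfg)
  marked <- res$state$cells[res$state$cells$dying == 1L, ]
  expect_equal(marked$id, sup$id)
  expect_equal(marked$target_volume, 0)
  expect_equal(res$report$classification, "slight")

  # membrane pixels above threshold convert to the damaged state
  st2 <- layered_state(cfg)
  st2$tox <- matrix(0, nrow(st$owner), ncol(st$owner))
  memb_row <- cfg$geometry$stroma_rows + 1L
  st2$tox[30:35, memb_row] <- 2 * cfg$tox$kill_threshold
  res2 <- kill_by_concentration(st2, cfg)
  expect_equal(res2$report$memb_destroyed, 6L)
  expect_equal(res2$report$classification, "moderate")
  dmg_id <- res2$state$cells$id[res2$state$cells$type == TY[["DMG"]]]
  expect_length(dmg_id, 1)
  expect_equal(sum(res2$state$owner == dmg_id), 6)
  # damaged membrane is frozen and never reverts over a subsequent run
  st3 <- res2$state; st3$config <- cfg
  sim <- simulate_cornea(cfg, state = st3, days = 1, seed = 2)
  expect_equal(sum(sim$state$owner == dmg_id), 6)
})

test_that("dying cells shrink away and are removed by the dynamics", {
  cfg <- small_config()
  st <- layered_state(cfg)
  st$tox <- matrix(0, nrow(st$owner), ncol(st$owner))
  victim <- st$cells$id[st$cells$type == TY[["SUPER"]]][2]
  st$tox[st$owner == victim] <- 2 * cfg$tox$kill_threshold
  res <- kill_by_concentration(st, cfg)
  st2 <- res$state; st2$config <- cfg
  sim <- simulate_cornea(cfg, state = st2, days = 0.5, seed = 3)
  expect_false(victim %in% sim$state$cells$id)
})

test_that("higher mean exposure never delays death relative to lower", {
  # two identical superficial cells, one dosed at 3x threshold, one at 1.5x:
  # the higher dose is marked dying no later (both immediately here)
  cfg <- small_config()
  st <- layered_state(cfg)
  sup <- st$cells$id[st$cells$type == TY[["SUPER"]]]
  st$tox <- matrix(0, nrow(st$owner), ncol(st$owner))
  st$tox[st$owner == sup[1]] <- 3 * cfg$tox$kill_threshold
  st$tox[st$owner == sup[2]] <- 1.5 * cfg$tox$kill_threshold
  res <- kill_by_concentration(st, cfg)
  dying <- res$state$cells$id[res$state$cells$dying == 1L]
  expect_true(sup[1] %in% dying)
  expect_true(sup[2] %in% dying)
})
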