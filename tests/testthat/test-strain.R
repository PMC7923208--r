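# posing and strain computation

test_that("strain percent follows the reference-length formula", {
  expect_identical(strain_percent(50, 50), 0)
  expect_equal(strain_percent(44, 40), 10)
  expect_equal(strain_percent(36, 40), -10)
  # scale invariance
  expect_equal(strain_percent(7 * 44, 7 * 40), strain_percent(44, 40))
  expect_error(strain_percent(10, 0), class = "nonpositive_reference_length")
  expect_error(strain_percent(10, -5), class = "nonpositive_reference_length")
})

test_that("posing is the identity at the reference pose and rigid elsewhere", {
  sp <- generate_specimen(generator_params(seed = 6, group = "II"))
  sph <- fit_sphere(sp$humeral_head_cloud)
  fr <- build_frame(sph$center, sp$medial_epicondyle_tip,
                    sp$lateral_epicondyle_tip, sp$side)
  fib <- derive_fibers(sp)

  posed_ref <- pose_insertions(sp, fr, c(90, 0))
  expect_equal(posed_ref, fib$insertions, tolerance = 1e-12)

  pd <- function(m) as.numeric(stats::dist(m))
  for (pose in list(c(0, 0), c(120, 10), c(30, 10), c(60, 0))) {
    posed <- pose_insertions(sp, fr, pose)
    expect_equal(pd(posed), pd(fib$insertions), tolerance = 1e-9)
  }
})

test_that("full extension equals an explicit -90 degree rotation oracle", {
  sp <- exact_test_specimen()
  fr <- build_frame(c(0, 300, 0), sp$medial_epicondyle_tip,
                    sp$lateral_epicondyle_tip, "left")
  fib <- derive_fibers(sp)
  posed <- pose_insertions(sp, fr, c(0, 0))
  R <- oracle_rotmat(c(-1, 0, 0), -90)   # frame z-axis for this layout
  for (i in 1:9)
    expect_equal(unname(posed[i, ]), as.numeric(R %*% fib$insertions[i, ]),
                 tolerance = 1e-9)
})

test_that("study strains match a closed-form rotation-matrix oracle", {
  sp <- exact_test_specimen()
  tab <- run_strain_study(sp)
  fib <- derive_fibers(sp)
  for (vg in c(0, 10)) for (fx in c(0, 30, 60, 90, 120)) {
    R <- oracle_rotmat(c(0, 0, 1), vg) %*% oracle_rotmat(c(-1, 0, 0), fx - 90)
    for (i in 1:9) {
      lt <- dist3(as.numeric(R %*% fib$insertions[i, ]), fib$origins[i, ])
      lst <- dist3(fib$insertions[i, ], fib$origins[i, ])
      got <- tab$strain_pct[tab$fiber == fib$names[i] & tab$flexion_deg == fx &
                              tab$valgus_deg == vg]
      expect_equal(got, (lt - lst) / lst * 100, tolerance = 1e-6)
    }
  }
})

test_that("insertions on the rotation axes never strain", {
  sp <- exact_test_specimen()
  # both rotation axes pass through the frame origin: a fiber inserting
  # there is a fixed point of every pose
  for (nm in grep("insertion|distal", names(sp$attachments), value = TRUE))
    sp$attachments[[nm]] <- c(0, 0, 0) + stats::rnorm(3, sd = 1e-9)
  tab <- suppressWarnings(run_strain_study(sp))
  expect_lt(max(abs(tab$strain_pct)), 1e-4)
})

test_that("strains are invariant under a global rigid transform", {
  set.seed(51)
  sp <- generate_specimen(generator_params(seed = 13, group = "III"))
  base <- run_strain_study(sp)
  for (i in 1:3) {
    f <- random_rigid_transform()
    moved <- apply_transform_to_specimen(sp, f)
    tab <- run_strain_study(moved)
    expect_equal(tab$strain_pct, base$strain_pct, tolerance = 1e-6)
  }
})

test_that("strains are invariant under uniform scaling", {
  sp <- generate_specimen(generator_params(seed = 17, group = "I"))
  base <- run_strain_study(sp)
  scaled <- apply_transform_to_specimen(sp, function(p) p * 2.7)
  expect_equal(run_strain_study(scaled)$strain_pct, base$strain_pct,
               tolerance = 1e-9)
})

test_that("every fiber strain is exactly zero at the reference pose", {
  for (g in c("I", "II", "III")) for (s in c(2L, 19L)) {
    tab <- run_strain_study(generate_specimen(generator_params(seed = s, group = g)))
    ref <- tab$strain_pct[tab$flexion_deg == 90 & tab$valgus_deg == 0]
    expect_identical(ref, rep(0, 9))
  }
})

test_that("grids must contain the reference pose", {
  sp <- generate_specimen(generator_params(seed = 1))
  expect_error(run_strain_study(sp, flexion_grid = c(0, 30)),
               class = "missing_reference_pose")
  expect_error(run_strain_study(sp, valgus_grid = 10),
               class = "missing_reference_pose")
})

test_that("average strain is the unweighted fiber mean per pose", {
  sp <- generate_specimen(generator_params(seed = 5))
  tab <- run_strain_study(sp)
  avg <- average_strain(tab)
  expect_identical(nrow(avg), 10L)
  expect_equal(avg$strain_pct[avg$flexion_deg == 90 & avg$valgus_deg == 0], 0)
  one <- avg$strain_pct[avg$flexion_deg == 30 & avg$valgus_deg == 10]
  expect_equal(one, mean(tab$strain_pct[tab$flexion_deg == 30 &
                                          tab$valgus_deg == 10]))

  # hand-built table: strains 0..8 average to 4
  toy <- tab[tab$flexion_deg == 90 & tab$valgus_deg == 0, ]
  toy$strain_pct <- 0:8
  toy2 <- tab
  toy2[tab$flexion_deg == 90 & tab$valgus_deg == 0, "strain_pct"] <- 0:8
  avg2 <- average_strain(toy2)
  expect_equal(avg2$strain_pct[avg2$flexion_deg == 90 & avg2$valgus_deg == 0], 4)

  expect_error(average_strain(tab[-1, ]), class = "incomplete_table")
})

test_that("rotation order is a configurable second-order effect", {
  sp <- generate_specimen(generator_params(seed = 3, group = "I"))
  a <- run_strain_study(sp, order = "flexion_first")
  b <- run_strain_study(sp, order = "valgus_first")
  expect_identical(a$strain_pct[a$valgus_deg == 0], b$strain_pct[b$valgus_deg == 0])
  expect_false(identical(a$strain_pct, b$strain_pct))
  # at the reference pose both orders are the identity
  expect_identical(a$strain_pct[a$flexion_deg == 90 & a$valgus_deg == 0],
                   b$strain_pct[b$flexion_deg == 90 & b$valgus_deg == 0])
})

test_that("wide tables agree with the long table cell-for-cell after rounding", {
  sp <- generate_specimen(generator_params(seed = 14, group = "II"))
  tab <- run_strain_study(sp)
  for (vg in c(0, 10)) {
    w <- widen_strain_table(tab, vg, decimals = 1)
    expect_identical(w$fiber, c(FIBER_NAMES, "Average"))
    for (fx in c(0, 30, 60, 90, 120)) {
      col <- w[[paste0("flex_", fx)]]
      long <- tab$strain_pct[tab$valgus_deg == vg & tab$flexion_deg == fx]
      expect_equal(col[1:9], round(long, 1))
      expect_equal(col[10], round(mean(long), 1))
    }
  }
})
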