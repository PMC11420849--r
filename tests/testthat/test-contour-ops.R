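# Slice-level vertebra assignment, canal -> stCTV expansion, bsPTV and
# volume computation.

test_that("slice vertebra map uses majority labels and nearest-slice fill", {
  dims <- c(5, 5, 3)
  labels <- array(0L, dims); canal <- array(FALSE, dims); body <- array(TRUE, dims)
  labels[, , 1] <- 10L                        # fully inside T3
  labels[1:3, 1:5, 2] <- 10L                  # 60/40 split T3/T4
  labels[4:5, 1:5, 2] <- 11L
  canal[3, 3, ] <- TRUE
  spine <- labeled_spine(labels, canal, body, c(1, 1, 1))
  zmap <- slice_vertebra_map(spine)
  expect_equal(zmap[1], 10L)
  expect_equal(zmap[2], 10L)                  # majority rule
  expect_equal(zmap[3], 10L)                  # canal-only slice: nearest wins
  # canal-only slice exactly between two blocks: inferior block wins the tie
  labels2 <- array(0L, dims)
  labels2[, , 1] <- 10L; labels2[, , 3] <- 11L
  spine2 <- labeled_spine(labels2, canal, body, c(1, 1, 1))
  expect_equal(slice_vertebra_map(spine2)[2], 10L)
  empty <- labeled_spine(array(0L, dims), canal, body, c(1, 1, 1))
  expect_error(slice_vertebra_map(empty), "no vertebra labels")
})

test_that("canal expansion is per-column interval arithmetic with half-up voxels", {
  dims <- c(7, 60, 2)
  canal <- array(FALSE, dims)
  canal[3:5, 41:50, ] <- TRUE                 # y in [40, 50) mm at 1 mm
  labels <- array(0L, dims); labels[3:5, 41:50, ] <- 10L
  body <- array(TRUE, dims)
  spine <- labeled_spine(labels, canal, body, c(1, 1, 1))
  cv <- structure_volume(canal, c(1, 1, 1))
  m <- margin_model(xd = rep(5, 26), xp = rep(3, 26), provenance = "test")
  st <- expand_canal_to_stctv(cv, spine, m)
  expect_equal(which(st$mask[4, , 1]), 36:53)  # [35, 53) mm half-open
  expect_false(any(st$mask[c(1, 2, 6, 7), , ]))  # untouched columns stay empty
  # tiny margins still round half-up to whole voxels
  m2 <- margin_model(xd = rep(0.5, 26), xp = rep(0.4, 26), provenance = "test")
  st2 <- expand_canal_to_stctv(cv, spine, m2)
  expect_equal(which(st2$mask[4, , 1]), 40:50)   # +1 anterior, +0 posterior
})

test_that("expansion is monotone, contains the canal, and respects the body", {
  ts <- toy_spine(N = 10, shell = 4L, spin = 3L)
  small <- margin_model(xd = rep(2, 26), xp = rep(2, 26), provenance = "test")
  big <- margin_model(xd = rep(6, 26), xp = rep(5, 26), provenance = "test")
  st_small <- expand_canal_to_stctv(ts$canal, ts$spine, small)
  st_big <- expand_canal_to_stctv(ts$canal, ts$spine, big)
  expect_true(all(ts$canal$mask <= st_small$mask))    # stCTV contains canal
  expect_true(all(st_small$mask <= st_big$mask))      # larger margin: superset
  expect_true(all(st_big$mask <= ts$spine$body))      # clipped to the body
  # growth factor < 1 shrinks the expansion column-wise
  st_g <- expand_canal_to_stctv(ts$canal, ts$spine, big, age = 5,
                                use_growth = TRUE)
  expect_true(all(st_g$mask <= st_big$mask))
  expect_error(expand_canal_to_stctv(ts$canal, ts$spine, big,
                                     use_growth = TRUE), "age")
})

test_that("expansion commutes with in-plane translation of the canal", {
  dims <- c(15, 30, 2)
  base <- array(FALSE, dims); base[6:8, 12:16, ] <- TRUE
  shifted <- array(FALSE, dims); shifted[8:10, 15:19, ] <- TRUE
  body <- array(TRUE, dims)
  m <- margin_model(xd = rep(3, 26), xp = rep(2, 26), provenance = "test")
  st_base <- expand_canal_to_stctv(
    structure_volume(base, c(1, 1, 1)),
    labeled_spine(base * 10L, base, body, c(1, 1, 1)), m)
  st_shift <- expand_canal_to_stctv(
    structure_volume(shifted, c(1, 1, 1)),
    labeled_spine(shifted * 10L, shifted, body, c(1, 1, 1)), m)
  expect_equal(st_shift$mask[8:10, 4:28, ], st_base$mask[6:8, 1:25, ])
})

test_that("bsPTV wraps the stCTV with range and lateral margins", {
  ts <- toy_spine(N = 10, shell = 3L, spin = 2L)
  st <- expand_canal_to_stctv(ts$canal, ts$spine,
                              margin_model(xd = rep(3, 26), xp = rep(2, 26),
                                           provenance = "test"))
  depths <- measure_spine_depths(ts$ct, ts$spine, uniform_rsp_table())
  bs <- build_bsptv(st, ts$spine, depths)
  expect_true(all(st$mask <= bs$mask))
  # anterior extension on the midline equals DM converted by the T-spine RSP
  Ld <- depth_distal(depths$d1, depths$x_d_wel)
  nd <- floor(wel_to_thickness(dm(Ld), "T") / 1 + 0.5)
  ys_st <- which(st$mask[11, , 1]); ys_bs <- which(bs$mask[11, , 1])
  expect_equal(min(ys_st) - min(ys_bs), nd)
  # lateral dilation: 7 mm at 1 mm spacing adds 7 columns each side
  expect_equal(min(which(apply(st$mask, 1, any))) -
               min(which(apply(bs$mask, 1, any))), 7)
  expect_error(build_bsptv(st, ts$spine, depths[depths$N != 10, ]),
               "no depth measurements")
})

test_that("degenerate zero-depth input leaves only the 1 mmWEL constant term", {
  expect_equal(dm(depth_distal(0, 0, beamline_constants(couch_wel = 0))), 1)
  expect_equal(wel_to_thickness(1, "T"), 1 / 1.27)
})

test_that("structure volume is voxel count times voxel volume", {
  m <- array(FALSE, c(20, 20, 10)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(structure_volume_ml(structure_volume(m, c(1, 1, 1))), 1)
  expect_equal(structure_volume_ml(structure_volume(array(FALSE, c(4, 4, 4)),
                                                    c(1, 1, 1))), 0)
  expect_equal(structure_volume_ml(structure_volume(m, c(2, 2, 2.5))), 10)
})
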