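# HU->RSP lookup, posterior WEL ray tracing and per-vertebra depth tables.

test_that("HU-RSP lookup interpolates linearly and clamps at the ends", {
  tab <- hu_rsp_table(hu = c(-1000, 0, 1000), rsp = c(0, 1, 1.8))
  expect_equal(hu_to_rsp(c(-1000, 0, 1000), tab), c(0, 1, 1.8))
  expect_equal(hu_to_rsp(-500, tab), 0.5)       # midpoint -> mean RSP
  expect_equal(hu_to_rsp(500, tab), 1.4)
  expect_equal(hu_to_rsp(-2000, tab), 0)        # clamped below
  expect_equal(hu_to_rsp(5000, tab), 1.8)       # clamped above
  expect_error(hu_rsp_table(hu = numeric(0), rsp = numeric(0)), "non-empty")
  expect_error(hu_rsp_table(hu = c(0, 0), rsp = c(1, 1)), "increasing")
})

make_slab_ct <- function(rsp_layers, layer_mm = 10, sy = 1) {
  # posterior slab phantom: layers listed from the skin inward (decreasing y)
  ny <- as.integer(sum(rep(layer_mm, length(rsp_layers))) / sy) + 10L
  hu <- rep(-1000, ny)
  y <- ny - 5L                       # skin at y = (ny-5)*sy
  hu_of_rsp <- function(r) 1000 * (r - 1)   # invert the test table below
  for (r in rsp_layers) {
    n <- as.integer(layer_mm / sy)
    hu[(y - n + 1):y] <- hu_of_rsp(r)
    y <- y - n
  }
  list(ct = ct_volume(array(rep(hu, each = 1), c(1, ny, 1)), c(1, sy, 1)),
       table = hu_rsp_table(hu = c(-1000, 0, 1000), rsp = c(0, 1, 2)),
       skin_y = (ny - 5L) * sy)
}

test_that("WEL tracing reproduces closed-form layered sums", {
  # uniform water: 50 mm geometric depth -> 50 mmWEL
  s <- make_slab_ct(c(1, 1, 1, 1, 1))
  expect_equal(trace_wel_depth(s$ct, c(1, 1), s$skin_y - 50, s$table,
                               surface_hu = -300), 50)
  # uniform RSP 1.27: 10 mm -> 12.7 mmWEL
  s <- make_slab_ct(c(1.27, 1.27))
  expect_equal(trace_wel_depth(s$ct, c(1, 1), s$skin_y - 10, s$table,
                               surface_hu = -300), 12.7)
  # two layers: 10 mm @ 1.0 then 10 mm @ 1.27 -> 22.7 mmWEL
  s <- make_slab_ct(c(1, 1.27))
  expect_equal(trace_wel_depth(s$ct, c(1, 1), s$skin_y - 20, s$table,
                               surface_hu = -300), 22.7)
})

test_that("WEL tracing handles fractional voxels, additivity and monotonicity", {
  s <- make_slab_ct(c(1, 1.27, 0.9))
  skin <- s$skin_y
  tr <- function(y) trace_wel_depth(s$ct, c(1, 1), y, s$table,
                                    surface_hu = -300)
  expect_equal(tr(skin - 10.5), 10 + 0.5 * 1.27)   # half-voxel end
  # additivity: the 15..25 mm segment crosses the 1.27/0.9 layer interface
  expect_equal(tr(skin - 25) - tr(skin - 15), 5 * 1.27 + 5 * 0.9)
  depths <- vapply(seq(0, 28, by = 1.7), function(d) tr(skin - d), numeric(1))
  expect_true(all(diff(depths) >= 0))              # deeper never decreases
  expect_error(tr(skin + 2), "posterior to the body surface")
  air <- ct_volume(array(-1000, c(2, 10, 2)), c(1, 1, 1))
  expect_error(trace_wel_depth(air, c(1, 1), 2, s$table), "misses the body")
})

test_that("per-vertebra depths recover the constructed shell and spinous sizes", {
  ts <- toy_spine(N = 10, shell = 3L, spin = 2L)
  row <- measure_vertebra_depths(ts$ct, ts$spine, 10, uniform_rsp_table())
  expect_equal(row$x_d_wel, 3)      # ventral shell: 3 voxels at 1 mm
  expect_equal(row$x_p_wel, 2)      # spinous process: 2 voxels
  expect_true(row$d1 <= row$d2 && row$d4 <= row$d3)
  expect_equal(row$region, "T")
  # three identical slices: mean equals the single-slice value
  one <- toy_spine(N = 10, shell = 3L, spin = 2L, nz = 1L)
  row1 <- measure_vertebra_depths(one$ct, one$spine, 10, uniform_rsp_table())
  expect_equal(row$d1, row1$d1)
  expect_equal(row$d3, row1$d3)
  expect_error(measure_vertebra_depths(ts$ct, ts$spine, 11), "absent")
})

test_that("a canal flush against the ventral wall gives a sub-voxel margin", {
  ts <- toy_spine(N = 10, shell = 3L, spin = 2L)
  # remove the ventral shell: no vertebra voxel anterior of the canal
  lab <- ts$spine$labels
  lab[, 1:15, ] <- 0L
  spine <- labeled_spine(lab, ts$spine$canal, ts$spine$body, ts$spine$spacing)
  row <- measure_vertebra_depths(ts$ct, spine, 10, uniform_rsp_table())
  expect_lte(row$x_d_wel, ts$ct$spacing[2])
})

test_that("cohort summaries give t-based CIs and degenerate cases are flagged", {
  base <- toy_spine(N = 10, shell = 3L, spin = 2L)
  row <- measure_vertebra_depths(base$ct, base$spine, 10, uniform_rsp_table())
  # identical patients: zero-width CI at the common value
  many <- do.call(rbind, replicate(5, row, simplify = FALSE))
  s <- summarize_cohort(many)
  expect_equal(s$xd_mean, 3)
  expect_equal(s$xd_ci_lo, 3)
  expect_equal(s$xd_ci_hi, 3)
  # single patient: mean defined, CI missing
  s1 <- summarize_cohort(row)
  expect_equal(s1$xd_mean, 3)
  expect_true(is.na(s1$xd_ci_lo))
  # known spread: mean and t CI match direct arithmetic
  spread <- many
  spread$x_d_wel <- c(2.4, 2.9, 3.0, 3.1, 3.8)
  s2 <- summarize_cohort(spread)
  expect_equal(s2$xd_mean, mean(spread$x_d_wel))
  half <- qt(0.975, 4) * sd(spread$x_d_wel) / sqrt(5)
  expect_equal(s2$xd_ci_hi - s2$xd_ci_lo, 2 * half)
})

test_that("packaged fixture round-trips through the cohort summarizer", {
  tab <- load_table3_fixture()
  fake <- data.frame(N = tab$N, x_d_wel = tab$xd_mean, x_p_wel = tab$xp_mean)
  s <- summarize_cohort(fake)
  expect_equal(s$xd_mean, tab$xd_mean)
  expect_equal(s$xp_mean, tab$xp_mean)
})

test_that("measurement CSV writer emits the documented schema", {
  ts <- toy_spine()
  row <- measure_vertebra_depths(ts$ct, ts$spine, 10, uniform_rsp_table())
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_measurements_csv(row, path)
  back <- read.csv(path)
  expect_equal(names(back), c("patient_id", "N", "region", "d1", "d2", "d3",
                              "d4", "x_d_wel", "x_p_wel"))
  expect_equal(back$x_d_wel, 3)
})
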