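# Water-equivalent depth measurement: HU -> relative stopping power
# conversion, posterior parallel-ray WEL integration, and the per-vertebra
# d1..d4 depth table with the derived ventral (x_d) and dorsal (x_p)
# expansions.

#' Piecewise-linear HU to stopping-power calibration
#'
#' Ordered (HU, RSP) breakpoints defining the CT-number to relative
#' stopping-power conversion; lookup interpolates linearly and clamps to the
#' end values outside the calibrated range. The default is a generic
#' calibration shape (air through cortical bone) suitable for the synthetic
#' phantoms; clinical use should supply the scanner's own curve.
#'
#' @param hu Strictly increasing HU breakpoints.
#' @param rsp Non-negative RSP at each breakpoint.
#' @return An object of class `hu_rsp_table`.
#' @export
hu_rsp_table <- function(hu = c(-1000, -100, 0, 40, 200, 700, 1500),
                         rsp = c(0.001, 0.93, 1.00, 1.03, 1.12, 1.42, 1.85)) {
  if (length(hu) == 0L) stop_domain("the HU-RSP table must be non-empty")
  if (length(hu) != length(rsp))
    stop_domain("`hu` and `rsp` must have equal length")
  if (is.unsorted(hu, strictly = TRUE))
    stop_domain("HU breakpoints must be strictly increasing")
  if (any(rsp < 0)) stop_domain("RSP values must be >= 0")
  structure(list(hu = as.numeric(hu), rsp = as.numeric(rsp)),
            class = "hu_rsp_table")
}

#' @rdname hu_rsp_table
#' @param x HU value(s) to convert.
#' @param table A `hu_rsp_table`.
#' @export
hu_to_rsp <- function(x, table = hu_rsp_table()) {
  stopifnot(inherits(table, "hu_rsp_table"))
  if (length(table$hu) == 1L) return(rep(table$rsp, length(x)))
  stats::approx(table$hu, table$rsp, xout = x, rule = 2)$y
}

#' Trace a water-equivalent depth along a posterior ray
#'
#' Integrates relative stopping power along a parallel ray entering the body
#' from the posterior surface (largest y) and travelling anteriorly
#' (decreasing y) down to the physical depth coordinate `stop_y` (mm). The
#' entry point is the posterior face of the most-posterior voxel on the column
#' whose HU exceeds `surface_hu`; partial voxels at either end contribute
#' fractionally.
#'
#' @param ct A [ct_volume()].
#' @param column Integer `c(ix, iz)` voxel column indices.
#' @param stop_y Physical y coordinate (mm) at which to stop, anterior to the
#'   surface.
#' @param table A [hu_rsp_table()].
#' @param surface_hu HU threshold separating body from air (default -300).
#' @return Depth in mmWEL.
#' @export
trace_wel_depth <- function(ct, column, stop_y, table = hu_rsp_table(),
                            surface_hu = -300) {
  stopifnot(inherits(ct, "ct_volume"))
  d <- dim(ct$data)
  ix <- column[1]; iz <- column[2]
  if (ix < 1 || ix > d[1] || iz < 1 || iz > d[3])
    stop_domain("`column` lies outside the volume")
  sy <- ct$spacing[2]
  hu <- ct$data[ix, , iz]
  inside <- which(hu > surface_hu)
  if (length(inside) == 0L)
    stop_domain("ray misses the body: no voxel above the surface threshold")
  i_surf <- max(inside)
  y_entry <- i_surf * sy               # posterior face of the entry voxel
  if (stop_y > y_entry)
    stop_domain("`stop_y` is posterior to the body surface")
  rsp <- hu_to_rsp(hu, table)
  lo <- (seq_len(d[2]) - 1) * sy
  hi <- seq_len(d[2]) * sy
  seg <- pmax(0, pmin(hi, y_entry) - pmax(lo, stop_y))
  sum(seg * rsp)
}

#' Measure per-vertebra WEL depths
#'
#' On the upper, middle and lower axial slices of vertebra `N`, measures on
#' the canal-midline column the WEL depths from the posterior skin surface to:
#' the posterior canal wall (`d3`), the spinous-process tip (`d4`), the
#' anterior canal wall (`d1`) and the anterior vertebral-body wall (`d2`), and
#' averages them over the three slices. The derived expansions are
#' `x_d = d2 - d1` (ventral) and `x_p = d3 - d4` (dorsal), in mmWEL.
#'
#' @param ct A [ct_volume()].
#' @param spine A [labeled_spine()] on the same grid.
#' @param N Vertebral level in 1..26.
#' @param table A [hu_rsp_table()].
#' @param surface_hu HU surface threshold.
#' @param patient_id Identifier copied into the output row.
#' @return One-row data.frame with columns `patient_id`, `N`, `region`,
#'   `d1`..`d4`, `x_d_wel`, `x_p_wel` (mmWEL).
#' @export
measure_vertebra_depths <- function(ct, spine, N, table = hu_rsp_table(),
                                    surface_hu = -300, patient_id = "case") {
  stopifnot(inherits(spine, "labeled_spine"))
  check_same_grid(ct, spine, "CT and spine labels")
  N <- check_vertebra_index(N)
  sy <- ct$spacing[2]
  zs <- which(apply(spine$labels == N, 3, any))
  if (length(zs) == 0L)
    stop_domain("vertebra ", vertebra_label(N), " is absent from the labels")
  # upper/middle/lower = last/middle/first slice of the label extent along z
  # (z grows towards superior); middle ties break towards inferior.
  picks <- unique(zs[c(1L, floor((length(zs) + 1) / 2), length(zs))])

  one_slice <- function(z) {
    canal_cols <- which(apply(spine$canal[, , z, drop = FALSE], 1, any))
    if (length(canal_cols) == 0L) return(NULL)
    x_mid <- round_half_up(mean(canal_cols))
    canal_y <- which(spine$canal[x_mid, , z])
    if (length(canal_y) == 0L) return(NULL)
    vert_y <- which(spine$labels[x_mid, , z] == N)
    ant_canal <- min(canal_y); post_canal <- max(canal_y)
    ant_vert <- vert_y[vert_y < ant_canal]
    post_vert <- vert_y[vert_y > post_canal]
    y_d1 <- (ant_canal - 1) * sy
    y_d2 <- (if (length(ant_vert)) min(ant_vert) - 1 else ant_canal - 1) * sy
    y_d3 <- post_canal * sy
    y_d4 <- (if (length(post_vert)) max(post_vert) else post_canal) * sy
    vapply(c(y_d1, y_d2, y_d3, y_d4), function(y)
      trace_wel_depth(ct, c(x_mid, z), y, table, surface_hu), numeric(1))
  }

  rows <- lapply(picks, one_slice)
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped))
    warning(sprintf("vertebra %s: canal absent on %d of %d slices; skipped",
                    vertebra_label(N), sum(skipped), length(picks)),
            call. = FALSE)
  rows <- rows[!skipped]
  if (length(rows) == 0L)
    stop_domain("vertebra ", vertebra_label(N), ": canal absent on all slices")
  m <- colMeans(do.call(rbind, rows))
  data.frame(patient_id = patient_id, N = N, region = vertebra_region(N),
             d1 = m[1], d2 = m[2], d3 = m[3], d4 = m[4],
             x_d_wel = m[2] - m[1], x_p_wel = m[3] - m[4],
             row.names = NULL)
}

#' @rdname measure_vertebra_depths
#' @description `measure_spine_depths()` runs the measurement for every
#'   vertebral level present in the label map.
#' @export
measure_spine_depths <- function(ct, spine, table = hu_rsp_table(),
                                 surface_hu = -300, patient_id = "case") {
  present <- sort(setdiff(unique(as.vector(spine$labels)), 0L))
  if (length(present) == 0L) stop_domain("no labeled vertebrae in the volume")
  do.call(rbind, lapply(present, function(n)
    measure_vertebra_depths(ct, spine, n, table, surface_hu, patient_id)))
}

#' Summarize a measurement cohort per vertebra
#'
#' Per vertebral level: mean and two-sided 95% t-based confidence interval of
#' the ventral and dorsal expansions across patients, in mmWEL. With a single
#' patient the CI is undefined and reported as `NA`.
#'
#' @param measurements A data.frame of measurement rows as produced by
#'   [measure_spine_depths()] (requires columns `N`, `x_d_wel`, `x_p_wel`).
#' @return A data.frame with one row per level: `N`, `region`, `n`,
#'   `xd_mean`, `xd_ci_lo`, `xd_ci_hi`, `xp_mean`, `xp_ci_lo`, `xp_ci_hi`.
#' @export
summarize_cohort <- function(measurements) {
  req <- c("N", "x_d_wel", "x_p_wel")
  if (!all(req %in% names(measurements)))
    stop_domain("`measurements` must contain columns ",
                paste(req, collapse = ", "))
  ci <- function(v) {
    n <- length(v); m <- mean(v)
    if (n < 2L) return(c(m, NA_real_, NA_real_))
    half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
    c(m, m - half, m + half)
  }
  levels_present <- sort(unique(measurements$N))
  do.call(rbind, lapply(levels_present, function(n) {
    sub <- measurements[measurements$N == n, ]
    d <- ci(sub$x_d_wel); p <- ci(sub$x_p_wel)
    data.frame(N = n, region = vertebra_region(n), n = nrow(sub),
               xd_mean = d[1], xd_ci_lo = d[2], xd_ci_hi = d[3],
               xp_mean = p[1], xp_ci_lo = p[2], xp_ci_hi = p[3],
               row.names = NULL)
  }))
}

#' Write a measurement table as CSV
#'
#' Fixed column order, '.' decimal separator, values rounded to 3 decimals.
#'
#' @param measurements Measurement data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  cols <- c("patient_id", "N", "region", "d1", "d2", "d3", "d4",
            "x_d_wel", "x_p_wel")
  out <- measurements[, cols]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "N"
  out[num] <- lapply(out[num], round, 3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
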