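# Contour agreement metrics: Dice, Jaccard, slice-averaged symmetric
# Hausdorff distance and mean distance-to-agreement, plus the
# region-stratified evaluation report.

#' Volumetric overlap coefficients
#'
#' `dice()` returns 2|A&B| / (|A| + |B|) and `jaccard()` |A&B| / |A|B|, both
#' over the full 3-D masks. When both masks are empty the coefficient is
#' undefined and `NA` is returned with a warning.
#'
#' @param A,B [structure_volume()] masks on the same grid.
#' @return Unitless coefficient in 0..1, or `NA`.
#' @export
dice <- function(A, B) {
  check_same_grid(A, B, "masks")
  na <- sum(A$mask); nb <- sum(B$mask)
  if (na + nb == 0L) {
    warning("both masks empty: Dice undefined", call. = FALSE)
    return(NA_real_)
  }
  2 * sum(A$mask & B$mask) / (na + nb)
}

#' @rdname dice
#' @export
jaccard <- function(A, B) {
  check_same_grid(A, B, "masks")
  u <- sum(A$mask | B$mask)
  if (u == 0L) {
    warning("both masks empty: Jaccard undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(A$mask & B$mask) / u
}

# In-plane boundary: mask voxels with at least one 4-neighborhood background
# neighbor (out-of-grid counts as background).
boundary_2d <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  interior <- matrix(FALSE, nx, ny)
  if (nx > 2 && ny > 2)
    interior[2:(nx - 1), 2:(ny - 1)] <-
      m[1:(nx - 2), 2:(ny - 1)] & m[3:nx, 2:(ny - 1)] &
      m[2:(nx - 1), 1:(ny - 2)] & m[2:(nx - 1), 3:ny]
  m & !interior
}

# Directed min distances between boundary point sets of two slice masks, in
# physical mm. Returns list(a = per-A-point mins, b = per-B-point mins).
slice_boundary_mins <- function(a2d, b2d, spacing_xy) {
  pa <- which(boundary_2d(a2d), arr.ind = TRUE)
  pb <- which(boundary_2d(b2d), arr.ind = TRUE)
  ax <- pa[, 1] * spacing_xy[1]; ay <- pa[, 2] * spacing_xy[2]
  bx <- pb[, 1] * spacing_xy[1]; by <- pb[, 2] * spacing_xy[2]
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  list(a = sqrt(apply(d2, 1, min)), b = sqrt(apply(d2, 2, min)))
}

# Shared slice loop for the two boundary-distance metrics.
slice_distance_metric <- function(A, B, per_slice) {
  check_same_grid(A, B, "masks")
  nz <- dim(A$mask)[3]
  vals <- numeric(0)
  for (z in seq_len(nz)) {
    a <- A$mask[, , z]; b <- B$mask[, , z]
    if (!any(a) || !any(b)) next     # slices missing either contour excluded
    mins <- slice_boundary_mins(a, b, A$spacing[1:2])
    vals <- c(vals, per_slice(mins))
  }
  if (length(vals) == 0L) {
    warning("no slice where both masks are non-empty: metric undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(vals)
}

#' Slice-averaged symmetric Hausdorff distance
#'
#' On each axial slice where both masks are non-empty, the symmetric Hausdorff
#' distance between the two in-plane contours (the larger of the two directed
#' maximum minimum boundary distances, in physical mm); the reported value is
#' the mean over those slices. Slices where either contour is absent are
#' excluded from the average.
#'
#' @param A,B [structure_volume()] masks on the same grid.
#' @return Distance in mm, or `NA` when no slice has both contours.
#' @export
slice_hausdorff <- function(A, B) {
  slice_distance_metric(A, B, function(mins) max(max(mins$a), max(mins$b)))
}

#' Slice-averaged mean distance-to-agreement
#'
#' On each common slice, the mean over boundary points of one contour of the
#' distance to the other contour's boundary, symmetrized by averaging the two
#' directions, then averaged over slices.
#'
#' @param A,B [structure_volume()] masks on the same grid.
#' @return Distance in mm, or `NA` when no slice has both contours.
#' @export
mean_distance_to_agreement <- function(A, B) {
  slice_distance_metric(A, B, function(mins)
    (mean(mins$a) + mean(mins$b)) / 2)
}

crop_slices <- function(v, zs) {
  structure_volume(v$mask[, , zs, drop = FALSE], v$spacing, v$origin)
}

#' Region-stratified agreement report
#'
#' Computes all four agreement metrics plus both structure volumes for the
#' whole spine and for the C- (reported both with and without C1), T-, L- and
#' S-spine slice ranges, taken from the vertebra labels.
#'
#' @param A,B [structure_volume()] masks on the same grid (e.g. stCTV and the
#'   clinical reference tCTV).
#' @param spine A [labeled_spine()] providing the per-slice level assignment.
#' @return A data.frame with one row per region: `region`, `n_slices`,
#'   `dH_mm`, `MDA_mm`, `DSC`, `J`, `volume_A_ml`, `volume_B_ml`. Regions with
#'   no slices are reported as `NA`.
#' @export
evaluate_regions <- function(A, B, spine) {
  check_same_grid(A, B, "masks")
  check_same_grid(A, spine, "masks and spine labels")
  zmap <- slice_vertebra_map(spine)
  regions <- list("whole spine" = 1:26, "C-spine (C1-C7)" = 1:7,
                  "C-spine (C2-C7)" = 2:7, "T-spine" = 8:19,
                  "L-spine" = 20:24, "S-spine" = 25:26)
  rows <- lapply(names(regions), function(nm) {
    zs <- which(zmap %in% regions[[nm]])
    if (length(zs) == 0L)
      return(data.frame(region = nm, n_slices = 0L, dH_mm = NA_real_,
                        MDA_mm = NA_real_, DSC = NA_real_, J = NA_real_,
                        volume_A_ml = NA_real_, volume_B_ml = NA_real_))
    a <- crop_slices(A, zs); b <- crop_slices(B, zs)
    data.frame(region = nm, n_slices = length(zs),
               dH_mm = slice_hausdorff(a, b),
               MDA_mm = mean_distance_to_agreement(a, b),
               DSC = dice(a, b), J = jaccard(a, b),
               volume_A_ml = structure_volume_ml(a),
               volume_B_ml = structure_volume_ml(b),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write a region report as CSV
#'
#' @param report Data.frame from [evaluate_regions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_report_csv <- function(report, path) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
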