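# Anisotropic structure expansion: spinal canal -> stCTV (per-vertebra
# ventral/dorsal margins) and stCTV -> bsPTV (beam range margins plus lateral
# setup margin).

#' Assign a vertebral level to each axial slice
#'
#' Each axial slice gets the majority vertebra label on that slice (ties break
#' towards the inferior, i.e. smaller, level). Slices containing canal but no
#' vertebra label inherit the nearest labeled slice's level, with inferior
#' slices winning distance ties.
#'
#' @param spine A [labeled_spine()].
#' @return Integer vector over axial slices: the level N, or `NA` for slices
#'   with neither label nor canal.
#' @export
slice_vertebra_map <- function(spine) {
  stopifnot(inherits(spine, "labeled_spine"))
  nz <- dim(spine$labels)[3]
  out <- rep(NA_integer_, nz)
  for (z in seq_len(nz)) {
    lab <- spine$labels[, , z]
    lab <- lab[lab > 0L]
    if (length(lab)) {
      tab <- table(lab)
      out[z] <- as.integer(names(tab)[which.max(tab)])  # ties: smallest N
    }
  }
  if (all(is.na(out))) stop_domain("no vertebra labels anywhere in the volume")
  canal_z <- which(apply(spine$canal, 3, any))
  labeled <- which(!is.na(out))
  for (z in setdiff(canal_z, labeled)) {
    dist <- abs(labeled - z)
    nearest <- labeled[dist == min(dist)]
    out[z] <- out[min(nearest)]        # distance ties: inferior slice wins
  }
  out
}

# Extend the occupied y-interval of every canal-containing column on one
# axial slice by nd voxels anteriorly and np voxels posteriorly; returns the
# slice mask.
extend_slice_columns <- function(slice_mask, nd, np) {
  ny <- ncol(slice_mask)
  out <- slice_mask
  for (ix in which(rowSums(slice_mask) > 0)) {
    ys <- which(slice_mask[ix, ])
    out[ix, max(1L, min(ys) - nd):min(ny, max(ys) + np)] <- TRUE
  }
  out
}

#' Expand the spinal canal into a simulated technical CTV
#'
#' On every axial slice, each canal-containing column's occupied
#' anterior-posterior interval is extended anteriorly by the level's ventral
#' margin `X_d(N)` and posteriorly by its dorsal margin `X_p(N)` (optionally
#' scaled by the growth factor), converted to voxels by half-up rounding of
#' margin / y-spacing. The result is clipped to the body mask and unioned
#' with the original canal.
#'
#' @param canal A [structure_volume()] of the spinal canal.
#' @param spine A [labeled_spine()] on the same grid.
#' @param model A [margin_model()].
#' @param age Patient age in years (required when `use_growth = TRUE`).
#' @param use_growth Apply the growth factor f(age) to both margins?
#' @param growth A [growth_model()].
#' @return A [structure_volume()]: the stCTV.
#' @export
expand_canal_to_stctv <- function(canal, spine, model = margin_model(),
                                  age = NULL, use_growth = FALSE,
                                  growth = growth_model()) {
  stopifnot(inherits(canal, "structure_volume"), inherits(model, "margin_model"))
  check_same_grid(canal, spine, "canal and spine labels")
  if (!any(canal$mask)) stop_domain("the canal mask is empty")
  if (use_growth && is.null(age))
    stop_domain("`age` is required when `use_growth = TRUE`")
  f <- if (use_growth) growth_factor(age, growth) else 1
  sy <- canal$spacing[2]
  zmap <- slice_vertebra_map(spine)
  out <- canal$mask
  for (z in which(apply(canal$mask, 3, any))) {
    N <- zmap[z]
    if (is.na(N)) stop_domain("no vertebral level assignable to slice ", z)
    nd <- round_half_up(xd_margin(N, model) * f / sy)
    np <- round_half_up(xp_margin(N, model) * f / sy)
    out[, , z] <- extend_slice_columns(canal$mask[, , z], nd, np)
  }
  out <- out & spine$body          # margins never exit the patient
  out <- out | canal$mask
  structure_volume(out, canal$spacing, canal$origin)
}

# In-plane dilation along x by `nl` voxels (shift-union).
dilate_x <- function(mask3d, nl) {
  if (nl <= 0) return(mask3d)
  nx <- dim(mask3d)[1]
  out <- mask3d
  for (k in seq_len(nl)) {
    out[1:(nx - k), , ] <- out[1:(nx - k), , ] | mask3d[(k + 1):nx, , ]
    out[(k + 1):nx, , ] <- out[(k + 1):nx, , ] | mask3d[1:(nx - k), , ]
  }
  out
}

#' Build the beam-specific PTV from the stCTV
#'
#' Per vertebral level, the distal depth `L_d = d1 + x_d + devices` and
#' proximal depth `L_p = d3 - x_p + devices` (mmWEL) give the range margins
#' `DM = 0.035 L_d + 1` and `PM = 0.035 L_p + 1`. The stCTV is extended
#' anteriorly by DM and posteriorly by PM (each converted to real thickness
#' with the region stopping power), then dilated laterally (x) by
#' `lateral_mm`, and clipped to the volume bounds.
#'
#' @param stctv A [structure_volume()].
#' @param spine A [labeled_spine()] on the same grid.
#' @param depths Measurement data.frame with columns `N`, `d1`, `d3`,
#'   `x_d_wel`, `x_p_wel` covering every level present.
#' @param bl A [beamline_constants()].
#' @param spmap A [stopping_power_map()].
#' @param lateral_mm Lateral setup margin in mm (default 7.0).
#' @return A [structure_volume()]: the bsPTV.
#' @export
build_bsptv <- function(stctv, spine, depths, bl = beamline_constants(),
                        spmap = stopping_power_map(), lateral_mm = 7.0) {
  stopifnot(inherits(stctv, "structure_volume"))
  check_same_grid(stctv, spine, "stCTV and spine labels")
  if (!any(stctv$mask)) stop_domain("the stCTV mask is empty")
  sy <- stctv$spacing[2]; sx <- stctv$spacing[1]
  zmap <- slice_vertebra_map(spine)
  zs <- which(apply(stctv$mask, 3, any))
  need <- unique(zmap[zs])
  missing <- setdiff(need, depths$N)
  if (length(missing))
    stop_domain("no depth measurements for level(s): ",
                paste(missing, collapse = ", "))
  out <- stctv$mask
  for (z in zs) {
    N <- zmap[z]
    row <- depths[match(N, depths$N), ]
    reg <- vertebra_region(N)
    DM <- dm(depth_distal(row$d1, row$x_d_wel, bl))
    PM <- pm(depth_proximal(row$d3, row$x_p_wel, bl))
    nd <- round_half_up(wel_to_thickness(DM, reg, spmap) / sy)
    np <- round_half_up(wel_to_thickness(PM, reg, spmap) / sy)
    out[, , z] <- extend_slice_columns(stctv$mask[, , z], nd, np)
  }
  out <- dilate_x(out, round_half_up(lateral_mm / sx))
  out <- out | stctv$mask
  structure_volume(out, stctv$spacing, stctv$origin)
}
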