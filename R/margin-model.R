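# Closed-form margin formulas: vertebral indexing, beamline constants,
# stopping-power conversion, body-surface area, the age growth factor, the
# per-vertebra ventral/dorsal margin model and the beam range margins.

# Per-vertebra cohort mean expansions in mmWEL for the levels kept outside the
# fitted lines: C1 (atlas, excluded from the cervical fit because the skull
# sits in the beam path) and the two sacral levels (too few measurements to
# support a fitted relationship).
.CONST_WEL <- list(
  xd = c(`1` = 15.1, `25` = 26.2, `26` = 16.8),
  xp = c(`1` = 3.9, `25` = 3.4, `26` = 3.0)
)

#' Vertebral level indexing
#'
#' Vertebrae are indexed by a single integer level `N`: 1--7 are C1--C7,
#' 8--19 are T1--T12, 20--24 are L1--L5 and 25--26 are S1--S2.
#'
#' @param N Integer vertebral level(s) in 1..26.
#' @return `vertebra_region()` returns the spine region code (`"C"`, `"T"`,
#'   `"L"` or `"S"`) for each level; `vertebra_label()` the anatomical name
#'   (e.g. `"T3"`).
#' @examples
#' vertebra_region(c(1, 8, 20, 26))
#' vertebra_label(10)
#' @export
vertebra_region <- function(N) {
  check_vertebra_index(N)
  regions <- c(rep("C", 7), rep("T", 12), rep("L", 5), rep("S", 2))
  regions[N]
}

#' @rdname vertebra_region
#' @export
vertebra_label <- function(N) {
  check_vertebra_index(N)
  labels <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5),
              paste0("S", 1:2))
  labels[N]
}

check_vertebra_index <- function(N) {
  if (!is.numeric(N) || length(N) < 1L || anyNA(N) ||
      any(N != as.integer(N)) || any(N < 1L) || any(N > 26L))
    stop_domain("vertebral level `N` must be integer(s) in 1..26")
  invisible(as.integer(N))
}

#' Beamline water-equivalent constants
#'
#' Water-equivalent lengths of hardware in the posterior beam path: the
#' treatment couch and (when present) a nozzle-mounted and a couch-mounted
#' range shifter. Only devices flagged present contribute to the distal and
#' proximal depths.
#'
#' @param couch_wel Couch WEL in mm (default 7.8).
#' @param nozzle_rs_wel Nozzle-mounted range-shifter WEL in mm (default 5).
#' @param couch_rs_wel Couch-mounted range-shifter WEL in mm (default 32).
#' @param has_nozzle_rs,has_couch_rs Logical flags: is the shifter in the beam?
#' @return An object of class `beamline_constants`.
#' @examples
#' beamline_constants()                       # couch only
#' beamline_constants(has_couch_rs = TRUE)    # couch + couch-mounted shifter
#' @export
beamline_constants <- function(couch_wel = 7.8, nozzle_rs_wel = 5,
                               couch_rs_wel = 32, has_nozzle_rs = FALSE,
                               has_couch_rs = FALSE) {
  for (v in c(couch_wel, nozzle_rs_wel, couch_rs_wel))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop_domain("beamline WEL constants must be single non-negative numbers")
  structure(list(couch_wel = couch_wel, nozzle_rs_wel = nozzle_rs_wel,
                 couch_rs_wel = couch_rs_wel,
                 has_nozzle_rs = isTRUE(has_nozzle_rs),
                 has_couch_rs = isTRUE(has_couch_rs)),
            class = "beamline_constants")
}

# Total WEL of present devices.
device_wel <- function(bl) {
  stopifnot(inherits(bl, "beamline_constants"))
  bl$couch_wel +
    (if (bl$has_nozzle_rs) bl$nozzle_rs_wel else 0) +
    (if (bl$has_couch_rs) bl$couch_rs_wel else 0)
}

#' Region relative stopping power map
#'
#' Relative proton stopping power (RSP) used to convert water-equivalent
#' lengths into real tissue thicknesses, one constant per spine region.
#' Defaults: 1.34 for the cervical spine, 1.27 for the thoracic, lumbar and
#' sacral spine.
#'
#' @param C,T,L,S Positive RSP constants per region.
#' @return An object of class `stopping_power_map`.
#' @export
stopping_power_map <- function(C = 1.34, T = 1.27, L = 1.27, S = 1.27) {
  vals <- c(C = C, T = T, L = L, S = S)
  if (!is.numeric(vals) || any(vals <= 0))
    stop_domain("stopping powers must all be > 0")
  structure(as.list(vals), class = "stopping_power_map")
}

region_rsp <- function(region, spmap = stopping_power_map()) {
  stopifnot(inherits(spmap, "stopping_power_map"))
  if (!all(region %in% c("C", "T", "L", "S")))
    stop_domain("unknown spine region: ",
                paste(setdiff(region, c("C", "T", "L", "S")), collapse = ", "))
  unlist(spmap[region], use.names = FALSE)
}

#' Convert between water-equivalent length and real thickness
#'
#' WEL divided by the region stopping power gives the geometric thickness;
#' `thickness_to_wel()` is the exact inverse.
#'
#' @param wel,thickness Non-negative lengths (mmWEL / mm).
#' @param region Spine region code(s) `"C"`, `"T"`, `"L"` or `"S"`.
#' @param spmap A [stopping_power_map()].
#' @return Length in mm (or mmWEL for the inverse).
#' @examples
#' wel_to_thickness(13.4, "C")   # 10 mm
#' thickness_to_wel(10, "C")     # 13.4 mmWEL
#' @export
wel_to_thickness <- function(wel, region, spmap = stopping_power_map()) {
  if (any(wel < 0)) stop_domain("`wel` must be >= 0")
  wel / region_rsp(region, spmap)
}

#' @rdname wel_to_thickness
#' @export
thickness_to_wel <- function(thickness, region, spmap = stopping_power_map()) {
  if (any(thickness < 0)) stop_domain("`thickness` must be >= 0")
  thickness * region_rsp(region, spmap)
}

#' Du Bois body surface area
#'
#' BSA = W^0.425 x H^0.725 x 0.007184, with weight in kg and height in cm.
#'
#' @param weight Body weight in kg (> 0).
#' @param height Body height in cm (> 0).
#' @return BSA in m^2.
#' @examples
#' bsa(21.9, 130.4)
#' @export
bsa <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop_domain("`weight` and `height` must be > 0")
  weight^0.425 * height^0.725 * 0.007184
}

#' Age growth factor
#'
#' Linear scaling of margins with patient age, derived from the regression of
#' body surface area on age in a pediatric cohort: f(g) = slope x g +
#' intercept with defaults 0.052/yr and 0.51.
#'
#' @param age Patient age in years (>= 0). A warning is emitted outside the
#'   supported 3--15 year range.
#' @param model A [growth_model()].
#' @return Unitless scaling factor f(age).
#' @examples
#' growth_factor(9)   # 0.978
#' @export
growth_factor <- function(age, model = growth_model()) {
  stopifnot(inherits(model, "growth_model"))
  if (any(age < 0)) stop_domain("`age` must be >= 0")
  if (any(age < 3 | age > 15))
    warning("growth factor applied outside the supported age range 3-15 years",
            call. = FALSE)
  model$slope * age + model$intercept
}

#' @rdname growth_factor
#' @param slope Slope in 1/year.
#' @param intercept Unitless intercept.
#' @export
growth_model <- function(slope = 0.052, intercept = 0.51) {
  check_scalar_number(slope, "slope")
  check_scalar_number(intercept, "intercept")
  m <- structure(list(slope = slope, intercept = intercept),
                 class = "growth_model")
  if (any(m$slope * c(3, 15) + m$intercept <= 0))
    stop_domain("growth factor must stay positive over ages 3-15")
  m
}

#' Per-vertebra ventral/dorsal margin model
#'
#' Piecewise model of the real-thickness expansion of the spinal canal at each
#' vertebral level `N`: a ventral (anterior, distal along a posterior beam)
#' margin `X_d(N)` towards the vertebral limbus, and a dorsal (posterior,
#' proximal) margin `X_p(N)` towards the spinous process tip.
#'
#' The published default is: `X_d` constant 8.2 mm over C2--C7 and
#' `0.6 N + 5.2` mm over T1--L5; `X_p` is `1.3 N + 1.2` mm over C2--C7 and
#' `-0.2 N + 12.6` mm over T1--L5. C1 and the sacral levels fall outside the
#' fitted model and use the cohort mean expansions converted from mmWEL by the
#' region stopping power.
#'
#' @param xd,xp Optional numeric vectors of length 26 (mm) to build a custom
#'   model; both must be supplied together.
#' @param provenance Provenance tag, `"published-default"` or `"refitted"`.
#' @param spmap [stopping_power_map()] used to convert the C1/S1/S2 cohort
#'   means from mmWEL.
#' @return An object of class `margin_model` with `xd` and `xp` vectors (mm,
#'   indexed by `N` = 1..26) and a provenance tag.
#' @examples
#' m <- margin_model()
#' xd_margin(8, m)    # 10.0 mm
#' xp_margin(2, m)    # 3.8 mm
#' @export
margin_model <- function(xd = NULL, xp = NULL,
                         provenance = if (is.null(xd)) "published-default"
                                      else "custom",
                         spmap = stopping_power_map()) {
  if (is.null(xd) != is.null(xp))
    stop_domain("supply both `xd` and `xp`, or neither")
  if (is.null(xd)) {
    N <- 1:26
    xd <- xp <- numeric(26)
    xd[2:7] <- 8.2
    xd[8:24] <- 0.6 * N[8:24] + 5.2
    xp[2:7] <- 1.3 * N[2:7] + 1.2
    xp[8:24] <- -0.2 * N[8:24] + 12.6
    for (n in c(1L, 25L, 26L)) {
      reg <- vertebra_region(n)
      xd[n] <- wel_to_thickness(.CONST_WEL$xd[[as.character(n)]], reg, spmap)
      xp[n] <- wel_to_thickness(.CONST_WEL$xp[[as.character(n)]], reg, spmap)
    }
  }
  if (length(xd) != 26L || length(xp) != 26L)
    stop_domain("margin vectors must have length 26 (N = 1..26)")
  if (any(!is.finite(xd)) || any(!is.finite(xp)) || any(xd <= 0) || any(xp <= 0))
    stop_domain("all margins must be finite and > 0")
  structure(list(xd = as.numeric(xd), xp = as.numeric(xp),
                 provenance = provenance),
            class = "margin_model")
}

#' @rdname margin_model
#' @param N Vertebral level(s) in 1..26.
#' @param model A `margin_model`.
#' @export
xd_margin <- function(N, model = margin_model()) {
  stopifnot(inherits(model, "margin_model"))
  model$xd[check_vertebra_index(N)]
}

#' @rdname margin_model
#' @export
xp_margin <- function(N, model = margin_model()) {
  stopifnot(inherits(model, "margin_model"))
  model$xp[check_vertebra_index(N)]
}

#' Apply the growth factor to a real-thickness margin
#'
#' Scales a margin in mm by the growth factor f(age). The scaling acts on real
#' thicknesses, never on water-equivalent quantities.
#'
#' @param margin Margin in mm (> 0).
#' @param age Patient age in years.
#' @param model A [growth_model()].
#' @return Scaled margin in mm.
#' @export
apply_growth <- function(margin, age, model = growth_model()) {
  if (any(margin <= 0)) stop_domain("`margin` must be > 0")
  margin * growth_factor(age, model)
}

#' Distal and proximal beam depths
#'
#' Water-equivalent depth of the distal edge (`L_d`, skin-to-anterior-canal
#' depth `d1` plus the ventral margin) and of the proximal edge (`L_p`,
#' skin-to-posterior-canal depth `d3` minus the dorsal margin), each plus the
#' water-equivalent lengths of the couch and any present range shifters.
#'
#' @param d1,d3 Measured WEL depths from the posterior skin surface (mmWEL).
#' @param xd_wel,xp_wel Ventral/dorsal margins in mmWEL.
#' @param bl A [beamline_constants()].
#' @return Depth in mmWEL.
#' @examples
#' depth_distal(50, 10, beamline_constants())   # 67.8
#' @export
depth_distal <- function(d1, xd_wel, bl = beamline_constants()) {
  if (any(d1 < 0) || any(xd_wel < 0)) stop_domain("depths and margins must be >= 0")
  d1 + xd_wel + device_wel(bl)
}

#' @rdname depth_distal
#' @export
depth_proximal <- function(d3, xp_wel, bl = beamline_constants()) {
  if (any(d3 < 0) || any(xp_wel < 0)) stop_domain("depths and margins must be >= 0")
  if (any(d3 < xp_wel))
    stop_domain("dorsal margin exceeds the posterior canal depth (d3 < x_p)")
  d3 - xp_wel + device_wel(bl)
}

#' Beam range margins
#'
#' Distal margin `DM` and proximal margin `PM` compensating proton range
#' uncertainty: 3.5% of the water-equivalent depth plus 1 mmWEL.
#'
#' @param L_d,L_p Water-equivalent depth of the distal/proximal edge (mmWEL).
#' @return Margin in mmWEL.
#' @examples
#' dm(100)   # 4.5
#' pm(200)   # 8.0
#' @export
dm <- function(L_d) {
  if (any(L_d < 0)) stop_domain("`L_d` must be >= 0")
  0.035 * L_d + 1
}

#' @rdname dm
#' @export
pm <- function(L_p) {
  if (any(L_p < 0)) stop_domain("`L_p` must be >= 0")
  0.035 * L_p + 1
}

#' @export
print.margin_model <- function(x, ...) {
  cat("Per-vertebra margin model (", x$provenance, ")\n", sep = "")
  cat(sprintf("  X_d: C2-C7 %.1f mm; T/L range %.1f-%.1f mm\n",
              x$xd[2], min(x$xd[8:24]), max(x$xd[8:24])))
  cat(sprintf("  X_p: C2-C7 range %.1f-%.1f mm; T/L range %.1f-%.1f mm\n",
              min(x$xp[2:7]), max(x$xp[2:7]), min(x$xp[8:24]), max(x$xp[8:24])))
  invisible(x)
}
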