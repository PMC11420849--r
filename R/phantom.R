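# Synthetic pediatric spine phantom: a posterior-beam CT geometry with a
# low-density spinal canal inside a high-density vertebral body carrying a
# dorsal spinous process, age-scaled dimensions, ground-truth construction
# margins, and a jittered "physician" reference contour. Also loads the
# packaged cohort fixtures.

#' Phantom specification
#'
#' Parameters of the synthetic spine phantom. All in-plane dimensions scale
#' with age through the same affine growth factor used for margins,
#' normalized to 1 at the cohort median age of 9 years. Ground-truth
#' ventral/dorsal expansions per level are taken from `model` (scaled), so
#' phantom construction and margin model share one geometry.
#'
#' @param age Patient age in years (default 9, the cohort median).
#' @param spacing Voxel spacing `c(x, y, z)` mm; default `c(2, 2, 2.5)`
#'   (2.5 mm is the planning-CT slice thickness the pipeline assumes).
#' @param slices_per_vertebra Axial slices per vertebral level (default 3).
#' @param jitter_sd Per-level Gaussian jitter (mm) applied to the truth
#'   margins when drawing the reference contour; 0 gives an exact reference.
#' @param seed Integer seed for the jitter; `NULL` uses the current RNG state.
#' @param model [margin_model()] supplying the truth margins.
#' @param growth [growth_model()] used for the age scaling.
#' @param hu Named list of HU assignments: `soft`, `bone`, `canal`, `air`.
#' @param canal_halfwidth_mm Canal half-width (mm) at age 9.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(age = 9, spacing = c(2, 2, 2.5),
                         slices_per_vertebra = 3, jitter_sd = 0, seed = NULL,
                         model = margin_model(), growth = growth_model(),
                         hu = list(soft = 40, bone = 700, canal = 10,
                                   air = -1000),
                         canal_halfwidth_mm = 7) {
  if (any(spacing <= 0)) stop_domain("`spacing` must be positive")
  if (slices_per_vertebra < 1) stop_domain("need >= 1 slice per vertebra")
  if (jitter_sd < 0) stop_domain("`jitter_sd` must be >= 0")
  if (canal_halfwidth_mm <= 0) stop_domain("canal half-width must be > 0")
  structure(list(age = age, spacing = as.numeric(spacing),
                 slices_per_vertebra = as.integer(slices_per_vertebra),
                 jitter_sd = jitter_sd, seed = seed, model = model,
                 growth = growth, hu = hu,
                 canal_halfwidth_mm = canal_halfwidth_mm),
            class = "phantom_spec")
}

#' Generate a synthetic spine phantom
#'
#' Builds a CT volume, vertebra labels C1--S2, canal and body masks, the
#' ground-truth construction margins per level, and a reference contour (the
#' canal expanded by the truth margins, perturbed per level by seeded Gaussian
#' jitter and re-voxelized). Deterministic for a given seed.
#'
#' Per axial block of `slices_per_vertebra` slices (superior = C1), the level
#' `N` carries: a square canal; a ventral bone shell of thickness `X_d(N)`
#' (the truth ventral margin) spanning the vertebral-body width; lateral bone
#' pedicles; and a dorsal spinous process of length `X_p(N)` (the truth
#' dorsal margin). Everything sits in a soft-tissue body whose posterior
#' surface is the beam entry.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `spine_phantom`: `ct` ([ct_volume()]), `spine`
#'   ([labeled_spine()]), `canal` ([structure_volume()]), `truth` (data.frame
#'   `N`, `xd_mm`, `xp_mm`), `truth_model` ([margin_model()]), `reference`
#'   ([structure_volume()]) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- growth_factor(spec$age, spec$growth) /
       growth_factor(9, spec$growth)          # scale 1 at the median age
  sx <- spec$spacing[1]; sy <- spec$spacing[2]
  spv <- spec$slices_per_vertebra

  xd_true <- xd_margin(1:26, spec$model) * s
  xp_true <- xp_margin(1:26, spec$model) * s

  ch_x <- max(1L, round_half_up(spec$canal_halfwidth_mm * s / sx))
  ch_y <- max(1L, round_half_up(spec$canal_halfwidth_mm * s / sy))
  shell <- pmax(1L, round_half_up(xd_true / sy))
  spin <- pmax(1L, round_half_up(xp_true / sy))
  wb <- ch_x + max(1L, round_half_up(12 * s / sx))   # vertebral body halfwidth
  ws <- max(1L, round_half_up(3 / sx))               # spinous halfwidth
  ped <- max(1L, round_half_up(4 * s / sx))          # pedicle thickness

  soft_ant <- max(2L, round_half_up(10 * s / sy))
  soft_post <- max(2L, round_half_up(15 * s / sy))
  yc_front <- 2L + soft_ant + max(shell)             # anterior canal face
  y_skin <- yc_front + 2L * ch_y + max(spin) + soft_post
  ny <- y_skin + 2L
  half_x <- wb + max(2L, round_half_up(8 * s / sx))
  xc <- half_x + 2L
  nx <- 2L * xc
  nz <- 26L * spv

  ct <- array(spec$hu$air, dim = c(nx, ny, nz))
  labels <- array(0L, dim = c(nx, ny, nz))
  canal <- array(FALSE, dim = c(nx, ny, nz))
  body <- array(FALSE, dim = c(nx, ny, nz))

  bx <- (xc - half_x):(xc + half_x)
  by <- 2:y_skin
  body[bx, by, ] <- TRUE

  a <- yc_front; b <- yc_front + 2L * ch_y           # canal y extent
  cx <- (xc - ch_x):(xc + ch_x)
  for (N in 1:26) {
    zs <- ((26L - N) * spv + 1L):((26L - N + 1L) * spv)
    canal[cx, a:b, zs] <- TRUE
    lab <- array(FALSE, dim = c(nx, ny))
    lab[(xc - wb):(xc + wb), (a - shell[N]):(a - 1L)] <- TRUE       # shell
    lab[c((xc - ch_x - ped):(xc - ch_x - 1L),
          (xc + ch_x + 1L):(xc + ch_x + ped)), a:b] <- TRUE         # pedicles
    lab[(xc - ws):(xc + ws), (b + 1L):(b + spin[N])] <- TRUE        # spinous
    labels[, , zs] <- rep(lab * N, times = length(zs))
  }

  ct[body] <- spec$hu$soft
  ct[labels > 0L] <- spec$hu$bone
  ct[canal] <- spec$hu$canal

  ctv <- ct_volume(ct, spec$spacing)
  spine <- labeled_spine(labels, canal, body, spec$spacing)
  canal_sv <- structure_volume(canal, spec$spacing)
  truth_model <- margin_model(xd = xd_true, xp = xp_true,
                              provenance = "phantom-truth")

  ref_model <- if (spec$jitter_sd > 0) {
    with_seed(spec$seed, {
      margin_model(xd = pmax(0.1, xd_true + stats::rnorm(26, 0, spec$jitter_sd)),
                   xp = pmax(0.1, xp_true + stats::rnorm(26, 0, spec$jitter_sd)),
                   provenance = "phantom-reference")
    })
  } else truth_model
  reference <- expand_canal_to_stctv(canal_sv, spine, ref_model)

  structure(list(ct = ctv, spine = spine, canal = canal_sv,
                 truth = data.frame(N = 1:26, xd_mm = xd_true,
                                    xp_mm = xp_true),
                 truth_model = truth_model, reference = reference,
                 spec = spec),
            class = "spine_phantom")
}

#' Packaged per-vertebra cohort expansion table
#'
#' The measured cohort relationship between vertebral level and the expanded
#' WEL margins: per level N = 1..26, the mean ventral (`xd_mean`) and dorsal
#' (`xp_mean`) expansions in mmWEL with 95% confidence bounds and per-level
#' R^2, exactly as packaged.
#'
#' @return A data.frame of class `table3_fixture` with columns `N`, `region`,
#'   `xd_mean`, `xd_ci_lo`, `xd_ci_hi`, `xd_r2`, `xp_mean`, `xp_ci_lo`,
#'   `xp_ci_hi`, `xp_r2`.
#' @examples
#' tab <- load_table3_fixture()
#' tab[tab$N == 8, "xd_mean"]   # 12.6 mmWEL
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "vertebra_wel_margins.csv",
                      package = "spinemargin", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_cols <- c("N", "region", "xd_mean", "xd_ci_lo", "xd_ci_hi", "xd_r2",
                   "xp_mean", "xp_ci_lo", "xp_ci_hi", "xp_r2")
  if (!identical(names(tab), expect_cols) || nrow(tab) != 26L ||
      !identical(tab$N, 1:26))
    stop_domain("packaged margin table is corrupted (schema/row check failed)")
  ok <- tab$xd_ci_lo <= tab$xd_mean & tab$xd_mean <= tab$xd_ci_hi &
        tab$xp_ci_lo <= tab$xp_mean & tab$xp_mean <= tab$xp_ci_hi
  if (!all(ok))
    stop_domain("packaged margin table is corrupted (CI bounds check failed)")
  class(tab) <- c("table3_fixture", "data.frame")
  tab
}

#' Packaged cohort anthropometrics summary
#'
#' Summary characteristics of the nine-patient pediatric cohort behind the
#' packaged margin table: counts, and median/range of age, height, weight,
#' BMI and body surface area.
#'
#' @return A named list of summary values.
#' @export
load_cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_summary.csv",
                      package = "spinemargin", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), c("quantity", "value")))
    stop_domain("packaged cohort summary is corrupted")
  out <- as.list(tab$value)
  names(out) <- tab$quantity
  out
}
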