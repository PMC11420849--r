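# Fitting the piecewise-linear margin model and the growth model from
# measurement tables.

#' Simple linear fit of a margin against vertebral level
#'
#' Ordinary least squares of `value` on `N` with the Pearson correlation.
#'
#' @param N Numeric predictor (vertebral levels).
#' @param value Numeric response (margins, mm).
#' @return An object of class `linear_fit`: `slope`, `intercept`, `r`, `r2`,
#'   `n`.
#' @export
fit_linear <- function(N, value) {
  if (length(N) != length(value)) stop_domain("`N` and `value` lengths differ")
  if (length(unique(N)) < 2L)
    stop_domain("degenerate design: need >= 2 distinct N")
  fit <- stats::lm(value ~ N)
  r <- if (stats::sd(value) == 0) 0 else stats::cor(N, value)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r2 = r^2, n = length(N)),
            class = "linear_fit")
}

#' Fit the per-vertebra margin model from a cohort summary table
#'
#' Converts the per-vertebra mean expansions from mmWEL to real thickness with
#' the region stopping powers, then fits the piecewise model: an OLS line for
#' the ventral margin over T1--L5 (N = 8..24), OLS lines for the dorsal margin
#' over C2--C7 and over T1--L5, and a constant (the mean converted thickness)
#' for the ventral margin over C2--C7. C1 and the sacral levels are taken
#' directly from the table (converted): the atlas is excluded from the
#' cervical fit because the skull enters the beam path, and two sacral levels
#' are too few to support a fitted line.
#'
#' Per-segment correlations (including the ventral C2--C7 and the dorsal
#' thoracic and lumbar sub-segments) are reported alongside. Display
#' coefficients are rounded to one decimal and correlations to two, matching
#' the model's quoted precision; full precision is retained in the fits.
#'
#' @param table Per-vertebra summary with columns `N`, `xd_mean`, `xp_mean`
#'   (mmWEL), covering at least N = 2..24 (as from [summarize_cohort()] or
#'   [load_table3_fixture()]).
#' @param spmap A [stopping_power_map()].
#' @return A list of class `margin_fit`: `model` (a [margin_model()] tagged
#'   `"refitted"`), `fits` (named `linear_fit` objects), `constants`
#'   (C2--C7 ventral constant and the C1/S pass-through margins, mm) and
#'   `display` (rounded coefficients).
#' @export
fit_margin_model <- function(table, spmap = stopping_power_map()) {
  req <- c("N", "xd_mean", "xp_mean")
  if (!all(req %in% names(table)))
    stop_domain("`table` must contain columns ", paste(req, collapse = ", "))
  need <- 2:24
  if (!all(need %in% table$N))
    stop_domain("incomplete range: table must cover N = 2..24, missing ",
                paste(setdiff(need, table$N), collapse = ", "))
  tab <- table[order(table$N), ]
  reg <- vertebra_region(tab$N)
  Xd <- wel_to_thickness(tab$xd_mean, reg, spmap)
  Xp <- wel_to_thickness(tab$xp_mean, reg, spmap)
  at <- function(n) match(n, tab$N)

  fits <- list(
    distal_TL    = fit_linear(8:24, Xd[at(8:24)]),
    proximal_C   = fit_linear(2:7,  Xp[at(2:7)]),
    proximal_TL  = fit_linear(8:24, Xp[at(8:24)]),
    distal_C     = fit_linear(2:7,  Xd[at(2:7)]),
    proximal_T   = fit_linear(8:19, Xp[at(8:19)]),
    proximal_L   = fit_linear(20:24, Xp[at(20:24)])
  )
  xd_c_const <- mean(Xd[at(2:7)])

  xd <- xp <- numeric(26)
  xd[2:7] <- xd_c_const
  xd[8:24] <- fits$distal_TL$intercept + fits$distal_TL$slope * (8:24)
  xp[2:7] <- fits$proximal_C$intercept + fits$proximal_C$slope * (2:7)
  xp[8:24] <- fits$proximal_TL$intercept + fits$proximal_TL$slope * (8:24)
  # pass-through levels, from the table when present, else cohort defaults
  pub <- margin_model(spmap = spmap)
  for (n in c(1L, 25L, 26L)) {
    i <- at(n)
    xd[n] <- if (!is.na(i)) Xd[i] else pub$xd[n]
    xp[n] <- if (!is.na(i)) Xp[i] else pub$xp[n]
  }
  model <- margin_model(xd = xd, xp = xp, provenance = "refitted")

  display <- lapply(fits, function(f)
    list(slope = round(f$slope, 1), intercept = round(f$intercept, 1),
         r = round(f$r, 2)))
  display$distal_C_const <- round(xd_c_const, 1)

  structure(list(model = model, fits = fits,
                 constants = list(xd_c_const = xd_c_const,
                                  xd_c1 = xd[1], xp_c1 = xp[1],
                                  xd_s = xd[25:26], xp_s = xp[25:26]),
                 display = display),
            class = "margin_fit")
}

#' Fit the growth model from age and body surface area
#'
#' OLS regression of BSA (m^2) on age (years); the fitted line is used
#' directly as the growth factor f(g).
#'
#' @param age Ages in years.
#' @param bsa_m2 Body surface areas in m^2.
#' @return A list: `model` (a [growth_model()]), `r` (Pearson correlation),
#'   `fit` (the underlying `linear_fit`).
#' @export
fit_growth_model <- function(age, bsa_m2) {
  f <- fit_linear(age, bsa_m2)
  list(model = growth_model(slope = f$slope, intercept = f$intercept),
       r = f$r, fit = f)
}

#' Serialize a margin fit report as JSON
#'
#' One record per fitted segment: segment name, n, slope, intercept, r, R2.
#'
#' @param fit A `margin_fit` from [fit_margin_model()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "margin_fit"))
  recs <- lapply(names(fit$fits), function(nm) {
    f <- fit$fits[[nm]]
    list(segment = nm, n = f$n, slope = f$slope, intercept = f$intercept,
         r = f$r, R2 = f$r2)
  })
  out <- list(provenance = fit$model$provenance,
              distal_C_const_mm = fit$constants$xd_c_const,
              segments = recs)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: slope %.4f, intercept %.4f, r %.3f (n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' @export
print.margin_fit <- function(x, ...) {
  d <- x$display
  cat("Refitted per-vertebra margin model\n")
  cat(sprintf("  X_d (T/L): %.1f N + %.1f, r %.2f\n",
              d$distal_TL$slope, d$distal_TL$intercept, d$distal_TL$r))
  cat(sprintf("  X_d (C2-C7): constant %.1f mm\n", d$distal_C_const))
  cat(sprintf("  X_p (C2-C7): %.1f N + %.1f\n",
              d$proximal_C$slope, d$proximal_C$intercept))
  cat(sprintf("  X_p (T/L): %.1f N + %.1f\n",
              d$proximal_TL$slope, d$proximal_TL$intercept))
  invisible(x)
}
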