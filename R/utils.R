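# Internal helpers shared across modules.

# Deterministic half-up rounding (base round() is banker's); used wherever a
# physical margin in mm is converted to a whole number of voxels.
round_half_up <- function(x) floor(x + 0.5)

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
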