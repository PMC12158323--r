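# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Impedance phase in the positive-degrees convention
#'
#' Internally impedance is a true complex number, so a capacitive circuit
#' has a negative argument. Every user-facing phase (classifier input,
#' CSV output, meter output) is reported as a positive quantity in
#' degrees: `phase_positive(z) = -Arg(z) * 180 / pi`, which is positive
#' for capacitive impedances.
#'
#' @param z complex impedance value(s), in ohm.
#' @return Phase in degrees, positive for capacitive behaviour.
#' @export
phase_positive <- function(z) -rad2deg(Arg(z))

# Wrap an angle in degrees into (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the global
# stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed and an integer salt,
# kept inside the 32-bit signed range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + 104729 * salt) %% 2147483647)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
}
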