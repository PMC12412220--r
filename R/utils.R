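# Internal helpers: scoped RNG, derived seeds, argument checks.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream. All randomness in the package flows through this helper so that
# every generator is a pure function of its explicit integer seed.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed < 2^31 from a parent seed and index.
childSeed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Standard wavelength grid
#'
#' The canonical reflectance wavelength grid used throughout the package:
#' 350 to 2500 nm inclusive in 1 nm steps (2151 points), the native range of
#' field spectroradiometers covering the VNIR/NIR/SWIR bands.
#'
#' @return Integer vector of wavelengths in nanometres.
#' @export
#' @examples
#' length(wavelengthGrid())  # 2151
wavelengthGrid <- function() 350:2500

sigmoid <- function(x) 1 / (1 + exp(-x))
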