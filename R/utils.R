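#' @import methods
#' @importFrom stats approx coef lm median rnorm runif sd setNames uniroot
#' @importFrom utils modifyList read.csv write.csv packageVersion
NULL

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so library code never clobbers user RNG streams.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible sub-seed (kept well below .Machine$integer.max).
subSeed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

#' Convert scanner resolution to pixel pitch
#'
#' @param dpi resolution in dots per inch.
#' @return pixel pitch in mm/pixel.
#' @examples dpiToPitch(1200)
#' @export
dpiToPitch <- function(dpi) {
  stopifnot(is.numeric(dpi), all(dpi > 0))
  25.4 / dpi
}

# log-log linear interpolation of tabulated positive data
logLogInterp <- function(x, tabX, tabY) {
  stopifnot(all(tabX > 0), all(tabY > 0))
  if (any(x < min(tabX)) || any(x > max(tabX)))
    stop("energy outside tabulated range [", min(tabX), ", ", max(tabX), "] keV",
         call. = FALSE)
  exp(approx(log(tabX), log(tabY), xout = log(x))$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
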