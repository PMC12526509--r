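#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never clobber the
#' caller's RNG stream. All stochastic stages take an explicit seed and fan
#' it out through this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic seed fan-out; keeps derived seeds inside 32-bit range
fanSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

#' The 48 texture positions
#'
#' A "position" is one (GLCM metric, band) pair, labelled metric name plus
#' band digit, e.g. `HOM6` = homogeneity of Band 6 (NIR).
#'
#' @return character vector of the 48 labels, metric-major order.
#' @examples
#' length(positionLabels())  # 48
#' @export
positionLabels <- function() {
  as.vector(t(outer(GLCM_METRICS, 1:6, paste0)))
}

#' Parse a position label into metric and band
#' @param label e.g. `"HOM6"`.
#' @return list with `metric` and `band`.
#' @export
parsePosition <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]{3})([1-6])$", label))[[1]]
  if (length(m) != 3L || !m[2] %in% GLCM_METRICS)
    stop("not a valid position label: '", label, "'")
  list(metric = m[2], band = as.integer(m[3]))
}
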