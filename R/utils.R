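#' Round half away from zero
#'
#' Standard commercial rounding: 0.5 always rounds away from zero, so
#' `round_half_up(77.78, 0)` is 78 and `round_half_up(66.65, 1)` is 66.7.
#' Used for all percentages and means reported by the package, matching how
#' the published tables were rounded (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded to `digits` decimal places, halves away from zero.
#' @export
#' @examples
#' round_half_up(c(77.78, 61.538, 2.5), 0)
#' round_half_up(100 * 5 / 7, 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:n; this never does
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

# Filter a data frame by a named list of equality conditions.
# Returns NULL when the frame lacks one of the scoped columns (scope not
# evaluable at this stage), otherwise a logical row mask.
scope_rows <- function(frame, scope) {
  keep <- rep(TRUE, nrow(frame))
  for (nm in names(scope)) {
    if (!nm %in% names(frame)) return(NULL)
    keep <- keep & frame[[nm]] == scope[[nm]]
  }
  keep
}
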