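#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals.  Base R's
#' `round()` rounds half to even, which never reproduces the half-up
#' percentages printed in genome-report tables; this helper does.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(66.545, 2)  # 66.55, where round() gives 66.54 or 66.55 by parity
#' @export
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    # nudge by an ulp-scale epsilon so values that are exactly .5 in decimal
    # but stored fractionally below it still round up
    z <- abs(x) * p
    z <- floor(z + 0.5 + sqrt(.Machine$double.eps))
    sign(x) * z / p
}

#' Percentage of a count over a total, half-up rounded
#'
#' @param count,total non-negative numbers, `total` > 0.
#' @param digits decimal places kept (2 matches genome-summary tables).
#' @return numeric percentage in [0, 100].
#' @examples
#' asPercent(45593, 68514)  # 66.55
#' @export
asPercent <- function(count, total, digits = 2L) {
    stopifnot(total > 0, count >= 0)
    roundHalfUp(100 * count / total, digits)
}

# stop() with the offending field named; used by config validators
.badField <- function(field, why) {
    stop(sprintf("invalid configuration: field '%s' %s", field, why),
         call. = FALSE)
}

# deterministic sub-seed derivation: one global seed, fixed per-stage offsets
.subSeed <- function(seed, offset) {
    (as.integer(seed) + as.integer(offset)) %% 2147483629L
}

.geoMean <- function(x) exp(mean(log(x)))
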