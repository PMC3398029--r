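#' RHMap: an ordered radiation hybrid map
#'
#' An ordered list of markers with per-interval breakage fractions
#' \eqn{\theta_i}, cumulative centiRay positions
#' (\eqn{d_{cR} = -100\,\ln(1-\theta)}), the retention probability used by the
#' multipoint model, the multipoint log-likelihood, and the obligate
#' chromosome break (OCB) count of the order.
#'
#' @slot markerOrder character vector of marker ids, in map order.
#' @slot theta numeric vector of per-interval breakage fractions, length
#'   one less than the number of markers.
#' @slot r retention probability of the fitted multipoint model.
#' @slot positionsCR cumulative centiRay positions; first marker at 0.
#' @slot logLik multipoint log-likelihood at the fitted parameters.
#' @slot obligateBreaks total obligate breaks of the order on its panel.
#' @slot unplaced marker ids that could not be placed (comprehensive maps).
#'
#' @seealso [fitMap()], [buildComprehensiveMap()]
#' @export
setClass("RHMap", representation(
    markerOrder = "character",
    theta = "numeric",
    r = "numeric",
    positionsCR = "numeric",
    logLik = "numeric",
    obligateBreaks = "integer",
    unplaced = "character"))

.validRHMap <- function(object) {
    msg <- NULL
    k <- length(object@markerOrder)
    if (anyDuplicated(object@markerOrder))
        msg <- c(msg, "markerOrder must be unique")
    if (length(object@theta) != max(k - 1L, 0L))
        msg <- c(msg, "theta must have one entry per interval")
    if (any(object@theta < 0 | object@theta > 1, na.rm = TRUE))
        msg <- c(msg, "theta must lie in [0, 1]")
    if (length(object@positionsCR) != k)
        msg <- c(msg, "positionsCR must have one entry per marker")
    if (k > 0 && is.unsorted(object@positionsCR))
        msg <- c(msg, "positionsCR must be non-decreasing")
    if (k > 0 && object@positionsCR[1] != 0)
        msg <- c(msg, "first marker must sit at 0 cR")
    if (length(object@obligateBreaks) == 1L &&
        !is.na(object@obligateBreaks) && object@obligateBreaks < 0L)
        msg <- c(msg, "obligateBreaks must be >= 0")
    if (is.null(msg)) TRUE else msg
}
setValidity("RHMap", .validRHMap)

#' @rdname RHMap-accessors
#' @export
setGeneric("markerOrder", function(x) standardGeneric("markerOrder"))

#' Accessors for RHMap objects
#'
#' `markerOrder()` gives the ordered marker ids, `intervalTheta()` the fitted
#' per-interval breakage fractions, `positionsCR()` the cumulative centiRay
#' positions, `totalLengthCR()` the map length in cR, `obligateBreaks()` the
#' obligate break count, and `unplacedMarkers()` any markers a comprehensive
#' map could not place.
#'
#' @param x an [RHMap-class].
#' @name RHMap-accessors
#' @aliases markerOrder intervalTheta positionsCR totalLengthCR
#'   obligateBreaks unplacedMarkers
NULL

#' @rdname RHMap-accessors
#' @export
setMethod("markerOrder", "RHMap", function(x) x@markerOrder)

#' @rdname RHMap-accessors
#' @export
setGeneric("intervalTheta", function(x) standardGeneric("intervalTheta"))

#' @rdname RHMap-accessors
#' @export
setMethod("intervalTheta", "RHMap", function(x) x@theta)

#' @rdname RHMap-accessors
#' @export
setGeneric("positionsCR", function(x) standardGeneric("positionsCR"))

#' @rdname RHMap-accessors
#' @export
setMethod("positionsCR", "RHMap", function(x)
    setNames(x@positionsCR, x@markerOrder))

#' @rdname RHMap-accessors
#' @export
setGeneric("totalLengthCR", function(x) standardGeneric("totalLengthCR"))

#' @rdname RHMap-accessors
#' @export
setMethod("totalLengthCR", "RHMap", function(x) {
    k <- length(x@positionsCR)
    if (k == 0L) 0 else x@positionsCR[k]
})

#' @rdname RHMap-accessors
#' @export
setGeneric("obligateBreaks", function(x) standardGeneric("obligateBreaks"))

#' @rdname RHMap-accessors
#' @export
setMethod("obligateBreaks", "RHMap", function(x) x@obligateBreaks)

#' @rdname RHMap-accessors
#' @export
setGeneric("unplacedMarkers", function(x) standardGeneric("unplacedMarkers"))

#' @rdname RHMap-accessors
#' @export
setMethod("unplacedMarkers", "RHMap", function(x) x@unplaced)

setMethod("show", "RHMap", function(object) {
    cat(sprintf("RHMap: %d markers, %.1f cR, %d obligate breaks (r = %.3f)\n",
                length(object@markerOrder), totalLengthCR(object),
                object@obligateBreaks, object@r))
    if (length(object@unplaced))
        cat("  unplaced:", paste(object@unplaced, collapse = ", "), "\n")
})

#' Map table of an RHMap
#'
#' @param x an [RHMap-class].
#' @return data.frame with columns `marker`, `interval_theta` (breakage
#'   fraction of the interval *preceding* each marker; NA for the first) and
#'   `position_cR`.
#' @export
mapTable <- function(x) {
    stopifnot(is(x, "RHMap"))
    data.frame(marker = x@markerOrder,
               interval_theta = c(NA_real_, x@theta),
               position_cR = x@positionsCR,
               row.names = NULL)
}
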