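validate_curve <- function(times, values, what = "curve") {
  if (length(times) < 3L)
    stop_input(what, " needs at least 3 points")
  if (length(times) != length(values))
    stop_input(what, ": times and values differ in length")
  if (any(diff(times) <= 0))
    stop_input(what, ": times must be strictly increasing")
  if (any(values < 0))
    stop_input(what, ": values must be non-negative")
  invisible(TRUE)
}

#' Lysis time from an OD600 growth curve
#'
#' Culture lysis shows as a collapse of optical density after the growth
#' phase. Two operational definitions are provided: \code{"threshold"}
#' returns the first time OD falls below a fraction \code{f} of its maximum
#' after the maximum is reached (default \code{f = 0.5});
#' \code{"max-decline"} returns the time of the steepest negative
#' finite-difference slope after the maximum. Both are invariant under
#' uniform positive scaling of the OD values and return \code{NA} ("no
#' lysis") when the condition never occurs.
#'
#' @param times Minutes, strictly increasing (>= 3 points).
#' @param od600 Optical density readings, same length.
#' @param method \code{"threshold"} or \code{"max-decline"}.
#' @param f Threshold fraction of the maximum OD (threshold method).
#' @return Lysis time in minutes, or \code{NA_real_} if the culture never
#'   lyses under the chosen definition.
#' @examples
#' curve <- makeOdCurve(lysisMidpoint = 30)
#' lysisTime(curve$time, curve$od600)
#' @export
lysisTime <- function(times, od600, method = c("threshold", "max-decline"),
                      f = 0.5) {
  method <- match.arg(method)
  validate_curve(times, od600, "OD curve")
  imax <- which.max(od600)
  if (imax == length(times)) return(NA_real_)  # still growing at the end
  after <- seq(imax, length(times))
  if (method == "threshold") {
    hit <- after[od600[after] < f * od600[imax]]
    if (length(hit) == 0L) return(NA_real_)
    return(times[hit[1L]])
  }
  slopes <- diff(od600[after]) / diff(times[after])
  if (all(slopes >= 0)) return(NA_real_)
  i <- which.min(slopes)
  # midpoint of the steepest declining interval
  (times[after[i]] + times[after[i + 1L]]) / 2
}

#' Growth rate as doublings per hour
#'
#' Fitness from a timed plate-growth assay: \code{log2(final/initial)/hours}.
#'
#' @param initialTiter,finalTiter Plaque-forming units (> 0).
#' @param hours Assay duration in hours (> 0; plate assays default to 3 h in
#'   the workflows this supports, but the duration is always explicit here).
#' @return Doublings per hour (negative if the titer fell).
#' @examples
#' doublingsPerHour(50, 400, 3)  # 1: 8-fold = 3 doublings over 3 h
#' @export
doublingsPerHour <- function(initialTiter, finalTiter, hours) {
  if (any(initialTiter <= 0) || any(finalTiter <= 0))
    stop_input("titers must be positive")
  if (any(hours <= 0))
    stop_input("hours must be positive")
  log2(finalTiter / initialTiter) / hours
}

#' Endpoint value of a fluorescence (or other) kinetic curve
#'
#' Returns the reading at the sample closest to \code{tEnd} (default 60 min,
#' the endpoint used to summarise in vitro transcription kinetics); feeds
#' \code{\link{normalizeActivity}}.
#'
#' @param times Minutes, strictly increasing.
#' @param values Readings, same length.
#' @param tEnd Endpoint in minutes; must lie within the recorded range.
#' @return The reading closest in time to \code{tEnd}.
#' @export
endpointActivity <- function(times, values, tEnd = 60) {
  validate_curve(times, values, "kinetic curve")
  if (tEnd < min(times) || tEnd > max(times))
    stop_input("tEnd ", tEnd, " outside recorded range [", min(times), ", ",
               max(times), "]")
  values[which.min(abs(times - tEnd))]
}

#' Read and write phenotype curves
#'
#' Curve TSV carries columns \code{time}, \code{value}, \code{label}.
#'
#' @param path File path.
#' @param curves data.frame with \code{time}, \code{value}, \code{label}.
#' @return Reader returns the data.frame; writer returns \code{path}
#'   invisibly.
#' @name curveIO
NULL

#' @rdname curveIO
#' @export
readCurveTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("time", "value", "label") %in% names(tab)))
    stop_input("curve table must have columns time, value, label")
  tab
}

#' @rdname curveIO
#' @export
writeCurveTable <- function(curves, path) {
  write.table(curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
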