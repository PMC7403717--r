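#' Per-cell time series of apical area
#'
#' Container for one cell's measurements during ventral furrow formation:
#' acquisition times, apical area (missing segmentation frames as `NA`), and
#' optionally a fluorescent reporter intensity and a shape anisotropy.
#'
#' @param times_s numeric, strictly increasing acquisition times in seconds.
#' @param area_um2 numeric, apical area in square micrometres; `NA` marks
#'   frames where segmentation failed. Present values must be positive.
#' @param intensity optional numeric reporter intensity (a.u.), same length.
#' @param anisotropy optional numeric shape anisotropy, same length.
#' @param embryo_id,cell_id identifiers of the embryo and the cell.
#' @return An object of class `cell_trace`.
#' @examples
#' tr <- cell_trace(times_s = c(0, 3.8, 7.6), area_um2 = c(40, NA, 38))
#' tr
#' @export
cell_trace <- function(times_s, area_um2, intensity = NULL, anisotropy = NULL,
                       embryo_id = "emb1", cell_id = "cell1") {
  times_s <- as.numeric(times_s)
  area_um2 <- as.numeric(area_um2)
  if (length(times_s) != length(area_um2))
    ap_stop("times_s and area_um2 must have equal length", "invalid_parameters")
  if (length(times_s) == 0) ap_stop("empty trace", "empty_trace")
  if (anyNA(times_s) || any(diff(times_s) <= 0))
    ap_stop("times_s must be strictly increasing and non-missing", "nonmonotone_times")
  if (any(area_um2[!is.na(area_um2)] <= 0))
    ap_stop("present area values must be positive", "invalid_parameters")
  for (nm in c("intensity", "anisotropy")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != length(times_s))
      ap_stop(sprintf("%s must match trace length", nm), "invalid_parameters")
  }
  structure(
    list(embryo_id = as.character(embryo_id), cell_id = as.character(cell_id),
         times_s = times_s, area_um2 = area_um2,
         intensity = if (is.null(intensity)) NULL else as.numeric(intensity),
         anisotropy = if (is.null(anisotropy)) NULL else as.numeric(anisotropy)),
    class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  n <- length(x$times_s)
  cat(sprintf("<cell_trace> %s/%s: %d samples, t = [%g, %g] s, %d missing\n",
              x$embryo_id, x$cell_id, n, x$times_s[1], x$times_s[n],
              sum(is.na(x$area_um2))))
  invisible(x)
}

#' @export
print.trace_cohort <- function(x, ...) {
  cat(sprintf("<trace_cohort> %d cells, %d embryos\n", length(x),
              length(unique(vapply(x, `[[`, "", "embryo_id")))))
  invisible(x)
}

as_trace_cohort <- function(traces) {
  stopifnot(all(vapply(traces, inherits, TRUE, "cell_trace")))
  structure(traces, class = "trace_cohort")
}

# indices of frames with a measured area
present_idx <- function(trace) which(!is.na(trace$area_um2))
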