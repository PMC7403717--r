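#' Write a cohort of cell traces to a delimited trace table
#'
#' The trace-table format is comma-separated text with a mandatory header and
#' columns `embryo_id, cell_id, time_s, area_um2` plus optional `intensity`
#' and `anisotropy`; missing values are empty fields. Rows are unique in
#' (embryo_id, cell_id, time_s) and times are strictly increasing within a
#' cell. The file is written atomically (write-then-rename).
#'
#' @param traces a `trace_cohort`, list of [cell_trace()]s, or one trace.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "cell_trace")) traces <- list(traces)
  has_int <- any(vapply(traces, function(tr) !is.null(tr$intensity), TRUE))
  has_ani <- any(vapply(traces, function(tr) !is.null(tr$anisotropy), TRUE))
  rows <- do.call(rbind, lapply(traces, function(tr) {
    df <- data.frame(embryo_id = tr$embryo_id, cell_id = tr$cell_id,
                     time_s = tr$times_s, area_um2 = tr$area_um2,
                     stringsAsFactors = FALSE)
    if (has_int) df$intensity <- if (is.null(tr$intensity)) NA_real_ else tr$intensity
    if (has_ani) df$anisotropy <- if (is.null(tr$anisotropy)) NA_real_ else tr$anisotropy
    df
  }))
  atomic_write(path, function(tmp)
    utils::write.csv(rows, tmp, row.names = FALSE, na = ""))
  invisible(path)
}

#' Read a delimited trace table into a cohort
#'
#' Validates the format written by [write_trace_table()]: required columns
#' must be present, (embryo_id, cell_id, time_s) keys unique, and times
#' strictly increasing within each cell. A write/read round trip is the
#' identity up to float formatting.
#'
#' @param path input file path.
#' @return a `trace_cohort`.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) ap_stop(sprintf("no such file: %s", path), "missing_file")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("embryo_id", "cell_id", "time_s", "area_um2")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    ap_stop(sprintf("trace table is missing column(s): %s", paste(miss, collapse = ", ")),
            "missing_column")
  key <- paste(df$embryo_id, df$cell_id, df$time_s, sep = "\r")
  if (anyDuplicated(key))
    ap_stop("duplicate (embryo_id, cell_id, time_s) rows", "duplicate_key")
  cellkey <- paste(df$embryo_id, df$cell_id, sep = "\r")
  traces <- lapply(split(df, factor(cellkey, levels = unique(cellkey))), function(g) {
    if (any(diff(g$time_s) <= 0))
      ap_stop(sprintf("times not strictly increasing for cell %s/%s",
                      g$embryo_id[1], g$cell_id[1]), "nonmonotone_times")
    cell_trace(times_s = g$time_s, area_um2 = g$area_um2,
               intensity = if ("intensity" %in% names(g) && !all(is.na(g$intensity))) g$intensity,
               anisotropy = if ("anisotropy" %in% names(g) && !all(is.na(g$anisotropy))) g$anisotropy,
               embryo_id = g$embryo_id[1], cell_id = g$cell_id[1])
  })
  names(traces) <- NULL
  as_trace_cohort(traces)
}

#' Write an analysis results bundle as JSON
#'
#' Serializes a named list (run configuration, seed, per-cell results, group
#' statistics, ...) to self-describing JSON, atomically. Software version and
#' units are added under `meta` unless already present.
#'
#' @param x named list of results.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_json <- function(x, path) {
  if (is.null(x$meta)) {
    x$meta <- list(package = "apicalpulse",
                   version = as.character(utils::packageVersion("apicalpulse")),
                   units = list(time = "s", area = "um^2", rate = "um^2/min"))
  }
  atomic_write(path, function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(path)
}

#' Write an image stack (or 2D/3D array) as multi-page TIFF with sidecar
#'
#' Intensities are scaled into \[0, 1\] for 32-bit float TIFF storage; the
#' scale and the physical calibration go to a JSON sidecar (`<path>.json`) so
#' [read_stack_tiff()] restores the original values.
#'
#' @param stack an [image_stack()] or numeric array `[y, x, z]`.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack)
  if (length(d) == 2) { dim(stack) <- c(d, 1L); d <- dim(stack) }
  scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(d[3]), function(s) unclass(stack)[, , s] / scale)
  atomic_write(path, function(tmp) tiff::writeTIFF(pages, tmp, bits.per.sample = 32L))
  sidecar <- list(scale = scale,
                  pixel_size_um = attr(stack, "pixel_size_um"),
                  z_step_um = attr(stack, "z_step_um"),
                  time_s = attr(stack, "time_s"))
  atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA, null = "null"))
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist for the
#'   intensity scale and calibration.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) ap_stop(sprintf("no such file: %s", path), "missing_file")
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) ap_stop("missing JSON sidecar with calibration", "missing_file")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) vox[, , s] <- pages[[s]] * side$scale
  image_stack(vox, pixel_size_um = side$pixel_size_um, z_step_um = side$z_step_um,
              time_s = side$time_s)
}

#' Randomized blinded presentation order
#'
#' Shuffles samples into a seed-reproducible uniform random order and assigns
#' opaque ids that carry no information about group or identity, so an
#' experimentalist can score phenotypes blind. The key mapping opaque ids
#' back to the true identities is kept separate (write it with
#' [write_blinded_key()] and open it only after scoring).
#'
#' @param items character vector (or coercible) of sample identities.
#' @param seed integer seed; the same seed reproduces the same order.
#' @return list of class `blinded_order`: `presentation` (data frame with
#'   `position`, `opaque_id`) and `key` (data frame with `opaque_id`,
#'   `item`), plus the seed.
#' @export
blinded_order <- function(items, seed) {
  items <- as.character(items)
  if (length(items) < 1) ap_stop("need at least one item", "empty_input")
  perm <- with_seed(seed, sample.int(length(items)))
  opaque <- sprintf("S%04d", seq_along(items))
  structure(list(presentation = data.frame(position = seq_along(items),
                                           opaque_id = opaque,
                                           stringsAsFactors = FALSE),
                 key = data.frame(opaque_id = opaque, item = items[perm],
                                  stringsAsFactors = FALSE),
                 seed = as.integer(seed)),
            class = "blinded_order")
}

#' Write the blinding key of a [blinded_order()] to CSV
#'
#' @param order a `blinded_order`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_blinded_key <- function(order, path) {
  stopifnot(inherits(order, "blinded_order"))
  atomic_write(path, function(tmp)
    utils::write.csv(order$key, tmp, row.names = FALSE))
  invisible(path)
}
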