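#' Save a run container
#'
#' Writes a single self-describing file holding any combination of package
#' objects (phantom, trajectory, k-space data, traces, masks, results and
#' the configuration with its seeds), so that a run is reconstructible from
#' its outputs alone. R's native serialization is used as the container
#' format; complex arrays round-trip bit-identically.
#'
#' @param path output file path.
#' @param objects named list of objects to store.
#' @return `path`, invisibly.
#' @export
save_container <- function(path, objects) {
  if (is.null(names(objects)) || any(names(objects) == ""))
    stop("objects must be a fully named list")
  payload <- list(.format = "radialnav-container", .version = 1L,
                  .written = format(Sys.time(), tz = "UTC"),
                  data = objects)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a run container
#'
#' @param path file written by [save_container()].
#' @param require optional character vector of dataset names that must be
#'   present; a schema error listing the absent names is raised otherwise.
#' @return the named list of stored objects.
#' @export
load_container <- function(path, require = NULL) {
  if (!file.exists(path)) stop("container not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("container unreadable (truncated or not a radialnav container): ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(payload) || !identical(payload$.format, "radialnav-container"))
    stop("schema error: file is not a radialnav container")
  if (!is.null(require)) {
    absent <- setdiff(require, names(payload$data))
    if (length(absent) > 0)
      stop("schema error: container is missing datasets: ",
           paste(absent, collapse = ", "))
  }
  payload$data
}

#' Export a motion trace as delimited text
#'
#' Writes one row per interleave with columns `interleave`, `dx_mm`,
#' `dy_mm` and, when available, `si_mm`.
#'
#' @param trace a [motion_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(interleave = seq_along(trace$dx_mm),
                   dx_mm = trace$dx_mm, dy_mm = trace$dy_mm)
  if (!is.null(trace$si_mm)) df$si_mm <- trace$si_mm
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trace written by [write_trace()]
#'
#' @param path delimited text file.
#' @param reference_index reference interleave of the stored trace.
#' @param pixel_mm optional pixel size to attach.
#' @return a [motion_trace()].
#' @export
read_trace <- function(path, reference_index = 1L, pixel_mm = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  motion_trace(df$dx_mm, df$dy_mm, reference_index = reference_index,
               pixel_mm = pixel_mm,
               si_mm = if ("si_mm" %in% names(df)) df$si_mm else NULL)
}
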