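#' Read and write nuslist schedule files
#'
#' The nuslist interchange format used by spectrometer software is plain text
#' with one 0-based sampled increment per line, ascending. Writing then reading
#' a schedule is the identity on `grid_size`, `indices` and `coverage`; kind
#' and seed are not stored in the file, so schedules read back have kind
#' `"custom"`.
#'
#' @param schedule a [new_sampling_schedule()] object.
#' @param path file path to write to / read from (or a connection).
#' @param grid_size Nyquist grid size the indices must fit in.
#' @return `write_nuslist()` returns `path` invisibly; `read_nuslist()` returns
#'   a `sampling_schedule` of kind `"custom"`.
#' @examples
#' f <- tempfile(fileext = ".nus")
#' write_nuslist(generate_random_shuffle(64, 0.5, seed = 1), f)
#' read_nuslist(f, grid_size = 64)
#' @export
write_nuslist <- function(schedule, path) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  writeLines(format(schedule$indices, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_nuslist
#' @export
read_nuslist <- function(path, grid_size) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_param("empty nuslist file: ", path)
  x <- suppressWarnings(as.numeric(lines))
  if (any(is.na(x)) || any(x != round(x)) || any(x < 0)) {
    stop_param("nuslist format error: every line must be one non-negative integer")
  }
  x <- as.integer(x)
  if (anyDuplicated(x)) stop_param("nuslist format error: duplicate index")
  if (any(x >= grid_size)) {
    stop_param("nuslist format error: index out of range for grid_size ", grid_size)
  }
  new_sampling_schedule(grid_size, sort(x), "custom")
}
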