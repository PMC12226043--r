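# Plain-text exchange formats for pipeline intermediates.

#' Write / read spike and unit tables as CSV
#'
#' Spike events are stored as `(unit_id, time_s)`, unit summaries as
#' `(unit_id, n_spikes, amplitude_uV, width_ms, cardiac_flag)`, and binned
#' rate series as their full tibble. Plain CSV keeps intermediates
#' language-agnostic and diffable.
#'
#' @param x Tibble to write.
#' @param path Output file path.
#' @return `path`, invisibly (writers); a tibble (readers).
#' @name cap_io
NULL

#' @rdname cap_io
#' @export
write_spikes_csv <- function(x, path) {
  utils::write.csv(x[, intersect(c("unit_id", "time_s"), names(x))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname cap_io
#' @export
write_units_csv <- function(x, path) {
  cols <- intersect(c("unit", "unit_id", "n_spikes", "amplitude_uV",
                      "width_ms", "cardiac_flag"), names(x))
  utils::write.csv(x[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cap_io
#' @export
write_rates_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cap_io
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
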