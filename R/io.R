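## Plain-text interchange: CSV schemas for event tables, histograms, colony
## counts and OD plates, plus JSON export of fit objects.

#' Read / write flow event tables
#'
#' CSV schema: `event_id,area,width` (a `population` column, if present, is
#' kept on read and dropped on write — it is simulation bookkeeping, not an
#' instrument field).
#'
#' @param path file path.
#' @param events a `flow_events` data.frame.
#' @return `read_flow_events`: a `flow_events` data.frame.
#' @export
read_flow_events <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event_id", "area", "width") %in% names(x)))
    stopf("%s: expected columns event_id,area,width", path)
  if (any(x$area < 0) || any(x$width < 0))
    stopf("%s: area and width must be >= 0", path)
  class(x) <- c("flow_events", "data.frame")
  x
}

#' @rdname read_flow_events
#' @export
write_flow_events <- function(events, path) {
  utils::write.csv(events[, c("event_id", "area", "width")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a PI histogram as `channel,count` CSV
#'
#' Channels are bin centers on a uniform grid; edges are reconstructed from
#' the spacing on read.
#'
#' @param path file path.
#' @param hist a `pi_histogram`.
#' @return `read_histogram_csv`: a `pi_histogram`.
#' @export
read_histogram_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "count") %in% names(x)))
    stopf("%s: expected columns channel,count", path)
  ch <- x$channel
  w <- diff(ch)
  if (length(unique(round(w, 9))) != 1) stopf("%s: channels must be uniform", path)
  structure(list(bin_edges = c(ch - w[1] / 2, ch[length(ch)] + w[1] / 2),
                 counts = x$count, n_bins = length(ch), n_overflow = 0L),
            class = "pi_histogram")
}

#' @rdname read_histogram_csv
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(data.frame(channel = bin_centers(hist), count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a colony-count table (`dose_gy,dish_id,cells_seeded,colonies`)
#'
#' @param path file path.
#' @param table a `colony_counts` data.frame.
#' @return a `colony_counts` data.frame.
#' @export
read_colony_counts <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_gy", "dish_id", "cells_seeded", "colonies")
  if (!all(need %in% names(x)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ","))
  if (any(x$colonies < 0) || any(x$cells_seeded <= 0))
    stopf("%s: colonies must be >= 0 and cells_seeded > 0", path)
  class(x) <- c("colony_counts", "data.frame")
  x
}

#' @rdname read_colony_counts
#' @export
write_colony_counts <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OD plate table (`well,row,col,condition,dose_gy,od562`)
#'
#' @param path file path.
#' @param plate an `od_table` data.frame.
#' @return an `od_table` data.frame.
#' @export
read_od_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "condition", "od562") %in% names(x)))
    stopf("%s: expected at least columns well,condition,od562", path)
  if (any(!is.finite(x$od562))) stopf("%s: od562 must be finite", path)
  class(x) <- c("od_table", "data.frame")
  x
}

#' @rdname read_od_table
#' @export
write_od_table <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## strip classes/attributes so jsonlite serialises plainly
.plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, unclass)))
  if (is.list(x)) return(lapply(x, .plain))
  unclass(x)
}

#' Write an analysis object as JSON
#'
#' Works for `mixture_fit`, `multitarget_fit`, `viability_table`,
#' `kinetics_result` and plain lists.
#'
#' @param x object to serialise.
#' @param path output path.
#' @export
write_fit_json <- function(x, path) {
  jsonlite::write_json(.plain(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
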