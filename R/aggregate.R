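#' Section annotations for a piece
#'
#' Sections tile the piece: `n_boundaries + 1` sections per piece. In the
#' study layout the three pieces have 7, 9, and 9 sections, so each
#' participant contributes 25 section-averaged observations per condition
#' and measure.
#'
#' @param piece_id Piece identifier.
#' @param duration_s Piece duration (s).
#' @param boundary_times_s Strictly increasing boundary onsets inside
#'   `(0, duration_s)`.
#' @param labels Optional section labels (`n_boundaries + 1`).
#' @return Tibble of class `section_annotation`: `piece_id`,
#'   `section_label`, `start_s`, `end_s`. Multiple pieces may be combined
#'   with [dplyr::bind_rows()].
#' @export
section_annotation <- function(piece_id, duration_s, boundary_times_s,
                               labels = NULL) {
  check_strictly_increasing(boundary_times_s, "boundary times")
  if (length(boundary_times_s) &&
      (min(boundary_times_s) <= 0 || max(boundary_times_s) >= duration_s)) {
    abort("boundaries must lie strictly inside the piece")
  }
  edges <- c(0, boundary_times_s, duration_s)
  ns <- length(edges) - 1
  labels <- labels %||% paste0("S", seq_len(ns))
  out <- tibble::tibble(piece_id = piece_id,
                        section_label = labels,
                        start_s = edges[-length(edges)],
                        end_s = edges[-1])
  structure(out, class = c("section_annotation", class(out)))
}

section_boundaries <- function(sections) {
  dplyr::transmute(
    dplyr::filter(dplyr::as_tibble(sections), .data$end_s < max(.data$end_s),
                  .by = "piece_id"),
    piece_id = .data$piece_id, boundary_time_s = .data$end_s
  )
}

piece_durations <- function(sections) {
  dplyr::summarise(dplyr::as_tibble(sections),
                   duration_s = max(.data$end_s), .by = "piece_id")
}

#' Time-averaged synchrony per section or 30-s bin
#'
#' Averages sliding-window synchrony values whose window centers fall inside
#' each musical section (default) or inside fixed 30-s bins (a check that
#' controls for section length). One row per grouping combination x
#' section/bin; sections that contain no window centers yield a masked
#' (`NA`) row.
#'
#' @param sync Long tibble with columns `window_center_s`, `value`, a
#'   `piece_id` column, and any further grouping columns (participant, pair,
#'   concert, condition, measure), e.g. stacked `sync_series` results.
#' @param sections A [section_annotation()] table covering every piece in
#'   `sync`.
#' @param mode `"sections"` or `"bins30s"`.
#' @param bin_s Bin length for `"bins30s"`.
#' @return Tibble with the grouping columns plus `section` and `value`.
#' @export
aggregate_time_averaged <- function(sync, sections,
                                    mode = c("sections", "bins30s"),
                                    bin_s = 30) {
  mode <- match.arg(mode)
  stopifnot(all(c("window_center_s", "value", "piece_id") %in% names(sync)))
  sec <- dplyr::as_tibble(sections)
  group_cols <- setdiff(names(sync), c("window_center_s", "value", "n_pairs"))
  if (mode == "sections") {
    pieces <- split(sec, sec$piece_id)
    sync <- dplyr::mutate(
      sync,
      section = {
        out <- character(dplyr::n())
        for (pid in names(pieces)) {
          rows <- .data$piece_id == pid
          edges <- c(pieces[[pid]]$start_s[1], pieces[[pid]]$end_s)
          idx <- findInterval(.data$window_center_s[rows], edges,
                              rightmost.closed = TRUE)
          idx[idx < 1 | idx > nrow(pieces[[pid]])] <- NA
          out[rows] <- pieces[[pid]]$section_label[idx]
        }
        out
      }
    )
    # every section appears, masked when empty
    full <- tidyr::crossing(
      dplyr::distinct(sync, dplyr::across(dplyr::all_of(
        setdiff(group_cols, "piece_id")))),
      dplyr::distinct(sec, .data$piece_id, section = .data$section_label)
    )
  } else {
    sync <- dplyr::mutate(sync,
                          section = sprintf("bin%02d",
                                            floor(.data$window_center_s / bin_s)))
    full <- NULL
  }
  agg <- dplyr::summarise(
    dplyr::filter(sync, !is.na(.data$section)),
    value = mean(.data$value, na.rm = TRUE),
    n_windows = sum(!is.na(.data$value)),
    .by = dplyr::all_of(c(group_cols, "section"))
  )
  agg$value[agg$n_windows == 0] <- NA_real_
  if (!is.null(full)) {
    agg <- dplyr::left_join(full, agg,
                            by = intersect(names(full), names(agg)))
    if (anyNA(agg$value)) {
      warn(sprintf("aggregate_time_averaged(): %d empty section cell(s) masked",
                   sum(is.na(agg$value))))
    }
  }
  dplyr::as_tibble(agg)
}

epoch_window_labels <- c("-10", "-5", "0", "5", "10")

#' Epoch synchrony (or rate) series around section boundaries
#'
#' Cuts ±`half_width_s` epochs around every section boundary and partitions
#' each into `window_len_s`-second windows — five 6-s windows for the
#' default ±15 s epoch, with edges at {-15, -9, -3, 3, 9, 15} s and the
#' conventional labels {-10, -5, 0, 5, 10}. Boundaries closer than
#' `half_width_s` to a piece edge are dropped (and reported). The per-window
#' mean is recorded; each retained epoch contributes exactly five rows per
#' grouping combination.
#'
#' @param sync Long tibble with a time column, `value`, `piece_id`, and any
#'   further grouping columns.
#' @param sections A [section_annotation()] table.
#' @param half_width_s Epoch half-width (s).
#' @param window_len_s Sub-window length (s); must divide `2*half_width_s`.
#' @param time_col Name of the time column (`"window_center_s"` for
#'   synchrony series, `"time_s"` for rate series).
#' @return Tibble of class `epoch_table`: grouping columns plus
#'   `boundary_index`, `boundary_time_s`, `window` (ordered factor) and
#'   `value`; attribute `dropped_boundaries`.
#' @export
epoch_around_boundaries <- function(sync, sections, half_width_s = 15,
                                    window_len_s = 6,
                                    time_col = "window_center_s") {
  stopifnot(all(c(time_col, "value", "piece_id") %in% names(sync)))
  n_win <- 2 * half_width_s / window_len_s
  if (abs(n_win - round(n_win)) > 1e-9) {
    abort("window_len_s must divide the epoch length")
  }
  n_win <- as.integer(round(n_win))
  labels <- if (n_win == 5L) epoch_window_labels else {
    as.character(seq(-half_width_s + window_len_s / 2,
                     by = window_len_s, length.out = n_win))
  }
  bounds <- section_boundaries(sections)
  durations <- piece_durations(sections)
  bounds <- dplyr::left_join(bounds, durations, by = "piece_id")
  bounds <- dplyr::mutate(bounds,
                          boundary_index = dplyr::row_number(),
                          .by = "piece_id")
  dropped <- dplyr::filter(bounds,
                           .data$boundary_time_s < half_width_s |
                             .data$boundary_time_s > .data$duration_s - half_width_s)
  if (nrow(dropped)) {
    warn(sprintf("epoch_around_boundaries(): %d boundary(ies) within %g s of a piece edge dropped",
                 nrow(dropped), half_width_s))
  }
  kept <- dplyr::anti_join(bounds, dropped,
                           by = c("piece_id", "boundary_index"))
  group_cols <- setdiff(names(sync), c(time_col, "value", "n_pairs"))
  pieces <- split(sync, sync$piece_id)
  out <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    b <- kept$boundary_time_s[i]
    pid <- kept$piece_id[i]
    d <- pieces[[pid]]
    if (is.null(d)) return(NULL)
    tt <- d[[time_col]]
    sel <- tt >= b - half_width_s & tt < b + half_width_s
    if (!any(sel)) return(NULL)
    d <- d[sel, , drop = FALSE]
    win_idx <- pmin(n_win, 1L + floor((d[[time_col]] - b + half_width_s) /
                                        window_len_s))
    d$window <- labels[win_idx]
    agg <- dplyr::summarise(d, value = mean(.data$value, na.rm = TRUE),
                            .by = dplyr::all_of(c(group_cols, "window")))
    agg$boundary_index <- kept$boundary_index[i]
    agg$boundary_time_s <- b
    agg
  })
  out$window <- factor(out$window, levels = labels)
  out$value[is.nan(out$value)] <- NA_real_
  structure(dplyr::as_tibble(out),
            class = c("epoch_table", class(dplyr::as_tibble(out))),
            dropped_boundaries = dropped,
            window_labels = labels)
}
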