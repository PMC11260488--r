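#' @section Gating pipeline:
#' The gating scheme mirrors analyzer practice: a forward-scatter trigger
#' threshold removes small particles, an FSC-W quantile gate removes
#' doublets/aggregates, a highest-density contour gate on FSC-A vs SSC-A
#' keeps the physiologically uniform core of the population, and the
#' fluorescence channels are log-transformed before noise statistics. The
#' order is fixed: trigger -> doublet -> contour -> log. Every gate returns
#' the subset table with a cumulative `gate_log` attribute of per-stage
#' reports; event order is never changed, so provenance labels stay aligned.
#' @name cytometry
#' @keywords internal
NULL

nv_channels <- c("FSC_A", "FSC_W", "SSC_A", "GFP", "mCherry")

require_channels <- function(events, channels) {
  miss <- setdiff(channels, names(events))
  if (length(miss))
    stop("missing channel(s): ", paste(miss, collapse = ", "))
}

append_gate <- function(events, stage, n_input, n_output, params = list()) {
  log <- attr(events, "gate_log")
  if (is.null(log)) log <- list()
  log[[length(log) + 1]] <- list(stage = stage, n_input = n_input,
                                 n_output = n_output, params = params)
  attr(events, "gate_log") <- log
  events
}

subset_events <- function(events, keep) {
  out <- events[keep, , drop = FALSE]
  attr(out, "log_channels") <- attr(events, "log_channels")
  attr(out, "log_base") <- attr(events, "log_base")
  attr(out, "gate_log") <- attr(events, "gate_log")
  class(out) <- class(events)
  out
}

#' Gate report accessor
#'
#' @param events An `event_table` that has passed through one or more gates.
#' @return List of per-stage reports (stage, n_input, n_output, parameters).
#' @export
gate_report <- function(events) {
  log <- attr(events, "gate_log")
  if (is.null(log)) list() else log
}

#' Serialize a gate report to JSON
#'
#' @param events A gated `event_table`.
#' @param path Output file path.
#' @export
write_gate_report <- function(events, path) {
  jsonlite::write_json(gate_report(events), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Forward-scatter trigger threshold
#'
#' Retains events with FSC-A at or above the trigger threshold; events with
#' FSC-A strictly below it (small particles in the fluidic system) are
#' excluded, matching the instrument convention of a `< threshold` cut.
#'
#' @param events An `event_table`.
#' @param min_fsc Trigger threshold in FSC-A units (default 2570).
#' @return The retained `event_table` with an appended gate report.
#' @export
trigger_threshold <- function(events, min_fsc = 2570) {
  require_channels(events, "FSC_A")
  keep <- events$FSC_A >= min_fsc
  out <- subset_events(events, keep)
  append_gate(out, "trigger", nrow(events), sum(keep),
              list(min_fsc = min_fsc))
}

#' FSC-width doublet gate
#'
#' Removes events whose FSC-W exceeds the given quantile of FSC-W within the
#' input: doublets and aggregates carry inflated widths. The boundary is
#' data-driven (a within-sample quantile) because no absolute width cutoff
#' generalizes across instruments.
#'
#' @param events An `event_table`.
#' @param width_quantile Quantile of FSC-W above which events are removed
#'   (default 0.90).
#' @return The retained `event_table` with an appended gate report. With
#'   fewer than 10 events the quantile is unreliable: the gate warns and is
#'   skipped.
#' @export
doublet_gate <- function(events, width_quantile = 0.90) {
  require_channels(events, "FSC_W")
  stopifnot(width_quantile > 0, width_quantile < 1)
  n <- nrow(events)
  if (n < 10) {
    warning("fewer than 10 events; doublet gate skipped")
    return(append_gate(events, "doublet", n, n,
                       list(width_quantile = width_quantile,
                            skipped = TRUE)))
  }
  cut <- stats::quantile(events$FSC_W, width_quantile, names = FALSE)
  keep <- events$FSC_W <= cut
  out <- subset_events(events, keep)
  append_gate(out, "doublet", n, sum(keep),
              list(width_quantile = width_quantile, boundary = cut))
}

#' Highest-density contour gate
#'
#' Approximates instrument contour gating: a 2-D histogram is built on the
#' two channels and bins are admitted in order of decreasing event count
#' (ties broken by row, then column index) until the admitted bins first
#' hold at least `fraction` of the events. The retained fraction therefore
#' lies in `[fraction, fraction + m/n]` where m is the count of the last
#' admitted bin.
#'
#' @param events An `event_table` with at least 100 events.
#' @param channels The two channels to gate on (default FSC-A vs SSC-A).
#' @param fraction Target retained fraction in (0, 1) (default 0.80).
#' @param bins Bins per axis (default 64). If the input has fewer events
#'   than bins per axis the grid is coarsened with a warning.
#' @return The retained `event_table` with an appended gate report.
#' @export
density_contour_gate <- function(events, channels = c("FSC_A", "SSC_A"),
                                 fraction = 0.80, bins = 64) {
  require_channels(events, channels)
  stopifnot(fraction > 0, fraction < 1, length(channels) == 2)
  n <- nrow(events)
  if (n < 100) stop("contour gate requires >= 100 events")
  if (n < bins) {
    bins <- max(2L, floor(sqrt(n)))
    warning("fewer events than bins per axis; grid coarsened to ", bins)
  }
  x <- events[[channels[1]]]
  y <- events[[channels[2]]]
  bx <- pmin(pmax(1L, findInterval(
    x, seq(min(x), max(x), length.out = bins + 1), rightmost.closed = TRUE)),
    bins)
  by <- pmin(pmax(1L, findInterval(
    y, seq(min(y), max(y), length.out = bins + 1), rightmost.closed = TRUE)),
    bins)
  cell <- (bx - 1L) * bins + by  # row-major: row = bx, column = by
  counts <- tabulate(cell, nbins = bins * bins)
  nonzero <- which(counts > 0)
  ord <- nonzero[order(-counts[nonzero], nonzero)]
  cum <- cumsum(counts[ord])
  n_admit <- which(cum >= fraction * n)[1]
  admitted <- ord[seq_len(n_admit)]
  keep <- cell %in% admitted
  out <- subset_events(events, keep)
  append_gate(out, "contour", n, sum(keep),
              list(channels = channels, fraction = fraction, bins = bins,
                   bins_admitted = n_admit))
}

#' Log-transform fluorescence channels
#'
#' Events with a non-positive intensity in any requested channel are dropped
#' (the drop count is recorded in the gate log; a warning is raised if more
#' than 5% of events are lost), then the channels are log-transformed. The
#' table's log flag is set so downstream noise statistics know the scale.
#' Note the Fano factor is not scale-invariant, so the base matters and is
#' recorded.
#'
#' @param events An `event_table`.
#' @param channels Channels to transform (default GFP and mCherry).
#' @param base Logarithm base (default 10, the cytometry convention).
#' @return The transformed `event_table`.
#' @export
log_transform <- function(events, channels = c("GFP", "mCherry"),
                          base = 10) {
  require_channels(events, channels)
  n <- nrow(events)
  ok <- rep(TRUE, n)
  for (ch in channels) ok <- ok & (events[[ch]] > 0)
  n_drop <- sum(!ok)
  if (n_drop > 0.05 * n)
    warning(sprintf("%d of %d events (%.1f%%) non-positive; dropped",
                    n_drop, n, 100 * n_drop / n))
  out <- subset_events(events, ok)
  for (ch in channels) out[[ch]] <- log(out[[ch]], base = base)
  attr(out, "log_channels") <- union(attr(out, "log_channels"), channels)
  attr(out, "log_base") <- base
  append_gate(out, "log_transform", n, sum(ok),
              list(channels = channels, base = base, n_dropped = n_drop))
}

#' Run the full gating pipeline
#'
#' trigger -> doublet -> contour -> log, in that fixed order.
#'
#' @param events An `event_table`.
#' @param min_fsc Trigger threshold.
#' @param width_quantile FSC-W doublet-gate quantile; `NA` disables the
#'   doublet gate (analysis runs in the source protocol used only the
#'   contour gate).
#' @param fraction Contour-gate fraction.
#' @param bins Contour-gate bins per axis.
#' @param log_base Log base for the fluorescence transform.
#' @return The gated, log-transformed `event_table`.
#' @export
gate_pipeline <- function(events, min_fsc = 2570, width_quantile = 0.90,
                          fraction = 0.80, bins = 64, log_base = 10) {
  out <- trigger_threshold(events, min_fsc)
  if (!is.na(width_quantile)) out <- doublet_gate(out, width_quantile)
  out <- density_contour_gate(out, fraction = fraction, bins = bins)
  log_transform(out, base = log_base)
}

#' Read an event table from CSV
#'
#' @param path CSV file with header columns event_id, FSC_A, FSC_W, SSC_A,
#'   GFP, mCherry and optionally provenance.
#' @return An `event_table`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  expected <- c("event_id", nv_channels)
  unknown <- setdiff(names(df), c(expected, "provenance", "lineage"))
  if (length(unknown) || !all(expected %in% names(df)))
    stop("unexpected event-table header; expected columns: ",
         paste(expected, collapse = ", "),
         " (optional: provenance, lineage)")
  new_event_table(df)
}

#' Write an event table to CSV
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
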