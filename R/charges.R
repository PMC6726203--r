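# Fragment-level aggregation of per-atom population-analysis charges and
# characterization of charge evolution along the reaction coordinate:
# stationary-point tables, extrema, deltas, and per-bond-event charge
# transfer. Charges are in elementary-charge units (a.u.) throughout; the
# population scheme (NPA by convention) is metadata only.

.series_matrix <- function(series) {
  m <- unclass(series)
  attr(m, "scheme") <- NULL
  attr(m, "validation") <- NULL
  as.matrix(m)
}

#' Sum a fragment's charge frame by frame
#'
#' Exact per-frame summation of the atomic charges of a named fragment
#' (e.g. the transferred PO3 group, the metal ion, a side chain); no
#' interpolation or smoothing.
#'
#' @param series a [charge_series] (or bare `n_atoms x n_frames` matrix).
#' @param atoms non-empty vector of 1-based atom indices.
#' @return Numeric vector of per-frame fragment charges, a.u.
#' @export
fragment_charge <- function(series, atoms) {
  m <- .series_matrix(series)
  if (length(atoms) == 0L) stop("fragment must contain at least one atom")
  atoms <- as.integer(atoms)
  if (any(atoms < 1L | atoms > nrow(m))) {
    stop(sprintf("fragment atom index out of range 1..%d", nrow(m)))
  }
  colSums(m[atoms, , drop = FALSE])
}

#' Fragment charge-evolution report
#'
#' Tabulates per-fragment summed charges at each stationary point (the
#' supplementary-table view of a charge analysis), locates each fragment's
#' minimum and maximum along the path, reports the reactant-to-minimum and
#' reactant-to-product deltas, and identifies the monotone segments of each
#' fragment trace from the sign of its finite differences.
#'
#' @param series a [charge_series].
#' @param fragments named list of atom-index vectors.
#' @param stationary_points data frame from [detect_stationary_points()]
#'   (columns `frame`, `kind` used; point labels are built from `kind`).
#' @param xi optional reaction-coordinate values (default frame index).
#' @return Object of class `fragment_charge_report`: list with
#'   `at_stationary` (fragments x points data frame), `extrema`,
#'   `deltas` (both data frames), `segments` (list per fragment),
#'   `traces` (fragments x frames matrix).
#' @export
charge_profile_report <- function(series, fragments, stationary_points,
                                  xi = NULL) {
  m <- .series_matrix(series)
  nf <- ncol(m)
  if (is.null(xi)) xi <- as.numeric(seq_len(nf) - 1L)
  if (is.null(names(fragments)) || any(!nzchar(names(fragments)))) {
    stop("fragments must be a named list")
  }
  traces <- t(vapply(fragments, function(a) fragment_charge(series, a),
                     numeric(nf)))
  rownames(traces) <- names(fragments)
  sp <- as.data.frame(stationary_points)
  lbl <- sp$kind
  for (k in c("ts", "intermediate")) {
    hit <- which(lbl == k)
    if (length(hit) > 1L) lbl[hit] <- paste0(k, seq_along(hit))
  }
  at_stat <- as.data.frame(traces[, sp$frame, drop = FALSE])
  colnames(at_stat) <- lbl
  i_min <- apply(traces, 1L, which.min)
  i_max <- apply(traces, 1L, which.max)
  extrema <- data.frame(
    fragment = rownames(traces),
    xi_min = xi[i_min], q_min = traces[cbind(seq_len(nrow(traces)), i_min)],
    xi_max = xi[i_max], q_max = traces[cbind(seq_len(nrow(traces)), i_max)],
    stringsAsFactors = FALSE)
  deltas <- data.frame(
    fragment = rownames(traces),
    reactant_to_min = extrema$q_min - traces[, 1L],
    reactant_to_product = traces[, nf] - traces[, 1L],
    stringsAsFactors = FALSE)
  segments <- lapply(rownames(traces), function(fr) {
    s <- sign(diff(traces[fr, ]))
    r <- rle(as.vector(s))
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    data.frame(from_frame = starts, to_frame = ends + 1L,
               trend = c("falling", "flat", "rising")[r$values + 2L])
  })
  names(segments) <- rownames(traces)
  structure(list(at_stationary = at_stat, extrema = extrema,
                 deltas = deltas, segments = segments, traces = traces),
            class = "fragment_charge_report")
}

#' @export
print.fragment_charge_report <- function(x, ...) {
  cat("fragment_charge_report\n  charges at stationary points (a.u.):\n")
  print(round(x$at_stationary, 3))
  invisible(x)
}

#' Charge transfer associated with bond events
#'
#' For each bond event, measures the change of every fragment's charge
#' across a window of reaction coordinate centred on the event peak,
#' `[xi_peak - window/2, xi_peak + window/2]`, together with a sign-only
#' summary (gains/loses/unchanged). A window reaching past the ends of the
#' path is clipped with a warning.
#'
#' @param frag_traces `n_fragments x n_frames` matrix of fragment charges
#'   (rownames = fragment names), e.g. the `traces` component of
#'   [charge_profile_report()].
#' @param xi reaction-coordinate values.
#' @param events data frame from [detect_bond_events()].
#' @param window width of the xi window (same units as xi).
#' @param tol |delta| below which a fragment counts as `unchanged`
#'   (default 0.01 a.u.).
#' @return data frame with one row per (event, fragment): `pair`,
#'   `direction`, `xi_peak`, `fragment`, `dq`, `summary`.
#' @export
charge_event_correlation <- function(frag_traces, xi, events, window,
                                     tol = 0.01) {
  frag_traces <- as.matrix(frag_traces)
  if (window <= 0) stop("window must be positive")
  out <- list()
  for (e in seq_len(nrow(events))) {
    lo <- events$xi_peak[e] - window / 2
    hi <- events$xi_peak[e] + window / 2
    if (lo < xi[1L] || hi > xi[length(xi)]) {
      warning(sprintf(
        "event window [%.3f, %.3f] clipped to the path range [%g, %g]",
        lo, hi, xi[1L], xi[length(xi)]), call. = FALSE)
      lo <- max(lo, xi[1L]); hi <- min(hi, xi[length(xi)])
    }
    k_lo <- which(xi >= lo)[1L]
    k_hi <- utils::tail(which(xi <= hi), 1L)
    dq <- frag_traces[, k_hi] - frag_traces[, k_lo]
    out[[e]] <- data.frame(
      pair = events$pair[e], direction = events$direction[e],
      xi_peak = events$xi_peak[e],
      fragment = rownames(frag_traces),
      dq = as.numeric(dq),
      summary = ifelse(abs(dq) < tol, "unchanged",
                       ifelse(dq > 0, "gains charge", "loses charge")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
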