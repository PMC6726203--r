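# Stationary-point analysis of the potential-energy profile and
# associative/dissociative classification of transition states through
# Pauling's bond order-distance relation D(n) = D(1) - 0.60 * log10(n).

#' Pauling fractional bond number at a transition state
#'
#' Quantifies how associative ("tight", phosphorane-like) or dissociative
#' ("loose", metaphosphate-like) a group-transfer transition state is.
#' Given the TS distances from the transferred atom to the leaving group
#' (`d_break`) and to the entering group (`d_form`), the average
#' `Davg = (d_break + d_form)/2` is inserted into Pauling's relation
#' `D(n) = D1 - 0.60 * log10(n)` and solved for the fractional bond number
#' `n = 10^((D1 - Davg)/0.60)`. `100*n` percent is the associative
#' character; its complement the dissociative character.
#'
#' The logarithm is base 10: with the 0.60 coefficient this is the form
#' used for P-O bonds in the phosphoryl-transfer literature, and it is the
#' only base that reproduces published fractional bond numbers from their
#' printed distances. `D1` defaults to 1.73 Angstrom, the P-O single-bond
#' distance; override it for other transferred groups.
#'
#' @param d_break TS distance to the leaving atom, Angstrom.
#' @param d_form TS distance to the entering atom, Angstrom.
#' @param D1 single-bond reference distance, Angstrom (default 1.73, P-O).
#' @return Object of class `pauling_result`: list with `D1`, `d_break`,
#'   `d_form`, `Davg`, `n` (full precision), `pct_assoc`, `pct_dissoc`
#'   (percentages, `pct_assoc = 100*n` clipped to \[0, 100\]).
#' @examples
#' # a loose TS: both partial bonds much longer than a single bond
#' pauling_bond_number(3.04, 2.10)
#' @export
pauling_bond_number <- function(d_break, d_form, D1 = 1.73) {
  if (!is.finite(d_break) || !is.finite(d_form) || !is.finite(D1) ||
      d_break <= 0 || d_form <= 0 || D1 <= 0) {
    stop("domain error: distances must be positive and finite")
  }
  Davg <- (d_break + d_form) / 2
  n <- 10^((D1 - Davg) / 0.60)
  pct_assoc <- min(max(100 * n, 0), 100)
  structure(list(D1 = D1, d_break = d_break, d_form = d_form, Davg = Davg,
                 n = n, pct_assoc = pct_assoc,
                 pct_dissoc = 100 - pct_assoc),
            class = "pauling_result")
}

#' @export
print.pauling_result <- function(x, ...) {
  cat(sprintf("Pauling bond number: Davg = %.2f A (break %.2f, form %.2f; D1 = %.2f)\n",
              x$Davg, x$d_break, x$d_form, x$D1))
  cat(sprintf("  n = %.3f  ->  %.1f%% associative / %.1f%% dissociative\n",
              x$n, x$pct_assoc, x$pct_dissoc))
  invisible(x)
}

# Topographic prominence of the local maximum at position p: height above
# the higher of the two bases, where each base is the minimum encountered
# walking away from p until the profile first exceeds y[p] (or ends).
.peak_prominence <- function(y, p) {
  left <- if (p > 1) {
    seg <- y[(p - 1):1]
    stop_at <- which(seg > y[p])[1L]
    if (!is.na(stop_at)) min(seg[seq_len(stop_at)]) else min(seg)
  } else y[p]
  right <- if (p < length(y)) {
    seg <- y[(p + 1):length(y)]
    stop_at <- which(seg > y[p])[1L]
    if (!is.na(stop_at)) min(seg[seq_len(stop_at)]) else min(seg)
  } else y[p]
  y[p] - max(left, right)
}

# Interior local maxima/minima with plateau handling (a flat stretch is
# treated as a continuation of the preceding trend).
.local_extrema <- function(y) {
  s <- sign(diff(y))
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  n <- length(y)
  idx <- 2:(n - 1L)
  list(maxima = idx[s[idx - 1L] > 0 & s[idx] < 0],
       minima = idx[s[idx - 1L] < 0 & s[idx] > 0])
}

.moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  if (window %% 2L == 0L) stop("smooth_window must be odd")
  sm <- stats::filter(y, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  pad <- (window - 1L) / 2L
  sm[seq_len(pad)] <- y[seq_len(pad)]
  sm[(length(y) - pad + 1L):length(y)] <- y[(length(y) - pad + 1L):length(y)]
  sm
}

#' Detect stationary points on an energy profile
#'
#' Labels the first frame `reactant` and the last `product`; interior local
#' maxima whose topographic prominence is at least `prominence_tol` become
#' `ts` points, and interior local minima lying between two retained `ts`
#' points become `intermediate`s. Reported energies are relative to the
#' reactant frame (raw energies, even when smoothing is used for
#' detection).
#'
#' The default prominence tolerance of 0.5 kcal/mol deliberately keeps
#' sub-kcal features: shallow TS/intermediate gaps of ~1 kcal/mol are
#' mechanistically meaningful in phosphoryl-transfer profiles and must not
#' be smoothed away. For noisy profiles a moving-average pre-smoothing
#' window (odd, in frames) can be supplied; peak positions are then refined
#' by a local quadratic fit so that the reported frame is robust to
#' noise-induced jitter around flat maxima.
#'
#' Adjacent transition states with equal heights (within 1e-8) are both
#' kept and flagged as a `"shoulder pair"` in the `note` column rather than
#' arbitrarily dropping one: on a potential-energy surface the distinction
#' can be below the method's resolution.
#'
#' @param energies numeric vector of per-frame energies, kcal/mol.
#' @param xi optional reaction-coordinate values (default frame index
#'   `0..n-1`).
#' @param prominence_tol minimum peak prominence in kcal/mol (default 0.5).
#' @param smooth_window odd moving-average window in frames (default 1 =
#'   no smoothing).
#' @return data frame with columns `frame` (1-based), `xi`, `kind`
#'   (`reactant`/`ts`/`intermediate`/`product`), `rel_energy` (kcal/mol,
#'   reactant = 0) and `note`.
#' @export
detect_stationary_points <- function(energies, xi = NULL,
                                     prominence_tol = 0.5,
                                     smooth_window = 1) {
  n <- length(energies)
  if (n < 3L) stop("insufficient data: need at least 3 frames")
  if (any(!is.finite(energies))) stop("energies must be finite")
  if (is.null(xi)) xi <- as.numeric(seq_len(n) - 1L)
  if (length(xi) != n || any(diff(xi) <= 0)) {
    stop("xi must be strictly increasing and match the energies")
  }
  es <- .moving_average(energies, smooth_window)
  ext <- .local_extrema(es)
  prom <- vapply(ext$maxima, function(p) .peak_prominence(es, p), numeric(1L))
  ts_idx <- ext$maxima[prom >= prominence_tol]
  # refine each peak by a quadratic vertex fit over the smoothing window
  if (smooth_window > 1L && length(ts_idx)) {
    half <- max(2L, (smooth_window - 1L) %/% 2L)
    ts_idx <- vapply(ts_idx, function(p) {
      lo <- max(2L, p - half); hi <- min(n - 1L, p + half)
      w <- lo:hi
      fit <- stats::lm.fit(cbind(1, w, w^2), es[w])
      b <- fit$coefficients
      if (is.finite(b[3L]) && b[3L] < 0) {
        v <- round(-b[2L] / (2 * b[3L]))
        if (v >= lo && v <= hi) p <- as.integer(v)
      }
      p
    }, integer(1L))
    ts_idx <- sort(unique(ts_idx))
  }
  int_idx <- integer(0)
  if (length(ts_idx) >= 2L) {
    for (k in seq_len(length(ts_idx) - 1L)) {
      between <- ext$minima[ext$minima > ts_idx[k] & ext$minima < ts_idx[k + 1L]]
      if (length(between)) {
        int_idx <- c(int_idx, between[which.min(es[between])])
      }
    }
  }
  frames <- c(1L, ts_idx, int_idx, n)
  kinds <- c("reactant", rep("ts", length(ts_idx)),
             rep("intermediate", length(int_idx)), "product")
  ord <- order(frames)
  frames <- frames[ord]; kinds <- kinds[ord]
  note <- rep("", length(frames))
  ts_pos <- which(kinds == "ts")
  if (length(ts_pos) >= 2L) {
    for (k in seq_len(length(ts_pos) - 1L)) {
      a <- ts_pos[k]; b <- ts_pos[k + 1L]
      if (abs(es[frames[a]] - es[frames[b]]) < 1e-8) {
        note[c(a, b)] <- "shoulder pair"
      }
    }
  }
  data.frame(frame = frames, xi = xi[frames], kind = kinds,
             rel_energy = energies[frames] - energies[1L],
             note = note, stringsAsFactors = FALSE)
}

#' Classify a group-transfer mechanism from a reaction path
#'
#' End-to-end mechanism characterization: detects the stationary points of
#' the energy profile, labels the pathway `concerted` (one TS), `stepwise`
#' (two or more TSs flanking at least one intermediate) or `none`
#' (barrierless profile with no interior maximum), and evaluates Pauling's
#' fractional bond number at every TS from the frame distances
#' d(donorO, P) and d(P, acceptorO).
#'
#' Each intermediate is additionally tested for metaphosphate character:
#' when a bond-order series is supplied the flag is true iff both
#' B(donorO, P) and B(P, acceptorO) are below 0.5 at the intermediate frame;
#' without bond orders a geometric heuristic is used instead (both P-O
#' distances longer than `D1 + 0.60` Angstrom, i.e. bond number below 0.1).
#'
#' @param path a [reaction_path] (geometry source).
#' @param energies per-frame energies in kcal/mol; defaults to
#'   `path$energy`.
#' @param donorO,P,acceptorO atom indices of the reactive triad (leaving
#'   oxygen, transferred phosphorus, entering oxygen).
#' @param bond_orders optional [bond_order_series] containing the
#'   (donorO, P) and (P, acceptorO) pairs, used for the metaphosphate test.
#' @param D1 single-bond reference distance for [pauling_bond_number()].
#' @param prominence_tol,smooth_window passed to
#'   [detect_stationary_points()].
#' @return Object of class `mechanism_report`: list with
#'   `stationary_points` (data frame), `pathway_class`, `character`
#'   (`associative`/`dissociative`, from the mean TS associative
#'   percentage, `NA` when there is no TS), `pauling` (list of
#'   [pauling_bond_number()] results, one per TS), `barrier`,
#'   `reaction_energy` (kcal/mol), `metaphosphate_flag` (logical per
#'   intermediate).
#' @export
classify_mechanism <- function(path, energies = NULL, donorO, P, acceptorO,
                               bond_orders = NULL, D1 = 1.73,
                               prominence_tol = 0.5, smooth_window = 1) {
  if (is.null(energies)) energies <- path$energy
  if (is.null(energies)) stop("no energies available on this path")
  nat <- nrow(path$atoms)
  for (a in c(donorO, P, acceptorO)) .check_atom_index(a, nat)
  if (length(unique(c(donorO, P, acceptorO))) != 3L) {
    stop("reactive triad indices must be distinct")
  }
  sp <- detect_stationary_points(energies, xi = path$xi,
                                 prominence_tol = prominence_tol,
                                 smooth_window = smooth_window)
  ts_rows <- which(sp$kind == "ts")
  int_rows <- which(sp$kind == "intermediate")
  pauling <- lapply(ts_rows, function(r) {
    m <- frame_coords(path, sp$frame[r])
    pauling_bond_number(atom_distance(m, donorO, P),
                        atom_distance(m, P, acceptorO), D1 = D1)
  })
  names(pauling) <- if (length(ts_rows)) paste0("TS", seq_along(ts_rows))
  pathway_class <- if (length(ts_rows) == 0L) "none"
    else if (length(ts_rows) == 1L) "concerted"
    else "stepwise"
  character_lbl <- NA_character_
  if (length(pauling)) {
    mean_assoc <- mean(vapply(pauling, `[[`, numeric(1L), "pct_assoc"))
    character_lbl <- if (mean_assoc > 50) "associative" else "dissociative"
  }
  meta_flag <- vapply(int_rows, function(r) {
    f <- sp$frame[r]
    if (!is.null(bond_orders)) {
      pair_orders(bond_orders, donorO, P)[f] < 0.5 &&
        pair_orders(bond_orders, P, acceptorO)[f] < 0.5
    } else {
      m <- frame_coords(path, f)
      atom_distance(m, donorO, P) > D1 + 0.60 &&
        atom_distance(m, P, acceptorO) > D1 + 0.60
    }
  }, logical(1L))
  structure(list(
    stationary_points = sp,
    pathway_class = pathway_class,
    character = character_lbl,
    pauling = pauling,
    barrier = if (length(ts_rows)) max(sp$rel_energy[ts_rows]) else NA_real_,
    reaction_energy = sp$rel_energy[nrow(sp)],
    metaphosphate_flag = meta_flag),
    class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(sprintf("mechanism_report: %s", x$pathway_class))
  if (!is.na(x$character)) cat(sprintf(", %s", x$character))
  cat("\n")
  if (is.finite(x$barrier)) {
    cat(sprintf("  barrier %.1f kcal/mol, reaction energy %.1f kcal/mol\n",
                x$barrier, x$reaction_energy))
  } else {
    cat(sprintf("  no barrier; reaction energy %.1f kcal/mol\n",
                x$reaction_energy))
  }
  print(x$stationary_points)
  for (nm in names(x$pauling)) {
    cat(nm, ": ", sep = "")
    cat(sprintf("n = %.3f (%.1f%% dissociative)\n",
                x$pauling[[nm]]$n, x$pauling[[nm]]$pct_dissoc))
  }
  invisible(x)
}
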