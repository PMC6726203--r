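# Per-frame geometric measurements: distances, angles, metal coordination,
# hydrogen bonds, and stationary-point distance tables. A "frame" is the
# n_atoms x 3 coordinate matrix returned by frame_coords(); all lengths in
# Angstrom, all angles in degrees.

.check_atom_index <- function(i, n, what = "atom index") {
  if (!.is_count(i) || i < 1 || i > n) {
    stop(sprintf("%s %s out of range 1..%d", what, format(i), n))
  }
}

#' Interatomic distance in one frame
#'
#' Euclidean distance between two atoms, symmetric in `(i, j)`. `i == j` is
#' permitted and returns 0 (callers flag self-distances in reports).
#'
#' @param frame `n_atoms x 3` coordinate matrix (see [frame_coords()]).
#' @param i,j atom indices.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(frame, i, j) {
  n <- nrow(frame)
  .check_atom_index(i, n); .check_atom_index(j, n)
  sqrt(sum((frame[i, ] - frame[j, ])^2))
}

#' Bond angle in one frame
#'
#' Angle at apex atom `j` formed by atoms `i`-`j`-`k`, in degrees within
#' \[0, 180\]. Used e.g. for the in-line attack angle donor-P-acceptor of a
#' phosphoryl transfer.
#'
#' @inheritParams atom_distance
#' @param k third atom index; `i`, `j`, `k` must be distinct.
#' @return Angle in degrees.
#' @export
atom_angle <- function(frame, i, j, k) {
  n <- nrow(frame)
  .check_atom_index(i, n); .check_atom_index(j, n); .check_atom_index(k, n)
  if (length(unique(c(i, j, k))) != 3L) stop("atoms i, j, k must be distinct")
  v1 <- frame[i, ] - frame[j, ]
  v2 <- frame[k, ] - frame[j, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-10 || n2 < 1e-10) {
    stop("undefined geometry: coincident points in angle()")
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Metal coordination profile along a path
#'
#' Tracks the coordination shell of a metal center (e.g. the active-site
#' Mg2+) frame by frame: a candidate ligand counts toward the coordination
#' number iff its distance to the metal is at or below `cutoff`; all
#' distances are reported regardless of the cutoff so partial decoordination
#' (a contact drifting past the cutoff) remains visible.
#'
#' The default cutoff of 2.6 Angstrom keeps typical conserved Mg-O contacts
#' (~1.9-2.4 A) in the shell while excluding contacts that have drifted to
#' ~3 A and beyond.
#'
#' @param path a [reaction_path].
#' @param metal atom index of the metal center.
#' @param ligands non-empty vector of candidate ligand atom indices.
#' @param cutoff coordination cutoff in Angstrom (default 2.6).
#' @return Object of class `coordination_profile`: list with `distances`
#'   (`n_frames x n_ligands` matrix), `coordination` (integer per frame),
#'   `cutoff`, `metal`, `ligands`.
#' @export
coordination_profile <- function(path, metal, ligands, cutoff = 2.6) {
  if (length(ligands) == 0L) stop("ligand list must be non-empty")
  if (cutoff <= 0) stop("cutoff must be > 0")
  nat <- nrow(path$atoms)
  .check_atom_index(metal, nat, "metal index")
  for (l in ligands) .check_atom_index(l, nat, "ligand index")
  nf <- n_frames(path)
  d <- matrix(NA_real_, nf, length(ligands),
              dimnames = list(NULL, path$atoms$name[ligands]))
  for (f in seq_len(nf)) {
    m <- frame_coords(path, f)
    d[f, ] <- sqrt(colSums((t(m[ligands, , drop = FALSE]) - m[metal, ])^2))
  }
  structure(list(distances = d,
                 coordination = as.integer(rowSums(d <= cutoff)),
                 cutoff = cutoff, metal = metal, ligands = ligands),
            class = "coordination_profile")
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf("coordination_profile: metal atom %d, %d ligands, cutoff %.2f A\n",
              x$metal, length(x$ligands), x$cutoff))
  cat(sprintf("  coordination number: %d (first frame) -> %d (last frame)\n",
              x$coordination[1], x$coordination[length(x$coordination)]))
  invisible(x)
}

#' Hydrogen-bond geometric criteria
#'
#' Container for the two geometric thresholds of a donor-H...acceptor
#' contact. The defaults (donor-acceptor distance <= 3.5 Angstrom,
#' D-H...A angle >= 120 degrees) are common structural-biology criteria;
#' both are configurable since there is no single community standard.
#'
#' @param d_da_max maximum donor-acceptor distance, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees, in (0, 180].
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_da_max = 3.5, angle_min = 120) {
  if (d_da_max <= 0) stop("d_da_max must be > 0")
  if (angle_min <= 0 || angle_min > 180) stop("angle_min must be in (0, 180]")
  structure(list(d_da_max = d_da_max, angle_min = angle_min),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in one frame
#'
#' Reports a donor-H...acceptor contact iff the donor-acceptor distance is
#' at most `criteria$d_da_max` and the D-H...A angle (apex at H) is at least
#' `criteria$angle_min`. Donor pairs whose D-H distance exceeds 1.3 Angstrom
#' are not covalently bonded and are skipped with a warning.
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param donors 2-column matrix of (donor heavy atom, hydrogen) index pairs.
#' @param acceptors vector of acceptor atom indices.
#' @param criteria an [hbond_criteria()].
#' @return data frame with columns `donor`, `h`, `acceptor`, `d_da`,
#'   `angle`, sorted by `d_da`.
#' @export
hbond_detect <- function(frame, donors, acceptors,
                         criteria = hbond_criteria()) {
  donors <- matrix(as.integer(as.matrix(donors)), ncol = 2L)
  out <- data.frame(donor = integer(0), h = integer(0), acceptor = integer(0),
                    d_da = numeric(0), angle = numeric(0))
  for (r in seq_len(nrow(donors))) {
    d_at <- donors[r, 1L]; h_at <- donors[r, 2L]
    if (atom_distance(frame, d_at, h_at) >= 1.3) {
      warning(sprintf("donor pair (%d,%d) is not D-H bonded (d >= 1.3 A); skipped",
                      d_at, h_at), call. = FALSE)
      next
    }
    for (a in acceptors) {
      if (a == d_at || a == h_at) next
      d_da <- atom_distance(frame, d_at, a)
      if (d_da > criteria$d_da_max) next
      ang <- atom_angle(frame, d_at, h_at, a)
      if (ang < criteria$angle_min) next
      out <- rbind(out, data.frame(donor = d_at, h = h_at, acceptor = a,
                                   d_da = d_da, angle = ang))
    }
  }
  out[order(out$d_da), , drop = FALSE]
}

#' Key-distance table at named stationary points
#'
#' Tabulates a set of labelled atom-pair distances at selected frames
#' (typically the stationary points found by [detect_stationary_points()]),
#' producing the classic reactant/TS/product distance table of a mechanism
#' study. Values are rounded to 2 decimals for display; the full-precision
#' table is kept in the `"full"` attribute.
#'
#' @param path a [reaction_path].
#' @param specs data frame with columns `label`, `i`, `j` (one row per
#'   distance); may be empty.
#' @param at_frames named vector of 1-based frame numbers; names become the
#'   table's columns (e.g. `c(Reac = 1, TS = 40, Prod = 101)`).
#' @return data frame, rows = `specs$label`, columns = stationary-point
#'   names, distances in Angstrom to 2 decimals.
#' @export
key_distance_table <- function(path, specs, at_frames) {
  specs <- as.data.frame(specs)
  pts <- names(at_frames)
  if (is.null(pts) || any(!nzchar(pts))) {
    pts <- paste0("frame", at_frames)
  }
  full <- matrix(NA_real_, nrow(specs), length(at_frames),
                 dimnames = list(specs$label, pts))
  for (ci in seq_along(at_frames)) {
    m <- frame_coords(path, at_frames[[ci]])
    for (ri in seq_len(nrow(specs))) {
      full[ri, ci] <- atom_distance(m, specs$i[ri], specs$j[ri])
    }
  }
  out <- as.data.frame(round(full, 2))
  attr(out, "full") <- full
  out
}
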