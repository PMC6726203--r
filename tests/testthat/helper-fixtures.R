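# Shared fixture builders: everything is generated in code at test time.

# quick reaction_path from a list of n_atoms x 3 coordinate matrices
make_path <- function(coords_list, elements = NULL, energy = NULL, xi = NULL) {
  nat <- nrow(coords_list[[1L]])
  if (is.null(elements)) elements <- rep("C", nat)
  atoms <- data.frame(index = seq_len(nat), element = elements,
                      name = paste0(elements, seq_len(nat)),
                      residue = NA_character_, stringsAsFactors = FALSE)
  arr <- array(unlist(coords_list), dim = c(nat, 3L, length(coords_list)))
  reaction_path(atoms, arr, energy = energy, xi = xi)
}

# multi-frame XYZ text from a list of coordinate matrices
make_xyz_text <- function(coords_list, elements, energies = NULL) {
  out <- character(0)
  for (f in seq_along(coords_list)) {
    m <- coords_list[[f]]
    comment <- sprintf("frame %d", f - 1L)
    if (!is.null(energies)) comment <- sprintf("%s energy=%.4f", comment,
                                               energies[f])
    out <- c(out, nrow(m), comment,
             sprintf("%s %12.6f %12.6f %12.6f", elements, m[, 1], m[, 2], m[, 3]))
  }
  paste(out, collapse = "\n")
}

# NBO-dialect Wiberg block text for a symmetric matrix
make_wiberg_text <- function(m, elements = NULL, chunk_size = 8L) {
  n <- nrow(m)
  if (is.null(elements)) elements <- rep("X", n)
  out <- c(" Wiberg bond index matrix in the NAO basis:", "")
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    cols <- s:min(s + chunk_size - 1L, n)
    out <- c(out,
             paste0("         Atom ", paste(sprintf("%7d", cols), collapse = " ")),
             paste0("         ---- ", paste(rep("-------", length(cols)),
                                            collapse = " ")))
    for (r in seq_len(n)) {
      out <- c(out, sprintf("     %2d.  %-2s %s", r, elements[r],
                            paste(sprintf("%7.4f", m[r, cols]), collapse = " ")))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

# uniformly random proper rotation matrix
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

logistic_curve <- function(xi, B0, B1, mu, s) {
  B0 + (B1 - B0) * stats::plogis((xi - mu) / s)
}

# zero-slope piecewise-cubic through stationary targets (independent
# re-implementation of the profile model, for building energy fixtures)
hermite_profile <- function(x, xp, yp) {
  idx <- findInterval(x, xp, all.inside = TRUE)
  t <- pmin(1, pmax(0, (x - xp[idx]) / (xp[idx + 1L] - xp[idx])))
  yp[idx] + (yp[idx + 1L] - yp[idx]) * (3 * t^2 - 2 * t^3)
}

# trapezoidal integral (oracle for the derivative-integral closure checks)
trapz_int <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
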