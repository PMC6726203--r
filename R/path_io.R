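# Reading/writing of reaction-path data: multi-frame XYZ, long-format CSV
# bond-order and charge tables, PDB atom tables, NBO Wiberg text blocks,
# and JSON/CSV reports. All readers normalize into the internal data model:
#   reaction_path      atoms + coords[n_atoms, 3, n_frames] + energy + xi
#   bond_order_series  pairs[n_pairs, 2] + values[n_pairs, n_frames]
#   charge_series      values[n_atoms, n_frames]
# Atom indices are 1-based everywhere inside the package (XYZ/PDB convention);
# the CSV dialects label frames 0-based externally and are remapped on read.

# ---- internal helpers -------------------------------------------------------

# Accept a file path, a connection, a single string with embedded newlines,
# or an already-split character vector of lines.
.as_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !nzchar(x)) return(character(0))
  if (is.character(x) && length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  if (is.character(x) && length(x) > 1L) return(x)
  readLines(x, warn = FALSE)
}

.read_table_any <- function(x) {
  if (is.character(x) && (length(x) > 1L || grepl("\n", x, fixed = TRUE))) {
    return(utils::read.csv(text = paste(.as_lines(x), collapse = "\n"),
                           strip.white = TRUE))
  }
  utils::read.csv(x, strip.white = TRUE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# ---- reaction_path ----------------------------------------------------------

#' Construct a reaction path
#'
#' Bundles an atom table, per-frame Cartesian coordinates, optional per-frame
#' energies and a scalar reaction-coordinate value per frame into a validated
#' `reaction_path` object, the container consumed by all analysis functions.
#'
#' @param atoms data frame with columns `index` (1..N, contiguous), `element`
#'   (chemical symbol), `name` (free-text atom label) and optionally
#'   `residue`.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, in
#'   Angstrom.
#' @param energy optional numeric vector of per-frame energies in kcal/mol
#'   (`NA` allowed for frames without an energy).
#' @param xi per-frame scalar reaction-coordinate values, strictly
#'   increasing. Defaults to `0, 1, ..., n_frames - 1` (frame index), since
#'   IRC outputs do not always carry an arc-length column.
#' @param meta named list of provenance strings.
#'
#' @return An object of class `reaction_path` with elements `atoms`,
#'   `coords`, `energy`, `xi`, `meta`.
#' @seealso [read_xyz_path()], [generate_path()]
#' @export
reaction_path <- function(atoms, coords, energy = NULL, xi = NULL,
                          meta = list()) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("index", "element", "name") %in% names(atoms)))
  if (is.null(atoms$residue)) atoms$residue <- NA_character_
  n_atoms <- nrow(atoms)
  if (!identical(as.integer(atoms$index), seq_len(n_atoms))) {
    stop("atom indices must be unique and contiguous from 1..N")
  }
  if (length(dim(coords)) != 3L || dim(coords)[1] != n_atoms ||
      dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  n_frames <- dim(coords)[3]
  if (n_frames < 2L) stop("a reaction path needs at least 2 frames")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(xi)) xi <- as.numeric(seq_len(n_frames) - 1L)
  if (length(xi) != n_frames) stop("length(xi) must equal the frame count")
  if (any(diff(xi) <= 0)) stop("xi must be strictly increasing")
  if (!is.null(energy)) {
    if (length(energy) != n_frames) {
      stop("length(energy) must equal the frame count")
    }
    energy <- as.numeric(energy)
  }
  structure(list(atoms = atoms, coords = coords, energy = energy,
                 xi = as.numeric(xi), meta = meta),
            class = "reaction_path")
}

#' @export
print.reaction_path <- function(x, ...) {
  cat(sprintf("reaction_path: %d atoms, %d frames, xi in [%g, %g]\n",
              nrow(x$atoms), n_frames(x), x$xi[1], x$xi[length(x$xi)]))
  if (!is.null(x$energy) && any(is.finite(x$energy))) {
    cat(sprintf("  energies: %d/%d frames, range [%.3f, %.3f] kcal/mol\n",
                sum(is.finite(x$energy)), n_frames(x),
                min(x$energy, na.rm = TRUE), max(x$energy, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of frames in a reaction path
#' @param path a `reaction_path`.
#' @return Integer frame count.
#' @export
n_frames <- function(path) dim(path$coords)[3]

#' Extract one frame's coordinate matrix
#' @param path a `reaction_path`.
#' @param frame 1-based frame number.
#' @return `n_atoms x 3` numeric matrix (Angstrom), rownames = atom names.
#' @export
frame_coords <- function(path, frame) {
  if (!.is_count(frame) || frame < 1 || frame > n_frames(path)) {
    stop(sprintf("frame %s out of range 1..%d", format(frame), n_frames(path)))
  }
  m <- path$coords[, , frame, drop = TRUE]
  dim(m) <- c(nrow(path$atoms), 3L)
  rownames(m) <- path$atoms$name
  m
}

#' Read a multi-frame XYZ reaction path
#'
#' Parses concatenated standard-XYZ frames. The comment line of each frame
#' may carry an `energy=<value>` token, interpreted as kcal/mol. Frames are
#' kept in file order; the reaction coordinate defaults to the frame index
#' `0..n-1` unless `xi` is supplied (e.g. from a sidecar CSV of IRC arc
#' lengths).
#'
#' @param file path, connection, or character text of the XYZ stream.
#' @param xi optional numeric vector overriding the reaction coordinate.
#' @param energy_unit `"kcal/mol"` (default) or `"hartree"`; Hartree inputs
#'   are converted with 627.5095 kcal/mol per Hartree.
#' @return A [reaction_path].
#' @export
read_xyz_path <- function(file, xi = NULL,
                          energy_unit = c("kcal/mol", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  lines <- .as_lines(file)
  i <- 1L
  n_lines <- length(lines)
  coords_list <- list()
  energies <- numeric(0)
  elements <- NULL
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_no <- length(coords_list) + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("XYZ format error at line %d: expected an atom count, got '%s'",
                   i, trimws(lines[i])))
    }
    if (!is.null(elements) && nat != length(elements)) {
      stop(sprintf(
        "XYZ format error: frame %d declares %d atoms but frame 1 had %d",
        frame_no, nat, length(elements)))
    }
    if (i + 1L + nat > n_lines) {
      stop(sprintf("XYZ format error: frame %d truncated (needs %d atom lines)",
                   frame_no, nat))
    }
    comment <- lines[i + 1L]
    e <- NA_real_
    m <- regmatches(comment,
                    regexec("energy\\s*=\\s*([-+]?[0-9.]+([eEdD][-+]?[0-9]+)?)",
                            comment))[[1L]]
    if (length(m) >= 2L) e <- as.numeric(sub("[dD]", "e", m[2L]))
    block <- lines[(i + 2L):(i + 1L + nat)]
    els <- character(nat)
    xyz <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      fields <- strsplit(trimws(block[k]), "[[:space:]]+")[[1L]]
      if (length(fields) < 4L) {
        stop(sprintf("XYZ parse error at line %d: expected 'element x y z'",
                     i + 1L + k))
      }
      vals <- suppressWarnings(as.numeric(fields[2:4]))
      if (any(is.na(vals))) {
        stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                     i + 1L + k))
      }
      els[k] <- fields[1L]
      xyz[k, ] <- vals
    }
    if (is.null(elements)) elements <- els
    coords_list[[frame_no]] <- xyz
    energies[frame_no] <- e
    i <- i + 2L + nat
  }
  if (length(coords_list) < 2L) {
    stop("XYZ stream must contain at least 2 frames")
  }
  nf <- length(coords_list)
  arr <- array(unlist(coords_list), dim = c(length(elements), 3L, nf))
  energy <- if (all(is.na(energies))) NULL else energies
  if (!is.null(energy) && energy_unit == "hartree") {
    energy <- energy * 627.5095
  }
  atoms <- data.frame(index = seq_along(elements), element = elements,
                      name = paste0(elements, seq_along(elements)),
                      residue = NA_character_, stringsAsFactors = FALSE)
  reaction_path(atoms, arr, energy = energy, xi = xi,
                meta = list(source = "xyz"))
}

#' Write a reaction path as multi-frame XYZ
#'
#' Inverse of [read_xyz_path()]: energies, when present, are emitted as
#' `energy=<value>` tokens on the comment line so a write/read round trip is
#' the identity up to the printed precision.
#'
#' @param path a [reaction_path].
#' @param file output path or connection.
#' @param digits printed coordinate precision (default 6 decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz_path <- function(path, file, digits = 6) {
  nf <- n_frames(path)
  nat <- nrow(path$atoms)
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 5L, digits, digits + 5L, digits, digits + 5L, digits)
  out <- character(0)
  for (f in seq_len(nf)) {
    e <- if (!is.null(path$energy)) path$energy[f] else NA_real_
    comment <- sprintf("frame %d", f - 1L)
    if (is.finite(e)) comment <- sprintf("%s energy=%.6f", comment, e)
    m <- frame_coords(path, f)
    body <- sprintf(fmt, path$atoms$element, m[, 1], m[, 2], m[, 3])
    out <- c(out, as.character(nat), comment, body)
  }
  writeLines(out, file)
  invisible(path)
}

# ---- bond_order_series ------------------------------------------------------

#' Construct a bond-order series
#'
#' Per-frame Wiberg bond orders for a selection of atom pairs. Pairs are
#' canonicalized to `i < j`; values must be non-negative.
#'
#' @param pairs 2-column integer matrix (or data frame) of atom-index pairs.
#' @param values numeric matrix, `n_pairs x n_frames`.
#' @return Object of class `bond_order_series` with elements `pairs`
#'   (canonical `i < j`) and `values` (rownames `"i-j"`).
#' @export
bond_order_series <- function(pairs, values) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (any(pairs[, 1] == pairs[, 2])) stop("a bond pair needs two distinct atoms")
  flip <- pairs[, 1] > pairs[, 2]
  pairs[flip, ] <- pairs[flip, 2:1]
  values <- as.matrix(values)
  if (nrow(values) != nrow(pairs)) {
    stop("values must have one row per pair")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("bond orders must be finite and >= 0")
  }
  key <- paste0(pairs[, 1], "-", pairs[, 2])
  if (anyDuplicated(key)) stop("duplicate atom pair after canonicalization")
  dimnames(pairs) <- list(key, c("i", "j"))
  rownames(values) <- key
  structure(list(pairs = pairs, values = values),
            class = "bond_order_series")
}

#' @export
print.bond_order_series <- function(x, ...) {
  cat(sprintf("bond_order_series: %d pairs x %d frames\n",
              nrow(x$pairs), ncol(x$values)))
  cat("  pairs:", paste(rownames(x$pairs), collapse = ", "), "\n")
  invisible(x)
}

#' Look up one pair's bond-order trajectory
#' @param series a [bond_order_series].
#' @param i,j atom indices (order irrelevant).
#' @return Numeric vector over frames.
#' @export
pair_orders <- function(series, i, j) {
  key <- paste0(min(i, j), "-", max(i, j))
  if (!key %in% rownames(x = series$values)) {
    stop(sprintf("pair (%d,%d) not present in the series", i, j))
  }
  series$values[key, ]
}

#' Read a long-format bond-order table
#'
#' Canonical CSV dialect with header `frame,i,j,order`: one row per
#' (frame, atom pair), frames labelled 0-based. Every pair must be present
#' at every frame (no silent interpolation); pairs are stored under the
#' canonical `i < j` ordering.
#'
#' @param file path, connection, or CSV text.
#' @return A [bond_order_series] with frames in ascending frame-label order.
#' @export
read_bond_orders <- function(file) {
  df <- .read_table_any(file)
  need <- c("frame", "i", "j", "order")
  if (!all(need %in% names(df))) {
    stop("bond-order table must have columns frame,i,j,order")
  }
  if (any(!is.finite(df$order)) || any(df$order < 0)) {
    bad <- which(!is.finite(df$order) | df$order < 0)[1L]
    stop(sprintf("validation error: negative or non-finite bond order in row %d",
                 bad))
  }
  ii <- pmin(df$i, df$j)
  jj <- pmax(df$i, df$j)
  if (any(ii == jj)) stop("validation error: pair with i == j")
  key <- paste0(ii, "-", jj)
  fkey <- paste(df$frame, key)
  if (anyDuplicated(fkey)) {
    stop(sprintf("validation error: duplicate (frame,i,j) row: %s",
                 fkey[duplicated(fkey)][1L]))
  }
  frames <- sort(unique(df$frame))
  pairs_u <- unique(cbind(ii, jj))
  pairs_u <- pairs_u[order(pairs_u[, 1], pairs_u[, 2]), , drop = FALSE]
  key_u <- paste0(pairs_u[, 1], "-", pairs_u[, 2])
  vals <- matrix(NA_real_, nrow(pairs_u), length(frames),
                 dimnames = list(key_u, frames))
  vals[cbind(match(key, key_u), match(df$frame, frames))] <- df$order
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing bond-order cell: pair %s at frame %s",
                 key_u[miss[1L]], frames[miss[2L]]))
  }
  bond_order_series(pairs_u, vals)
}

#' Write a bond-order series as the canonical long CSV
#' @param series a [bond_order_series].
#' @param file output path or connection.
#' @return `series`, invisibly.
#' @export
write_bond_orders <- function(series, file) {
  nfr <- ncol(series$values)
  df <- data.frame(
    frame = rep(seq_len(nfr) - 1L, each = nrow(series$pairs)),
    i = rep(series$pairs[, 1], nfr),
    j = rep(series$pairs[, 2], nfr),
    order = as.vector(series$values))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(series)
}

# ---- Wiberg text block ------------------------------------------------------

#' Parse a Wiberg bond index matrix text block
#'
#' Reads the `Wiberg bond index matrix` block emitted by the standard NBO
#' program dialect: the full symmetric matrix printed in chunks of at most
#' nine columns, each chunk headed by a row of column numbers under an
#' `Atom` label, with atom rows of the form `"  1. P   0.0000 ..."`.
#' A frozen example of the dialect ships in
#' `system.file("extdata", "wiberg_block_example.txt", package = "ircmech")`.
#'
#' @param file path, connection, or text of the log fragment.
#' @param frame_index 0-based frame label to attach to the result.
#' @return The full symmetric `n_atoms x n_atoms` bond-order matrix
#'   (diagonal zeroed), with attribute `frame_index`.
#' @seealso [wiberg_to_series()] to extract selected pairs.
#' @export
parse_wiberg_block <- function(file, frame_index = 0L) {
  lines <- .as_lines(file)
  start <- grep("Wiberg bond index matrix", lines)
  if (length(start) == 0L) {
    stop("parse error: no 'Wiberg bond index matrix' block found")
  }
  lines <- lines[(start[1L] + 1L):length(lines)]
  atom_re <- "^\\s*([0-9]+)\\.\\s+\\S+\\s+(.*)$"
  header_re <- "^\\s*Atom\\s+[0-9]"
  entries <- list()   # per chunk: list(cols, rows(list idx -> numeric))
  chunk <- NULL
  for (ln in lines) {
    if (grepl(header_re, ln)) {
      if (!is.null(chunk)) entries[[length(entries) + 1L]] <- chunk
      cols <- as.integer(strsplit(trimws(sub("^\\s*Atom", "", ln)),
                                  "[[:space:]]+")[[1L]])
      chunk <- list(cols = cols, rows = list())
    } else if (grepl(atom_re, ln) && !is.null(chunk)) {
      m <- regmatches(ln, regexec(atom_re, ln))[[1L]]
      idx <- as.integer(m[2L])
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(m[3L]), "[[:space:]]+")[[1L]]))
      if (anyNA(vals)) next  # not a data row (e.g. dashes)
      chunk$rows[[as.character(idx)]] <- vals
    } else if (!is.null(chunk) && !nzchar(trimws(ln)) &&
               length(chunk$rows) > 0L) {
      entries[[length(entries) + 1L]] <- chunk
      chunk <- NULL
    }
  }
  if (!is.null(chunk)) entries[[length(entries) + 1L]] <- chunk
  entries <- Filter(function(ch) length(ch$rows) > 0L, entries)
  if (length(entries) == 0L) stop("parse error: empty Wiberg block")
  n <- max(vapply(entries, function(ch) max(as.integer(names(ch$rows))),
                  integer(1L)))
  mat <- matrix(NA_real_, n, n)
  for (ch in entries) {
    for (nm in names(ch$rows)) {
      vals <- ch$rows[[nm]]
      if (length(vals) != length(ch$cols)) {
        stop(sprintf(
          "parse error: truncated Wiberg block: atom %s row has %d values, expected %d columns",
          nm, length(vals), length(ch$cols)))
      }
      mat[as.integer(nm), ch$cols] <- vals
    }
  }
  if (anyNA(mat)) {
    stop("parse error: truncated Wiberg block: matrix not fully covered by column chunks")
  }
  if (max(abs(mat - t(mat))) > 1e-4) {
    stop("parse error: Wiberg matrix is not symmetric")
  }
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  if (any(mat < 0)) stop("parse error: negative Wiberg bond index")
  attr(mat, "frame_index") <- as.integer(frame_index)
  mat
}

#' Extract selected pairs of a Wiberg matrix as a one-frame series fragment
#' @param mat symmetric matrix from [parse_wiberg_block()].
#' @param pairs 2-column matrix of atom-index pairs.
#' @return A one-frame [bond_order_series].
#' @export
wiberg_to_series <- function(mat, pairs) {
  pairs <- as.matrix(pairs)
  vals <- matrix(mat[pairs], ncol = 1L)
  bond_order_series(pairs, vals)
}

# ---- charge_series ----------------------------------------------------------

#' Construct an atomic-charge series
#'
#' Per-atom, per-frame partial charges in elementary-charge units. The
#' population scheme (NPA by convention) is carried as metadata only. The
#' per-frame total charge is validated to be constant within
#' `charge_sum_tol`; drift beyond the tolerance raises a warning that is
#' also recorded in the object's `validation` attribute so downstream
#' reports can surface it.
#'
#' @param values numeric matrix, `n_atoms x n_frames`, in a.u.
#' @param scheme population-analysis scheme label (metadata).
#' @param charge_sum_tol allowed drift of the per-frame total charge (a.u.).
#' @return Object of class `charge_series` (a matrix with attributes
#'   `scheme` and `validation`).
#' @export
charge_series <- function(values, scheme = "NPA", charge_sum_tol = 0.01) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("charges must be finite")
  sums <- colSums(values)
  validation <- character(0)
  if (diff(range(sums)) > charge_sum_tol) {
    msg <- sprintf(
      "per-frame total charge drifts by %.4f a.u. (> tol %.4f); range [%.4f, %.4f]",
      diff(range(sums)), charge_sum_tol, min(sums), max(sums))
    warning(msg, call. = FALSE)
    validation <- msg
  }
  structure(values, scheme = scheme, validation = validation,
            class = c("charge_series", "matrix", "array"))
}

#' @export
print.charge_series <- function(x, ...) {
  cat(sprintf("charge_series (%s): %d atoms x %d frames, total %.3f a.u.\n",
              attr(x, "scheme"), nrow(x), ncol(x), sum(x[, 1])))
  if (length(attr(x, "validation"))) {
    cat("  validation:", attr(x, "validation"), "\n")
  }
  invisible(x)
}

#' Read a long-format atomic-charge table
#'
#' Canonical CSV dialect `frame,atom_index,charge` (frames 0-based, atoms
#' 1-based). Every atom must be present at every frame.
#'
#' @inheritParams read_bond_orders
#' @param scheme population-scheme label to attach (metadata only).
#' @param charge_sum_tol see [charge_series()].
#' @return A [charge_series].
#' @export
read_charges <- function(file, scheme = "NPA", charge_sum_tol = 0.01) {
  df <- .read_table_any(file)
  need <- c("frame", "atom_index", "charge")
  if (!all(need %in% names(df))) {
    stop("charge table must have columns frame,atom_index,charge")
  }
  frames <- sort(unique(df$frame))
  atoms <- sort(unique(df$atom_index))
  if (!identical(as.integer(atoms), seq_along(atoms))) {
    stop("atom_index must cover 1..N contiguously")
  }
  vals <- matrix(NA_real_, length(atoms), length(frames),
                 dimnames = list(atoms, frames))
  k <- paste(df$atom_index, df$frame)
  if (anyDuplicated(k)) stop("duplicate (frame, atom_index) row")
  vals[cbind(df$atom_index, match(df$frame, frames))] <- df$charge
  if (anyNA(vals)) stop("missing (frame, atom_index) cell in charge table")
  charge_series(vals, scheme = scheme, charge_sum_tol = charge_sum_tol)
}

#' Write a charge series as the canonical long CSV
#' @param series a [charge_series].
#' @param file output path or connection.
#' @return `series`, invisibly.
#' @export
write_charges <- function(series, file) {
  nfr <- ncol(series)
  df <- data.frame(
    frame = rep(seq_len(nfr) - 1L, each = nrow(series)),
    atom_index = rep(seq_len(nrow(series)), nfr),
    charge = as.vector(unclass(series)[seq_len(nrow(series)), ]))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(series)
}

# ---- PDB atom table ---------------------------------------------------------

#' Read the atom table of a PDB file
#'
#' Extracts atom serial, name, residue name and residue number from the
#' coordinate records of a PDB file (the QM-region model), for resolving the
#' atom labels used in analysis configs (e.g. `"PG"`, `"O3B"`, `"OD1"`).
#' Parsing is delegated to \pkg{bio3d}. Only the atom table is kept; no
#' coordinates are taken from the PDB (geometry always comes from the
#' trajectory).
#'
#' @param file path, connection, or PDB text.
#' @return data frame with columns `index`, `element`, `name`, `residue`
#'   (`"<resName><resSeq>"`).
#' @export
read_pdb_atoms <- function(file) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_atoms() requires the bio3d package")
  }
  lines <- .as_lines(file)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  # fall back to the atom name with digits stripped (e.g. "O3B" -> "O")
  element[blank] <- substr(gsub("[0-9']", "", trimws(at$elety[blank])), 1L, 1L)
  data.frame(index = seq_len(nrow(at)),
             element = trimws(element),
             name = trimws(at$elety),
             residue = paste0(at$resid, at$resno),
             stringsAsFactors = FALSE)
}

# ---- reports ----------------------------------------------------------------

# Recursively strip S3 classes/attributes so jsonlite serializes plainly.
.report_sanitize <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.matrix(x)) {
    return(as.data.frame(x))
  }
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .report_sanitize))
  }
  attributes(x) <- if (!is.null(names(x))) list(names = names(x)) else NULL
  x
}

#' Serialize an analysis report
#'
#' Writes any of the package's report objects (mechanism, synchronicity,
#' charge, or combined reports) as pretty-printed JSON; optionally the
#' report's tabular components are also emitted as flat CSV files next to
#' it, one per table.
#'
#' @param report a report object (nested list / data frames).
#' @param file output JSON path.
#' @param csv_dir optional directory for flat CSV exports of every data
#'   frame found in the report (created if missing).
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file, csv_dir = NULL) {
  clean <- .report_sanitize(report)
  jsonlite::write_json(clean, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  if (!is.null(csv_dir)) {
    if (!dir.exists(csv_dir)) dir.create(csv_dir, recursive = TRUE)
    emit <- function(x, prefix) {
      if (is.data.frame(x)) {
        utils::write.csv(x, file.path(csv_dir, paste0(prefix, ".csv")),
                         row.names = FALSE)
      } else if (is.list(x)) {
        for (nm in names(x)) {
          emit(x[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = "_") else nm)
        }
      }
    }
    emit(clean, "")
  }
  invisible(file)
}
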