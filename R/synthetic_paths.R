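# Deterministic synthetic reaction paths with known ground truth.
#
# The generator emulates the structure of QM/MM IRC output for a
# phosphoryl-transfer reaction: sigmoidal (logistic) bond-order transitions
# for breaking/forming bonds, an energy profile interpolated through
# prescribed stationary points, smoothly drifting fragment charges with the
# per-frame total forced to the system charge, and a collinear reactive
# triad whose P-O distances are coupled to the bond orders through the
# inverted Pauling relation d(B) = D1 - 0.60*log10(B). Observation noise is
# i.i.d. Gaussian per channel. Everything is reproducible from the spec's
# seed (Mersenne-Twister / inversion sampling, pinned).

.smoothstep_interp <- function(x, xp, yp) {
  # piecewise-cubic Hermite interpolation with zero slope at every node:
  # nodes are exact stationary points and the curve is monotone between
  # consecutive nodes.
  idx <- findInterval(x, xp, all.inside = TRUE)
  t <- (x - xp[idx]) / (xp[idx + 1L] - xp[idx])
  t <- pmin(1, pmax(0, t))
  yp[idx] + (yp[idx + 1L] - yp[idx]) * (3 * t^2 - 2 * t^3)
}

.logistic_mix <- function(xi, events_for_pair) {
  ev <- events_for_pair[order(vapply(events_for_pair, `[[`, numeric(1L), "mu"))]
  B <- rep(ev[[1L]]$B_start, length(xi))
  for (e in ev) {
    B <- B + (e$B_end - e$B_start) * stats::plogis((xi - e$mu) / e$s)
  }
  B
}

.pauling_distance <- function(B, D1 = 1.73) {
  D1 - 0.60 * log10(pmax(B, 0.01))
}

.default_atom_table <- function(n_atoms) {
  # canonical QM-region layout used by the presets: reactive core first,
  # then static spectators
  core <- data.frame(
    index = 1:12,
    element = c("P", "O", "O", "O", "O", "O", "H", "O", "N", "H", "Mg", "O"),
    name = c("PG", "O3B", "OG", "O1G", "O2G", "O3G", "HG",
             "OD1", "NZ", "HZ1", "MG", "OW"),
    residue = c(rep("ATP1", 2), rep("SER5", 1), rep("ATP1", 3), "SER5",
                "ASP127", "LYS129", "LYS129", "MG201", "HOH301"),
    stringsAsFactors = FALSE)
  if (n_atoms < 12L) {
    return(core[seq_len(n_atoms), , drop = FALSE])
  }
  extra <- n_atoms - 12L
  if (extra == 0L) return(core)
  el <- rep(c("C", "H", "H", "O", "N"), length.out = extra)
  spect <- data.frame(index = 12L + seq_len(extra), element = el,
                      name = paste0(el, 12L + seq_len(extra)),
                      residue = "ENV", stringsAsFactors = FALSE)
  rbind(core, spect)
}

#' Specify a synthetic reaction path
#'
#' Validated container for everything [generate_path()] needs: the grid,
#' the planted logistic bond-order events, the energy-profile stationary
#' targets, fragment charge trends, the reactive triad, and per-channel
#' Gaussian noise levels. Presets emulating the canonical mechanism
#' scenarios are available from [path_preset()].
#'
#' @param n_atoms number of atoms (>= 3; presets use 61, the size of a
#'   typical kinase QM region).
#' @param n_frames number of frames (>= 3).
#' @param xi_range length-2 numeric, reaction-coordinate range.
#' @param events list of logistic event specs, each
#'   `list(pair = c(i, j), B_start, B_end, mu, s)` with steepness `s > 0`;
#'   several events on one pair compose additively (break-then-reform).
#' @param profile data frame of stationary targets with columns `xi`,
#'   `rel_energy` (kcal/mol) and `kind`; first/last kinds must be
#'   `reactant`/`product` and interior kinds alternate max/min
#'   (`ts`/`intermediate`).
#' @param triad named integer vector `c(donor =, P =, acceptor =)`; both
#'   triad bonds must appear among the event pairs so geometry can be
#'   emitted.
#' @param fragments named list of atom-index vectors used by the charge
#'   analysis (e.g. `list(PO3 = c(1, 4, 5, 6))`).
#' @param charge_trends named list of fragment charge trends, each
#'   `list(atoms =, points = data.frame(xi, q))` with `q` the fragment
#'   total charge at the node; trend fragments must be disjoint. Atoms not
#'   covered by any trend share the residual so the per-frame total equals
#'   `total_charge` exactly before noise.
#' @param total_charge system total charge, a.u.
#' @param noise named list of Gaussian sigmas: `bond` (bond orders),
#'   `energy` (kcal/mol), `charge` (a.u. per atom; the default 0.0003
#'   emulates the rounding of population-analysis tables printed to three
#'   decimals, which keeps per-frame totals conserved within the standard
#'   0.01 a.u. tolerance).
#' @param D1 single-bond P-O reference distance for the distance coupling.
#' @param seed integer RNG seed.
#' @param atoms optional atom table (default: canonical layout).
#' @return Object of class `synthetic_path_spec`.
#' @export
synthetic_path_spec <- function(n_atoms = 61L, n_frames = 101L,
                                xi_range = c(0, 10), events, profile,
                                triad = c(donor = 2L, P = 1L, acceptor = 3L),
                                fragments = list(),
                                charge_trends = list(),
                                total_charge = -2,
                                noise = list(bond = 0.005, energy = 0.02,
                                             charge = 0.0003),
                                D1 = 1.73, seed = 1L, atoms = NULL) {
  if (n_frames < 3L) stop("n_frames must be >= 3")
  if (n_atoms < 3L) stop("n_atoms must be >= 3")
  if (diff(xi_range) <= 0) stop("xi_range must span a positive interval")
  if (length(events) == 0L) stop("at least one bond-order event is required")
  for (e in events) {
    if (is.null(e$pair) || length(e$pair) != 2L) stop("event needs pair = c(i, j)")
    if (any(e$pair < 1L) || any(e$pair > n_atoms)) stop("event pair out of range")
    if (is.null(e$s) || e$s <= 0) stop("event steepness s must be > 0")
    if (e$B_start < 0 || e$B_end < 0) stop("bond orders must be >= 0")
  }
  profile <- as.data.frame(profile)
  stopifnot(all(c("xi", "rel_energy", "kind") %in% names(profile)))
  if (nrow(profile) < 2L || profile$kind[1L] != "reactant" ||
      profile$kind[nrow(profile)] != "product") {
    stop("profile must run from a 'reactant' to a 'product' target")
  }
  if (any(diff(profile$xi) <= 0)) stop("profile xi targets must increase")
  interior <- profile$kind[-c(1L, nrow(profile))]
  if (length(interior) && !all(interior %in% c("ts", "intermediate"))) {
    stop("interior profile kinds must be 'ts' or 'intermediate'")
  }
  if (any(interior == "intermediate") &&
      !all(rle(interior)$lengths == 1L)) {
    stop("profile kinds must alternate max/min")
  }
  noise <- utils::modifyList(list(bond = 0, energy = 0, charge = 0), noise)
  if (any(unlist(noise) < 0)) stop("noise sigmas must be >= 0")
  pair_keys <- vapply(events, function(e)
    paste0(min(e$pair), "-", max(e$pair)), character(1L))
  for (b in list(c(triad[["donor"]], triad[["P"]]),
                 c(triad[["P"]], triad[["acceptor"]]))) {
    if (!paste0(min(b), "-", max(b)) %in% pair_keys) {
      stop(sprintf(
        "spec error: triad bond (%d,%d) has no event, so no distance coupling is available",
        b[1L], b[2L]))
    }
  }
  trend_atoms <- unlist(lapply(charge_trends, `[[`, "atoms"))
  if (anyDuplicated(trend_atoms)) stop("charge-trend fragments must be disjoint")
  if (any(trend_atoms > n_atoms)) stop("charge-trend atom out of range")
  if (length(trend_atoms) >= n_atoms) {
    stop("at least one atom must be left free to absorb the charge residual")
  }
  if (is.null(atoms)) atoms <- .default_atom_table(n_atoms)
  structure(list(n_atoms = as.integer(n_atoms),
                 n_frames = as.integer(n_frames),
                 xi_range = as.numeric(xi_range), events = events,
                 profile = profile, triad = triad, fragments = fragments,
                 charge_trends = charge_trends,
                 total_charge = total_charge, noise = noise, D1 = D1,
                 seed = as.integer(seed), atoms = atoms),
            class = "synthetic_path_spec")
}

#' Generate a synthetic reaction path with ground truth
#'
#' Deterministically (for a fixed seed) renders a
#' [synthetic_path_spec] into the full data bundle the analysis layer
#' consumes, plus the ground truth needed to validate it.
#'
#' Construction, per channel:
#' \itemize{
#'   \item bond orders: additive logistic transitions per pair, plus
#'     Gaussian noise, clamped at 0;
#'   \item energies: zero-slope piecewise-cubic interpolation through the
#'     profile's stationary targets (so the targets are exact stationary
#'     points), plus noise;
#'   \item geometry: the reactive triad is collinear along z with P-O
#'     distances derived from the noise-free bond orders via
#'     `d = D1 - 0.60*log10(B)` (clamped at `B < 0.01`); spectator atoms
#'     are static at seeded random positions;
#'   \item charges: fragment trends interpolated through their control
#'     points and split equally over the fragment's atoms; the remaining
#'     atoms share the residual so each frame sums exactly to the system
#'     charge before noise.
#' }
#'
#' @param spec a [synthetic_path_spec] (or preset name, see
#'   [path_preset()]).
#' @return List of class `synthetic_path` with elements `path`
#'   ([reaction_path]), `bond_orders` ([bond_order_series]), `charges`
#'   ([charge_series]), `truth` (planted event midpoints, stationary
#'   points, mechanism labels, metaphosphate frame, fragment trend nodes)
#'   and `spec`.
#' @export
generate_path <- function(spec) {
  if (is.character(spec)) spec <- path_preset(spec)
  stopifnot(inherits(spec, "synthetic_path_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  nf <- spec$n_frames
  xi <- seq(spec$xi_range[1L], spec$xi_range[2L], length.out = nf)

  ## bond orders -------------------------------------------------------------
  pair_keys <- vapply(spec$events, function(e)
    paste0(min(e$pair), "-", max(e$pair)), character(1L))
  keys <- unique(pair_keys)
  pairs <- t(vapply(strsplit(keys, "-", fixed = TRUE),
                    function(s) as.integer(s), integer(2L)))
  B_true <- matrix(NA_real_, length(keys), nf, dimnames = list(keys, NULL))
  for (k in seq_along(keys)) {
    B_true[k, ] <- .logistic_mix(xi, spec$events[pair_keys == keys[k]])
  }
  B_obs <- B_true
  if (spec$noise$bond > 0) {
    B_obs <- pmax(B_true + matrix(stats::rnorm(length(B_true), 0, spec$noise$bond),
                                  nrow(B_true)), 0)
  }
  bond_orders <- bond_order_series(pairs, B_obs)

  ## energies ----------------------------------------------------------------
  E_true <- .smoothstep_interp(xi, spec$profile$xi, spec$profile$rel_energy)
  E_obs <- E_true
  if (spec$noise$energy > 0) {
    E_obs <- E_true + stats::rnorm(nf, 0, spec$noise$energy)
  }

  ## geometry ----------------------------------------------------------------
  donor <- spec$triad[["donor"]]; P <- spec$triad[["P"]]
  acceptor <- spec$triad[["acceptor"]]
  d_break <- .pauling_distance(B_true[paste0(min(donor, P), "-", max(donor, P)), ],
                               spec$D1)
  d_form <- .pauling_distance(B_true[paste0(min(P, acceptor), "-", max(P, acceptor)), ],
                              spec$D1)
  base_pos <- matrix(stats::rnorm(spec$n_atoms * 3L, 0, 4), spec$n_atoms, 3L)
  base_pos <- base_pos + 8 * sign(base_pos)   # push spectators away from origin
  coords <- array(rep(base_pos, nf), dim = c(spec$n_atoms, 3L, nf))
  for (f in seq_len(nf)) {
    coords[P, , f] <- c(0, 0, 0)
    coords[donor, , f] <- c(0, 0, -d_break[f])
    coords[acceptor, , f] <- c(0, 0, d_form[f])
  }

  ## charges -----------------------------------------------------------------
  q_true <- matrix(0, spec$n_atoms, nf)
  trend_atoms <- integer(0)
  for (tr in spec$charge_trends) {
    pts <- as.data.frame(tr$points)
    qf <- if (nrow(pts) == 1L) rep(pts$q, nf)
          else .smoothstep_interp(xi, pts$xi, pts$q)
    q_true[tr$atoms, ] <- matrix(rep(qf / length(tr$atoms), each = length(tr$atoms)),
                                 length(tr$atoms), nf)
    trend_atoms <- c(trend_atoms, tr$atoms)
  }
  free <- setdiff(seq_len(spec$n_atoms), trend_atoms)
  residual <- spec$total_charge - colSums(q_true)
  q_true[free, ] <- q_true[free, ] +
    matrix(rep(residual / length(free), each = length(free)), length(free), nf)
  q_obs <- q_true
  if (spec$noise$charge > 0) {
    q_obs <- q_true + matrix(stats::rnorm(length(q_true), 0, spec$noise$charge),
                             nrow(q_true))
  }
  # validation tolerance consistent with the generator's own noise model:
  # per-frame totals are N(total, sigma_q * sqrt(n_atoms)); an 8-sigma band
  # on the range covers the realized spread at any path length used here
  tol <- max(0.01, 8 * spec$noise$charge * sqrt(spec$n_atoms))
  charges <- charge_series(q_obs, scheme = "NPA", charge_sum_tol = tol)

  ## ground truth ------------------------------------------------------------
  nearest_frame <- function(x) vapply(x, function(v) which.min(abs(xi - v)),
                                      integer(1L))
  ev_truth <- data.frame(
    pair = pair_keys,
    mu = vapply(spec$events, `[[`, numeric(1L), "mu"),
    delta = vapply(spec$events, function(e) e$B_end - e$B_start, numeric(1L)),
    stringsAsFactors = FALSE)
  ev_truth$direction <- ifelse(ev_truth$delta > 0, "forming",
                               ifelse(ev_truth$delta < 0, "breaking", "none"))
  stat_truth <- spec$profile
  stat_truth$frame <- nearest_frame(stat_truth$xi)
  ts_xi <- stat_truth$xi[stat_truth$kind == "ts"]
  topology <- if (length(ts_xi) == 0L) "none"
    else if (length(ts_xi) == 1L) "concerted" else "stepwise"
  char_lbl <- NA_character_
  if (length(ts_xi)) {
    pct <- vapply(ts_xi, function(x0) {
      f <- nearest_frame(x0)
      pauling_bond_number(d_break[f], d_form[f], D1 = spec$D1)$pct_assoc
    }, numeric(1L))
    char_lbl <- if (mean(pct) > 50) "associative" else "dissociative"
  }
  int_frames <- stat_truth$frame[stat_truth$kind == "intermediate"]
  key_bp <- paste0(min(donor, P), "-", max(donor, P))
  key_pf <- paste0(min(P, acceptor), "-", max(P, acceptor))
  meta_frame <- int_frames[
    B_true[key_bp, int_frames] < 0.5 & B_true[key_pf, int_frames] < 0.5]
  truth <- list(events = ev_truth, stationary = stat_truth,
                label = list(topology = topology, character = char_lbl),
                metaphosphate_frames = meta_frame,
                charge_trends = spec$charge_trends)

  path <- reaction_path(spec$atoms, coords, energy = E_obs, xi = xi,
                        meta = list(source = "synthetic", seed = spec$seed))
  structure(list(path = path, bond_orders = bond_orders, charges = charges,
                 truth = truth, spec = spec),
            class = "synthetic_path")
}

#' @export
print.synthetic_path <- function(x, ...) {
  cat(sprintf("synthetic_path (seed %d): %s/%s, %d frames, %d bond pairs\n",
              x$spec$seed, x$truth$label$topology,
              x$truth$label$character, n_frames(x$path), nrow(x$bond_orders$pairs)))
  invisible(x)
}

#' Frozen synthetic-path presets
#'
#' Four documented scenarios exercising the mechanistic space the analysis
#' layer must distinguish:
#' \describe{
#'   \item{`base_assisted_like`}{Stepwise dissociative path: two transition
#'     states (rel. energies 8.2 and 14.3 kcal/mol) flanking a shallow
#'     metaphosphate-like intermediate (7.1 kcal/mol; TS1-Int gap only
#'     1.1 kcal/mol, TS2-Int 7.2 kcal/mol), product at 2.5 kcal/mol.
#'     P-O bond breaking precedes bond formation; two late proton-transfer
#'     pairs (Lys-to-phosphate slightly before Ser-to-Asp, peak offset 0.05
#'     of the path) near TS2. Fragment charges follow the published P,
#'     PO3 and Mg trends, with the PO3 group planted at exactly -1.00 a.u.
#'     (the ideal metaphosphate charge) at the intermediate.}
#'   \item{`substrate_assisted_like`}{Concerted dissociative path: a single
#'     high TS (50.5 kcal/mol, product 2.3), early leaving-group rupture,
#'     and proton-transfer events synchronized at the TS so the forming and
#'     breaking proton curves cross near the maximum.}
#'   \item{`associative_toy`}{Single TS with short, tight P-O distances
#'     (bond orders ~0.6 at the TS), exercising the associative branch of
#'     the classifier.}
#'   \item{`barrierless_toy`}{Monotone downhill profile with no interior
#'     maximum: the degenerate "none" pathway class.}
#' }
#'
#' Presets are frozen specs: same name + same seed always yields the same
#' bundle.
#'
#' @param name one of `"base_assisted_like"`, `"substrate_assisted_like"`,
#'   `"associative_toy"`, `"barrierless_toy"`.
#' @param seed RNG seed stored in the spec (default 1).
#' @return A [synthetic_path_spec].
#' @export
path_preset <- function(name, seed = 1L) {
  ev <- function(i, j, B_start, B_end, mu, s) {
    list(pair = c(i, j), B_start = B_start, B_end = B_end, mu = mu, s = s)
  }
  core_frags <- list(PO3 = c(1L, 4L, 5L, 6L), Pgamma = 1L, Mg = 11L)
  switch(
    name,
    base_assisted_like = {
      nodes <- c(0, 3, 4.5, 7, 10)
      po3 <- c(-1.10, -0.98, -1.00, -0.94, -0.97)
      pg <- c(2.61, 2.57, 2.56, 2.59, 2.60)
      synthetic_path_spec(
        n_atoms = 61L, n_frames = 101L, xi_range = c(0, 10),
        events = list(
          ev(2, 1, 0.90, 0.02, 2.5, 0.45),   # O3B-PG breaking
          ev(1, 3, 0.00, 0.90, 4.6, 0.60),   # PG-OG forming
          ev(9, 10, 0.75, 0.05, 6.5, 0.25),  # NZ-HZ1 breaking (Lys)
          ev(5, 10, 0.00, 0.70, 6.5, 0.25),  # O2G-HZ1 forming (Lys)
          ev(3, 7, 0.75, 0.03, 7.0, 0.25),   # OG-HG breaking (Ser)
          ev(8, 7, 0.00, 0.72, 7.0, 0.25)),  # OD1-HG forming (Asp)
        profile = data.frame(
          xi = nodes, rel_energy = c(0, 8.2, 7.1, 14.3, 2.5),
          kind = c("reactant", "ts", "intermediate", "ts", "product")),
        fragments = core_frags,
        charge_trends = list(
          Pgamma = list(atoms = 1L, points = data.frame(xi = nodes, q = pg)),
          nonbridging_O = list(atoms = c(4L, 5L, 6L),
                               points = data.frame(xi = nodes, q = po3 - pg)),
          Mg = list(atoms = 11L,
                    points = data.frame(xi = c(0, 10), q = c(1.72, 1.79)))),
        total_charge = -2, seed = seed)
    },
    substrate_assisted_like = {
      nodes <- c(0, 4, 5, 10)
      po3 <- c(-0.90, -1.00, -0.85, -0.95)
      pg <- c(2.55, 2.49, 2.52, 2.61)
      synthetic_path_spec(
        n_atoms = 61L, n_frames = 101L, xi_range = c(0, 10),
        events = list(
          ev(2, 1, 0.90, 0.02, 3.0, 0.50),   # O3B-PG breaking (early)
          ev(1, 3, 0.00, 0.90, 5.6, 0.40),   # PG-OG forming
          ev(3, 7, 0.75, 0.02, 5.0, 0.30),   # OG-HG breaking at the TS
          ev(4, 7, 0.00, 0.75, 5.0, 0.30)),  # O1G-HG forming at the TS
        profile = data.frame(
          xi = c(0, 5, 10), rel_energy = c(0, 50.5, 2.3),
          kind = c("reactant", "ts", "product")),
        fragments = core_frags,
        charge_trends = list(
          Pgamma = list(atoms = 1L, points = data.frame(xi = nodes, q = pg)),
          nonbridging_O = list(atoms = c(4L, 5L, 6L),
                               points = data.frame(xi = nodes, q = po3 - pg)),
          Mg = list(atoms = 11L,
                    points = data.frame(xi = c(0, 10), q = c(1.72, 1.76)))),
        total_charge = -2, seed = seed)
    },
    associative_toy = synthetic_path_spec(
      n_atoms = 12L, n_frames = 81L, xi_range = c(0, 10),
      events = list(
        ev(2, 1, 1.00, 0.20, 5, 0.8),
        ev(1, 3, 0.20, 1.00, 5, 0.8)),
      profile = data.frame(xi = c(0, 5, 10), rel_energy = c(0, 20, 1),
                           kind = c("reactant", "ts", "product")),
      fragments = list(PO3 = c(1L, 4L, 5L, 6L)),
      total_charge = -1, seed = seed),
    barrierless_toy = synthetic_path_spec(
      n_atoms = 12L, n_frames = 61L, xi_range = c(0, 10),
      events = list(
        ev(2, 1, 0.25, 0.25, 5, 1),
        ev(1, 3, 0.05, 0.90, 5, 0.8)),
      profile = data.frame(xi = c(0, 10), rel_energy = c(0, -8),
                           kind = c("reactant", "product")),
      fragments = list(PO3 = c(1L, 4L, 5L, 6L)),
      total_charge = -1, seed = seed),
    stop(sprintf("unknown preset '%s'", name))
  )
}

#' Serialize / restore a synthetic-path spec
#'
#' Specs round-trip through JSON so fixtures can be stored and shared as
#' plain text.
#'
#' @param spec a [synthetic_path_spec].
#' @param file JSON path (or, for `spec_from_json`, path or JSON text).
#' @return `spec_to_json` returns `file` invisibly; `spec_from_json`
#'   returns a validated [synthetic_path_spec].
#' @export
spec_to_json <- function(spec, file) {
  stopifnot(inherits(spec, "synthetic_path_spec"))
  out <- unclass(spec)
  out$triad <- as.list(out$triad)  # keep names through JSON
  # 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, dataframe = "columns")
  invisible(file)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  events <- lapply(seq_along(raw$events$pair), function(k) {
    list(pair = as.integer(raw$events$pair[[k]]),
         B_start = raw$events$B_start[k], B_end = raw$events$B_end[k],
         mu = raw$events$mu[k], s = raw$events$s[k])
  })
  trends <- lapply(raw$charge_trends, function(tr) {
    list(atoms = as.integer(tr$atoms), points = as.data.frame(tr$points))
  })
  frags <- lapply(raw$fragments, as.integer)
  synthetic_path_spec(
    n_atoms = raw$n_atoms, n_frames = raw$n_frames,
    xi_range = as.numeric(raw$xi_range), events = events,
    profile = as.data.frame(raw$profile),
    triad = c(donor = as.integer(raw$triad[["donor"]]),
              P = as.integer(raw$triad[["P"]]),
              acceptor = as.integer(raw$triad[["acceptor"]])),
    fragments = frags, charge_trends = trends,
    total_charge = raw$total_charge, noise = as.list(raw$noise),
    D1 = raw$D1, seed = raw$seed, atoms = as.data.frame(raw$atoms))
}

#' Write a synthetic bundle to disk in the canonical external formats
#'
#' Renders a generated path as the file set the readers (and the command
#' line) consume: multi-frame XYZ with energy tokens, long-format
#' bond-order and charge CSVs, the spec and ground truth as JSON, and a
#' ready-to-run analysis config.
#'
#' @param x a `synthetic_path` from [generate_path()] (or a preset name).
#' @param dir output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
synthesize_bundle <- function(x, dir) {
  if (is.character(x)) x <- generate_path(path_preset(x))
  stopifnot(inherits(x, "synthetic_path"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(xyz = file.path(dir, "path.xyz"),
             bond_orders = file.path(dir, "bond_orders.csv"),
             charges = file.path(dir, "charges.csv"),
             xi = file.path(dir, "xi.csv"),
             spec = file.path(dir, "spec.json"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_xyz_path(x$path, files[["xyz"]])
  write_bond_orders(x$bond_orders, files[["bond_orders"]])
  write_charges(x$charges, files[["charges"]])
  utils::write.csv(data.frame(frame = seq_len(n_frames(x$path)) - 1L,
                              xi = x$path$xi),
                   files[["xi"]], row.names = FALSE, quote = FALSE)
  spec_to_json(x$spec, files[["spec"]])
  write_report(x$truth, files[["truth"]])
  triad <- x$spec$triad
  cfg <- list(
    files = list(xyz = "path.xyz", bond_orders = "bond_orders.csv",
                 charges = "charges.csv", xi = "xi.csv"),
    triad = list(donor = unname(triad[["donor"]]), P = unname(triad[["P"]]),
                 acceptor = unname(triad[["acceptor"]])),
    fragments = lapply(x$spec$fragments, as.integer),
    thresholds = list())
  yaml::write_yaml(cfg, files[["config"]])
  invisible(files)
}
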