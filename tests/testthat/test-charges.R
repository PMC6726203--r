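test_that("fragment charges are exact per-frame sums", {
  q <- charge_series(matrix(c(0.5, -0.5, 0, 0.4, -0.4, 0), 3, 2))
  expect_equal(unname(fragment_charge(q, 1:3)), c(0, 0))
  expect_equal(unname(fragment_charge(q, 2)), c(-0.5, -0.4))
  expect_error(fragment_charge(q, 9), "out of range")
  expect_error(fragment_charge(q, integer(0)), "at least one atom")
})

test_that("the planted metaphosphate fragment charge is recovered", {
  g <- generate_path(path_preset("base_assisted_like"))
  mf <- g$truth$metaphosphate_frames
  expect_length(mf, 1L)
  po3 <- fragment_charge(g$charges, c(1, 4, 5, 6))
  # generated to sum to exactly -1.00 a.u. there, up to observation noise
  expect_equal(unname(po3[mf]), -1.00, tolerance = 0.01)
})

test_that("charge profile reports deltas, extrema and monotone segments", {
  nf <- 11
  lin <- matrix(0, 2, nf)
  lin[1, ] <- seq(2.55, 2.61, length.out = nf)   # drifting centre atom
  lin[2, ] <- -2 - lin[1, ]                      # absorbs the residual
  q <- charge_series(lin)
  sp <- data.frame(frame = c(1, 6, 11), kind = c("reactant", "ts", "product"))
  rep1 <- charge_profile_report(q, list(P = 1), sp)
  expect_equal(rep1$deltas$reactant_to_product, 0.06, tolerance = 1e-9)
  expect_equal(unlist(rep1$at_stationary[1, c("reactant", "product")],
                      use.names = FALSE), c(2.55, 2.61))
  expect_equal(rep1$segments$P$trend, "rising")

  const <- charge_series(matrix(-0.5, 1, nf))
  rep2 <- charge_profile_report(const, list(f = 1), sp)
  expect_equal(rep2$deltas$reactant_to_min, 0)
  expect_equal(rep2$deltas$reactant_to_product, 0)

  v <- matrix(c(abs(seq(-5, 5)) / 10, -seq(-5, 5) * 0), 2, nf, byrow = TRUE)
  qv <- charge_series(v, charge_sum_tol = 10)
  rep3 <- charge_profile_report(qv, list(v = 1), sp, xi = seq(0, 1, by = 0.1))
  expect_equal(rep3$extrema$xi_min, 0.5)
  expect_equal(rep3$extrema$q_min, 0)
})

test_that("profile extrema agree with brute-force scans of the traces", {
  g <- generate_path(path_preset("substrate_assisted_like"))
  sp <- detect_stationary_points(g$path$energy, g$path$xi)
  frags <- list(PO3 = c(1, 4, 5, 6), Mg = 11)
  rep <- charge_profile_report(g$charges, frags, sp, xi = g$path$xi)
  for (fr in names(frags)) {
    trace <- fragment_charge(g$charges, frags[[fr]])
    expect_equal(rep$extrema$q_min[rep$extrema$fragment == fr], min(trace))
    expect_equal(rep$extrema$xi_max[rep$extrema$fragment == fr],
                 g$path$xi[which.max(trace)])
  }
})

test_that("event windows attribute charge transfer to the right fragments", {
  xi <- seq(0, 10, by = 0.1)
  gain <- logistic_curve(xi, -0.5, -0.4, 5, 0.3)   # +0.1 at the event
  lose <- logistic_curve(xi, 0.2, 0.1, 5, 0.3)     # equal and opposite
  flat <- rep(0.3, length(xi))
  traces <- rbind(donor = lose, acceptor = gain, spectator = flat)
  ev <- data.frame(pair = "5-10", direction = "forming", xi_peak = 5)
  cc <- charge_event_correlation(traces, xi, ev, window = 4)
  dq <- setNames(cc$dq, cc$fragment)
  expect_equal(unname(dq["acceptor"]), 0.1, tolerance = 0.01)
  expect_equal(unname(dq["donor"]), -dq[["acceptor"]], tolerance = 1e-9)
  expect_equal(unname(dq["spectator"]), 0, tolerance = 1e-9)
  expect_equal(cc$summary, c("loses charge", "gains charge", "unchanged"))

  # a window reaching past the path ends is clipped with a warning
  ev_edge <- data.frame(pair = "5-10", direction = "forming", xi_peak = 0.5)
  expect_warning(charge_event_correlation(traces, xi, ev_edge, window = 4),
                 "clipped")
})

test_that("any fragment partition conserves the total charge along the path", {
  g <- generate_path(path_preset("base_assisted_like"))
  set.seed(1)
  cuts <- sort(sample(2:60, 3))
  partition <- split(1:61, findInterval(1:61, cuts))
  tot <- Reduce(`+`, lapply(partition, function(a) fragment_charge(g$charges, a)))
  expect_equal(unname(tot), unname(colSums(unclass(g$charges))), tolerance = 1e-12)
  expect_true(all(abs(tot - (-2)) <= 0.01))
})

test_that("reports are invariant under consistent atom re-indexing", {
  g <- generate_path(path_preset("associative_toy"))
  q <- unclass(g$charges)
  set.seed(4)
  perm <- sample(nrow(q))
  q_perm <- charge_series(q[perm, ], charge_sum_tol = 1)
  sp <- detect_stationary_points(g$path$energy, g$path$xi)
  frags <- list(PO3 = c(1, 4, 5, 6))
  frags_perm <- list(PO3 = match(frags$PO3, perm))
  r1 <- charge_profile_report(g$charges, frags, sp, xi = g$path$xi)
  r2 <- charge_profile_report(q_perm, frags_perm, sp, xi = g$path$xi)
  expect_equal(r1$deltas, r2$deltas)
  expect_equal(r1$extrema, r2$extrema)
})
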