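test_that("derivatives are exact for constant and linear bond orders", {
  xi <- c(0, 0.3, 0.9, 1.4, 2.8, 3.1, 4.0)   # deliberately non-uniform
  B <- rbind(rep(0.7, 7), 0.3 * xi)
  d <- bond_order_derivative(B, xi)
  expect_equal(unname(d[1, ]), rep(0, 7))
  expect_equal(unname(d[2, ]), rep(0.3, 7))
  df <- bond_order_derivative(B, xi, scheme = "forward")
  expect_equal(unname(df[2, ]), rep(0.3, 7))
  expect_error(bond_order_derivative(B, rev(xi)), "strictly increasing")
})

test_that("the logistic derivative peaks at the transition midpoint", {
  xi <- seq(0, 10, by = 0.1)
  B <- matrix(logistic_curve(xi, 0, 1, 5, 0.5), 1)
  d <- bond_order_derivative(B, xi)
  expect_lte(abs(xi[which.max(d)] - 5), 0.1)
  # closed form: maximum slope of a logistic is (B1-B0)/(4s)
  expect_equal(max(d), 1 / (4 * 0.5), tolerance = 0.01)
})

test_that("derivative-integral closure holds (fundamental theorem)", {
  xi <- seq(0, 10, by = 0.1)
  # exact for linear data with the unsmoothed central scheme
  lin <- matrix(0.25 * xi, 1)
  d_lin <- bond_order_derivative(lin, xi)
  expect_equal(trapz_int(xi, d_lin[1, ]), 2.5, tolerance = 1e-9)
  # within 2% of the net change for logistic fixtures
  for (s in c(0.3, 0.6, 1.0)) {
    B <- logistic_curve(xi, 0.9, 0.05, 5, s)
    d <- bond_order_derivative(matrix(B, 1), xi)
    net <- B[length(B)] - B[1]
    expect_lte(abs(trapz_int(xi, d[1, ]) - net), 0.02 * abs(net))
  }
})

test_that("bond events are detected with direction and order", {
  xi <- seq(0, 10, by = 0.1)
  one <- bond_order_series(rbind(c(1, 2)),
                           matrix(logistic_curve(xi, 0, 0.9, 5, 0.4), 1))
  ev <- detect_bond_events(bond_order_derivative(one, xi), one, xi)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "forming")
  expect_gt(ev$peak_height, 0)
  expect_gt(ev$net_change, 0)
  expect_lte(abs(ev$xi_peak - 5), 0.1)

  flat <- bond_order_series(rbind(c(1, 2)), matrix(rep(0.4, length(xi)), 1))
  expect_equal(nrow(detect_bond_events(bond_order_derivative(flat, xi),
                                       flat, xi)), 0L)

  # break then reform on a single pair
  B2 <- logistic_curve(xi, 0.9, 0.05, 3, 0.4) +
    0.85 * stats::plogis((xi - 7) / 0.4)
  two <- bond_order_series(rbind(c(1, 2)), matrix(B2, 1))
  ev2 <- detect_bond_events(bond_order_derivative(two, xi), two, xi)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$direction, c("breaking", "forming"))
  expect_equal(ev2$xi_peak, c(3, 7), tolerance = 0.11)
})

test_that("planted logistic events are recovered under observation noise", {
  # up to 4 events, midpoints well separated, noise sigma = 0.01 with
  # Savitzky-Golay pre-smoothing: exactly K events within one grid step
  mus <- c(2, 4.5, 6.5, 8)
  for (sd in 1:3) {
    spec <- synthetic_path_spec(
      n_atoms = 12, n_frames = 101, xi_range = c(0, 10),
      events = list(
        list(pair = c(2, 1), B_start = 0.9, B_end = 0.05, mu = 2, s = 0.45),
        list(pair = c(1, 3), B_start = 0.0, B_end = 0.85, mu = 4.5, s = 0.45),
        list(pair = c(3, 7), B_start = 0.8, B_end = 0.05, mu = 6.5, s = 0.45),
        list(pair = c(8, 7), B_start = 0.0, B_end = 0.8, mu = 8, s = 0.45)),
      profile = data.frame(xi = c(0, 5, 10), rel_energy = c(0, 12, 1),
                           kind = c("reactant", "ts", "product")),
      noise = list(bond = 0.01, energy = 0, charge = 0), seed = sd)
    g <- generate_path(spec)
    d <- bond_order_derivative(g$bond_orders, g$path$xi,
                               smooth = list(window = 5, degree = 2))
    ev <- detect_bond_events(d, g$bond_orders, g$path$xi)
    expect_equal(nrow(ev), 4L)
    expect_true(all(abs(sort(ev$xi_peak) - mus) <= 0.1))
  }
})

test_that("smoothing does not shift a symmetric derivative peak", {
  xi <- seq(0, 10, by = 0.1)
  s <- bond_order_series(rbind(c(1, 2)),
                         matrix(logistic_curve(xi, 0, 0.9, 5, 0.5), 1))
  raw <- detect_bond_events(bond_order_derivative(s, xi), s, xi)
  smo <- detect_bond_events(
    bond_order_derivative(s, xi, smooth = list(window = 5, degree = 2)), s, xi)
  expect_lte(abs(raw$xi_peak - smo$xi_peak), 0.1)
})

test_that("curve crossings are interpolated correctly", {
  xi <- seq(0, 10, by = 0.1)
  up <- logistic_curve(xi, 0, 1, 5, 0.6)
  down <- logistic_curve(xi, 1, 0, 5, 0.6)
  s <- bond_order_series(rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4)),
                         rbind(up, down, rep(0.2, length(xi)),
                               rep(0.8, length(xi))))
  cr <- find_crossings(s, xi, c(1, 2), c(1, 3))
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$xi_cross, 5, tolerance = 1e-9)
  expect_equal(cr$B_cross, 0.5, tolerance = 1e-9)
  expect_equal(nrow(find_crossings(s, xi, c(2, 3), c(1, 4))), 0L)
})

test_that("coarse-grid crossings agree with dense-grid evaluation", {
  f_a <- function(x) logistic_curve(x, 0.05, 0.95, 5.3, 0.7)
  f_b <- function(x) rep(0.5, length(x))
  xi_c <- seq(0, 10, by = 0.1)
  xi_d <- seq(0, 10, by = 0.001)
  mk <- function(xi) bond_order_series(rbind(c(1, 2), c(1, 3)),
                                       rbind(f_a(xi), f_b(xi)))
  cr_c <- find_crossings(mk(xi_c), xi_c, c(1, 2), c(1, 3))
  cr_d <- find_crossings(mk(xi_d), xi_d, c(1, 2), c(1, 3))
  expect_equal(nrow(cr_c), 1L)
  expect_lte(abs(cr_c$xi_cross - cr_d$xi_cross), 1e-3)
  expect_lte(abs(cr_c$B_cross - cr_d$B_cross), 1e-3)
})

test_that("synchronicity span normalizes peak spread", {
  ev <- data.frame(pair = c("1-2", "1-3"), direction = c("forming", "breaking"),
                   xi_peak = c(4, 4))
  expect_equal(synchronicity_span(ev, c(0, 10))$span, 0)
  ev2 <- data.frame(pair = c("1-2", "1-3"), direction = c("forming", "breaking"),
                    xi_peak = c(2, 8))
  sp <- synchronicity_span(ev2, c(0, 10))
  expect_equal(sp$span, 0.6)
  expect_equal(sp$offsets$offset, 6)
  expect_error(synchronicity_span(ev2[1, ], c(0, 10)), "insufficient")
})

test_that("the slightly asynchronous proton-transfer preset is quantified", {
  g <- generate_path(path_preset("base_assisted_like"))
  d <- bond_order_derivative(g$bond_orders, g$path$xi,
                             smooth = list(window = 5, degree = 2))
  ev <- detect_bond_events(d, g$bond_orders, g$path$xi)
  proton <- ev[ev$pair %in% c("9-10", "5-10", "3-7", "7-8"), ]
  expect_equal(nrow(proton), 4L)
  sp <- synchronicity_span(proton, range(g$path$xi))
  # planted offset between the two proton transfers: 0.05 of the path
  expect_lte(abs(sp$span - 0.05), 0.015)
})
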