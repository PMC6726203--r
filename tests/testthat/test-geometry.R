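test_that("distances reproduce a rebuilt loose-TS geometry", {
  # reactive core rebuilt so the labelled pairs match the published
  # substrate-assisted TS column: leaving O at 3.04 A and entering O at
  # 2.10 A from P, collinear
  frame <- rbind(PG = c(0, 0, 0),
                 O3B = c(0, 0, -3.04),
                 OG = c(0, 0, 2.10))
  expect_equal(atom_distance(frame, 2, 1), 3.04)
  expect_equal(atom_distance(frame, 1, 3), 2.10)
  expect_equal(atom_distance(frame, 1, 3), atom_distance(frame, 3, 1))
  expect_equal(atom_distance(frame, 2, 2), 0)
  simple <- rbind(c(0, 0, 0), c(0, 0, 2.10))
  expect_equal(atom_distance(simple, 1, 2), 2.10)
  expect_error(atom_distance(simple, 1, 5), "out of range")
})

test_that("angles cover collinear, right-angle and symmetric cases", {
  frame <- rbind(c(0, 0, -1), c(0, 0, 0), c(0, 0, 4), c(0, 2, 0))
  expect_equal(atom_angle(frame, 1, 2, 3), 180)
  expect_equal(atom_angle(frame, 1, 2, 4), 90)
  expect_equal(atom_angle(frame, 1, 2, 4), atom_angle(frame, 4, 2, 1))
  degenerate <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(atom_angle(degenerate, 1, 2, 3), "coincident")
  expect_error(atom_angle(frame, 1, 2, 2), "distinct")
})

test_that("geometric measurements are invariant under rigid motions", {
  set.seed(42)
  frame <- matrix(rnorm(6 * 3, sd = 2), 6, 3)
  frame[2, ] <- frame[1, ] + c(0.97, 0, 0)     # a D-H bond for hbond tests
  d0 <- atom_distance(frame, 1, 4)
  a0 <- atom_angle(frame, 1, 4, 5)
  hb0 <- hbond_detect(frame, donors = cbind(1, 2), acceptors = c(4, 5, 6))
  for (k in 1:5) {
    R <- random_rotation()
    t0 <- rnorm(3, sd = 10)
    moved <- sweep(frame %*% t(R), 2, -t0)
    expect_equal(atom_distance(moved, 1, 4), d0, tolerance = 1e-10)
    expect_equal(atom_angle(moved, 1, 4, 5), a0, tolerance = 1e-8)
    hb <- hbond_detect(moved, donors = cbind(1, 2), acceptors = c(4, 5, 6))
    expect_equal(hb[c("donor", "h", "acceptor")], hb0[c("donor", "h", "acceptor")])
    expect_equal(hb$d_da, hb0$d_da, tolerance = 1e-10)
  }
})

test_that("coordination counts ligands inside the cutoff, reporting all", {
  # octahedral shell with one contact drifted to 3.18 A (partial
  # decoordination of a phosphate oxygen in the product state)
  d_prod <- c(3.18, 1.97, 2.03, 2.17, 2.17, 1.98)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  lig <- dirs * d_prod
  coords <- rbind(c(0, 0, 0), lig)
  path <- make_path(list(coords, coords), c("Mg", rep("O", 6)))
  cp <- coordination_profile(path, metal = 1, ligands = 2:7)
  expect_equal(cp$coordination, c(5L, 5L))
  expect_equal(unname(cp$distances[1, ]), d_prod, tolerance = 1e-10)

  all2 <- make_path(list(rbind(c(0, 0, 0), dirs * 2.0),
                         rbind(c(0, 0, 0), dirs * 2.0)))
  expect_equal(coordination_profile(all2, 1, 2:7)$coordination[1], 6L)
  expect_equal(coordination_profile(all2, 1, 2:7, cutoff = 0.1)$coordination[1], 0L)
  expect_error(coordination_profile(path, 1, integer(0)), "non-empty")
})

test_that("coordination number is monotone non-decreasing in the cutoff", {
  set.seed(7)
  dists <- sort(runif(8, 1.8, 3.6))
  dirs <- matrix(rnorm(24), 8, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- rbind(c(0, 0, 0), dirs * dists)
  path <- make_path(list(coords, coords))
  cuts <- seq(0.5, 4, by = 0.25)
  cn <- vapply(cuts, function(ct)
    coordination_profile(path, 1, 2:9, cutoff = ct)$coordination[1], integer(1))
  expect_true(all(diff(cn) >= 0))
})

test_that("hydrogen-bond detection applies both geometric criteria", {
  # ideal linear O-H...O, donor-acceptor 2.8 A
  fr <- rbind(c(0, 0, 0), c(0, 0, 0.97), c(0, 0, 2.8))
  hb <- hbond_detect(fr, donors = cbind(1, 2), acceptors = 3)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle, 180)
  expect_equal(hb$d_da, 2.8)

  far <- rbind(c(0, 0, 0), c(0, 0, 0.97), c(0, 0, 4.0))
  expect_equal(nrow(hbond_detect(far, cbind(1, 2), 3)), 0L)

  # bent contact at 100 degrees: excluded under defaults, included at 90
  h <- c(0, 0, 0.97)
  acc <- h + 2.0 * c(sin(80 * pi / 180), 0, cos(80 * pi / 180))
  bent <- rbind(c(0, 0, 0), h, acc)
  expect_equal(nrow(hbond_detect(bent, cbind(1, 2), 3)), 0L)
  hb90 <- hbond_detect(bent, cbind(1, 2), 3, hbond_criteria(angle_min = 90))
  expect_equal(nrow(hb90), 1L)
  expect_equal(hb90$angle, 100, tolerance = 1e-6)

  # a (D, H) pair that is not covalently bonded is skipped with a warning
  loose <- rbind(c(0, 0, 0), c(0, 0, 1.6), c(0, 0, 2.8))
  expect_warning(res <- hbond_detect(loose, cbind(1, 2), 3), "skipped")
  expect_equal(nrow(res), 0L)
})

test_that("key-distance tables equal direct per-frame measurements", {
  set.seed(5)
  coords <- lapply(1:4, function(f) matrix(rnorm(15, sd = 3), 5, 3))
  path <- make_path(coords)
  specs <- data.frame(label = c("a-b", "c-d"), i = c(1, 3), j = c(2, 4))
  tab <- key_distance_table(path, specs, c(Reac = 1, TS = 2, Prod = 4))
  full <- attr(tab, "full")
  for (ci in seq_len(ncol(tab))) {
    fr <- frame_coords(path, c(1, 2, 4)[ci])
    expect_equal(full[1, ci], atom_distance(fr, 1, 2))
    expect_equal(full[2, ci], atom_distance(fr, 3, 4))
  }
  expect_equal(tab[1, 1], round(full[1, 1], 2))
  empty <- key_distance_table(path, specs[0, ], c(Reac = 1))
  expect_equal(nrow(empty), 0L)
})
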