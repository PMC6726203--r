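test_that("multi-frame XYZ with energy tokens is read faithfully", {
  c1 <- matrix(c(0, 0, 0,  0, 0, 1.5,  1.2, 0, 0), 3, 3, byrow = TRUE)
  c2 <- c1 + 0.1
  txt <- make_xyz_text(list(c1, c2), c("O", "P", "O"), energies = c(-1.25, 3.5))
  p <- read_xyz_path(txt)
  expect_s3_class(p, "reaction_path")
  expect_equal(n_frames(p), 2L)
  expect_equal(p$energy, c(-1.25, 3.5))
  expect_equal(unname(frame_coords(p, 1)), c1, tolerance = 1e-8)
  expect_equal(p$xi, c(0, 1))
  expect_equal(p$atoms$element, c("O", "P", "O"))
})

test_that("XYZ write/read round trip is the identity to printed precision", {
  set.seed(11)
  for (rep in 1:3) {
    coords <- lapply(1:4, function(f) matrix(rnorm(5 * 3, sd = 3), 5, 3))
    p <- make_path(coords, c("P", "O", "O", "H", "Mg"),
                   energy = rnorm(4), xi = c(0, 0.5, 1.7, 2.0))
    f <- withr::local_tempfile(fileext = ".xyz")
    write_xyz_path(p, f)
    q <- read_xyz_path(f, xi = p$xi)
    expect_equal(q$coords, p$coords, tolerance = 1e-5)
    expect_equal(q$energy, p$energy, tolerance = 1e-5)
    expect_equal(q$atoms$element, p$atoms$element)
  }
})

test_that("XYZ format errors name the offending frame and line", {
  c1 <- matrix(0, 3, 3); c2 <- matrix(1, 4, 3)
  bad <- paste(make_xyz_text(list(c1), c("O", "P", "O")),
               make_xyz_text(list(c2), c("O", "P", "O", "H")), sep = "\n")
  expect_error(read_xyz_path(bad), "frame 2")
  txt <- "3\ncomment\nO 0 0 0\nP 0 0 zz\nO 1 0 0\n3\nc\nO 0 0 0\nP 0 0 1\nO 1 0 0"
  expect_error(read_xyz_path(txt), "line 4")
  expect_error(read_xyz_path(make_xyz_text(list(c1), c("O", "P", "O"))),
               "at least 2 frames")
})

test_that("hartree energies are converted to kcal/mol on read", {
  c1 <- matrix(0, 2, 3); c2 <- matrix(1, 2, 3)
  txt <- make_xyz_text(list(c1, c2), c("O", "P"), energies = c(0, 0.01))
  p <- read_xyz_path(txt, energy_unit = "hartree")
  expect_equal(p$energy[2], 6.275095, tolerance = 1e-8)
})

test_that("bond-order tables are validated and canonicalized", {
  ok <- "frame,i,j,order\n0,1,2,1.0\n1,1,2,0.5"
  s <- read_bond_orders(ok)
  expect_equal(unname(s$values["1-2", ]), c(1.0, 0.5))

  flipped <- "frame,i,j,order\n0,2,1,0.7\n1,2,1,0.6"
  s2 <- read_bond_orders(flipped)
  expect_equal(rownames(s2$pairs), "1-2")
  expect_equal(unname(s2$pairs["1-2", ]), c(i = 1L, j = 2L), ignore_attr = TRUE)

  expect_error(read_bond_orders("frame,i,j,order\n0,1,2,-0.1"), "negative")
  expect_error(read_bond_orders("frame,i,j,order\n0,1,2,0.5\n0,2,1,0.4"),
               "duplicate")
  incomplete <- "frame,i,j,order\n0,1,2,0.5\n1,1,2,0.4\n0,1,3,0.2"
  expect_error(read_bond_orders(incomplete), "missing")
})

test_that("bond-order series round-trips through the long CSV", {
  s <- bond_order_series(rbind(c(1, 2), c(3, 1)),
                         rbind(c(0.9, 0.5, 0.1), c(0.0, 0.4, 0.8)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_bond_orders(s, f)
  s2 <- read_bond_orders(f)
  expect_equal(s2$values, s$values, ignore_attr = TRUE)
  expect_equal(s2$pairs, s$pairs, ignore_attr = TRUE)
})

test_that("Wiberg blocks reassemble chunked columns into one symmetric matrix", {
  set.seed(3)
  n <- 11
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- round(runif(sum(upper.tri(m)), 0, 1.5), 4)
  m <- m + t(m)
  one_chunk <- parse_wiberg_block(make_wiberg_text(m, chunk_size = n))
  two_chunks <- parse_wiberg_block(make_wiberg_text(m, chunk_size = 4))
  expect_equal(unname(one_chunk), unname(two_chunks))
  mm <- m; diag(mm) <- 0
  expect_equal(unname(two_chunks), mm, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(isSymmetric(unname(two_chunks)))
  expect_true(all(two_chunks >= 0))
})

test_that("the shipped Wiberg dialect fixture parses", {
  f <- system.file("extdata", "wiberg_block_example.txt", package = "ircmech")
  M <- parse_wiberg_block(f, frame_index = 0)
  expect_equal(dim(M), c(12L, 12L))
  expect_equal(M[1, 2], 0.8)
  frag <- wiberg_to_series(M, rbind(c(2, 1), c(1, 3)))
  expect_equal(unname(frag$values[, 1]), c(0.8, 0.12))
})

test_that("truncated or empty Wiberg blocks raise parse errors", {
  expect_error(parse_wiberg_block(""), "no 'Wiberg")
  txt <- paste(" Wiberg bond index matrix in the NAO basis:", "",
               "         Atom       1       2       3",
               "      1.  P   0.0000  0.8000", sep = "\n")
  expect_error(parse_wiberg_block(txt), "expected 3 columns")
})

test_that("charge tables validate per-frame conservation", {
  s <- read_charges("frame,atom_index,charge\n0,1,0.5\n0,2,-0.5")
  expect_equal(unname(colSums(s)), 0)
  drifting <- "frame,atom_index,charge\n0,1,0.5\n0,2,-0.5\n1,1,0.55\n1,2,-0.5"
  expect_warning(s2 <- read_charges(drifting, charge_sum_tol = 0.01), "drifts")
  expect_match(attr(s2, "validation"), "0.05")
  f <- withr::local_tempfile(fileext = ".csv")
  write_charges(s, f)
  expect_equal(unname(unclass(read_charges(f))), unname(unclass(s)))
})

test_that("PDB atom tables resolve the names used in analysis configs", {
  skip_if_not_installed("bio3d")
  pdb <- paste(
    "ATOM      1  PG  ATP A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  O3B ATP A   1       1.600   0.000   0.000  1.00  0.00           O",
    "ATOM      3  OG  SER A   5       3.600   0.000   0.000  1.00  0.00           O",
    "END", sep = "\n")
  at <- read_pdb_atoms(pdb)
  expect_equal(at$name, c("PG", "O3B", "OG"))
  expect_equal(at$element, c("P", "O", "O"))
  expect_equal(at$residue[1], "ATP1")
})
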