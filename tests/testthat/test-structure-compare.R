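test_that("C-alpha loading respects file order, altlocs and missing atoms", {
  set.seed(1)
  xyz <- random_chain_xyz(3)
  path <- write_pdb_fixture(xyz, c("ALA", "GLY", "TRP"))
  ch <- read_calpha(path)
  expect_identical(nrow(ch), 3L)
  expect_identical(ch$aa, c("A", "G", "W"))
  expect_equal(as.matrix(ch[, c("x", "y", "z")]), xyz, tolerance = 1e-3,
               ignore_attr = TRUE)

  # altloc A/B on residue 2: the first record wins
  alt_path <- write_pdb_fixture(xyz, c("ALA", "GLY", "TRP"),
                                altloc = list(" ", c("A", "B"), " "))
  suppressMessages(ch2 <- read_calpha(alt_path))
  expect_identical(nrow(ch2), 3L)
  expect_equal(ch2$x[2], xyz[2, 1], tolerance = 1e-3)

  # one missing C-alpha: residue skipped
  miss_path <- write_pdb_fixture(xyz, c("ALA", "GLY", "TRP"), skip_ca = 2)
  ch3 <- read_calpha(miss_path)
  expect_identical(nrow(ch3), 2L)
  expect_identical(ch3$resno, c(1L, 3L))

  expect_error(read_calpha(path, chain = "Z"), "available")
  expect_error(read_calpha(path, model = 5), "model")
  expect_error(read_calpha(tempfile()), "not found")
})

test_that("residue mapping matches identity, offsets and an independent aligner", {
  set.seed(2)
  n <- 30L
  aa3 <- sample(aa3_alphabet, n, replace = TRUE)
  xyz <- random_chain_xyz(n)
  a <- read_calpha(write_pdb_fixture(xyz, aa3))
  pairs <- map_residues(a, a)
  expect_identical(pairs$idx_a, seq_len(n))
  expect_identical(pairs$idx_b, seq_len(n))

  b <- a[-(1:5), ]
  off <- map_residues(a, b)
  expect_identical(nrow(off), n - 5L)
  expect_identical(off$idx_a, off$idx_b + 5L)

  # random low-identity pair against Biostrings' Needleman-Wunsch
  set.seed(3)
  sa <- sample(c("A", "R", "N", "D", "C", "Q", "E", "G"), 40, replace = TRUE)
  sb <- sample(c("A", "R", "N", "D", "C", "Q", "E", "G"), 35, replace = TRUE)
  mine <- map_residues(list(aa = sa), list(aa = sb))
  letters_all <- unique(c(sa, sb))
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  oracle <- Biostrings::pairwiseAlignment(
    paste(sa, collapse = ""), paste(sb, collapse = ""), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  expect_equal(attr(mine, "score"), Biostrings::score(oracle))
  expect_identical(nrow(mine),
                   Biostrings::nmatch(oracle) + Biostrings::nmismatch(oracle))
})

test_that("Kabsch superposition is exact under rigid motion and properly oriented", {
  set.seed(4)
  a <- random_chain_xyz(12)
  fit0 <- kabsch(a, a)
  expect_equal(fit0$rmsd, 0)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)

  rot <- random_rotation()
  trans <- c(3, -2, 7)
  b <- apply_rigid(a, rot, trans)
  fit <- kabsch(a, b)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # recovered transform maps b back onto a
  back <- sweep(b %*% t(fit$rotation), 2, -fit$translation)
  expect_equal(back, a, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(kabsch(a[1:2, ], b[1:2, ]), "3 point")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch(line, line + 1), "Degenerate")
})

test_that("Kabsch RMSD is symmetric, rigid-invariant, optimal, and matches bio3d", {
  set.seed(5)
  for (rep in 1:3) {
    a <- random_chain_xyz(8)
    b <- a + matrix(rnorm(24, sd = 1), ncol = 3)
    f_ab <- kabsch(a, b)
    f_ba <- kabsch(b, a)
    expect_lt(abs(f_ab$rmsd - f_ba$rmsd), 1e-9)
    expect_lte(f_ab$rmsd, f_ab$rmsd_unsuperposed + 1e-12)
    # invariance to a rigid premotion of either input
    pre <- apply_rigid(b, random_rotation(), c(-4, 9, 2))
    expect_lt(abs(kabsch(a, pre)$rmsd - f_ab$rmsd), 1e-9)
    # independent cross-check: bio3d's least-squares fit (rounds to 3 d.p.)
    oracle <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_lt(abs(f_ab$rmsd - oracle), 6e-4)
  }
})

test_that("optimizer RMSD matches the rotation-grid brute force on 5-point sets", {
  set.seed(6)
  for (rep in 1:2) {
    a <- random_chain_xyz(5, sd = 3)
    b <- a + matrix(rnorm(15, sd = 0.8), ncol = 3)
    fit <- kabsch(a, b)
    oracle <- grid_search_rmsd(a, b)
    expect_lt(abs(fit$rmsd - oracle), 1e-3)
    expect_lte(fit$rmsd, oracle + 1e-9)
  }
})

test_that("chain superposition aligns sequences and trim mode rejects outliers", {
  set.seed(7)
  n <- 40L
  aa3 <- sample(aa3_alphabet, n, replace = TRUE)
  xyz <- random_chain_xyz(n, sd = 8)
  a <- read_calpha(write_pdb_fixture(xyz, aa3))
  moved <- apply_rigid(xyz, random_rotation(), c(5, 5, -5))
  moved[c(10, 20), ] <- moved[c(10, 20), ] + 25   # two gross outliers
  b <- read_calpha(write_pdb_fixture(moved, aa3))

  all_fit <- superpose_chains(a, b, mode = "all")
  expect_identical(all_fit$n_pairs, n)
  expect_gt(all_fit$rmsd, 1)

  trim_fit <- superpose_chains(a, b, mode = "trim", trim_cutoff = 2)
  expect_identical(trim_fit$n_pairs, n - 2L)
  # residual limited only by the 0.001-Angstrom PDB coordinate precision
  expect_lt(trim_fit$rmsd, 5e-3)

  tmp_a <- write_pdb_fixture(xyz, aa3)
  tmp_b <- write_pdb_fixture(moved, aa3)
  tab <- structure_rmsd(tmp_a, tmp_b)
  expect_identical(names(tab),
                   c("n_pairs", "rmsd_all", "n_pairs_trim", "rmsd_trim"))
  expect_lt(tab$rmsd_trim, tab$rmsd_all)
})
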