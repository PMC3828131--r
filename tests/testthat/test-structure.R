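toy_model <- function(per_res) {
  # per_res: list of n x 3 matrices (heavy-atom coordinates), one per position
  atoms <- do.call(rbind, lapply(seq_along(per_res), function(p) {
    xyz <- per_res[[p]]
    data.frame(pos = p, res_name = "ALA",
               atom = paste0("C", seq_len(nrow(xyz))), element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = "A")
  }))
  structure_model(atoms)
}

test_that("burial bins follow the printed cutoffs", {
  expect_equal(burial_class(c(0, 5, 8)), rep("exposed", 3))
  expect_equal(burial_class(c(9, 10, 14)), rep("intermediate", 3))
  expect_equal(burial_class(c(15, 20)), rep("buried", 2))
})

test_that("pair burial mapping matches the six-way rule and is symmetric", {
  expect_equal(pair_burial_class("buried", "buried"), "buried")
  expect_equal(pair_burial_class("buried", "intermediate"), "buried")
  expect_equal(pair_burial_class("exposed", "buried"), "intermediate")
  expect_equal(pair_burial_class("intermediate", "intermediate"), "intermediate")
  expect_equal(pair_burial_class("exposed", "intermediate"), "exposed")
  expect_equal(pair_burial_class("exposed", "exposed"), "exposed")
  for (a in c("exposed", "intermediate", "buried")) {
    for (b in c("exposed", "intermediate", "buried")) {
      expect_equal(pair_burial_class(a, b), pair_burial_class(b, a))
    }
  }
})

test_that("C-beta neighbor counts respect the strict 8 A rule", {
  # CB atoms placed on a line at 0, 5, 7.9, 16 along x
  atoms <- data.frame(pos = 1:4, res_name = "ALA", atom = "CB",
                      element = "C", x = c(0, 5, 7.9, 16), y = 0, z = 0,
                      chain = "A")
  counts <- cb_neighbor_counts(structure_model(atoms))
  expect_equal(unname(counts), c(2L, 2L, 2L, 0L))
  # atom order within residues does not matter
  counts2 <- cb_neighbor_counts(structure_model(atoms[4:1, ]))
  expect_equal(unname(counts2[as.character(1:4)]),
               unname(counts[as.character(1:4)]))
})

test_that("glycine gets a virtual C-beta consistent with real geometry", {
  # a residue with full backbone + CB, then the same with CB stripped:
  # the virtual CB must sit close to the real one
  n <- c(1.46, 0, 0); ca <- c(0, 0, 0); c_ <- c(-0.55, 1.42, 0)
  with_cb <- covarcomp:::virtual_cb(n, ca, c_)
  atoms <- data.frame(pos = 1, res_name = "GLY",
                      atom = c("N", "CA", "C"), element = c("N", "C", "C"),
                      x = c(n[1], ca[1], c_[1]), y = c(n[2], ca[2], c_[2]),
                      z = c(n[3], ca[3], c_[3]), chain = "A")
  two <- rbind(atoms, within(atoms, {pos <- 2; x <- x + 6}))
  counts <- cb_neighbor_counts(structure_model(two))
  expect_equal(unname(counts), c(1L, 1L))  # virtual CBs ~6 A apart, < 8
  expect_equal(sqrt(sum(with_cb^2)), 1.53, tolerance = 0.05)  # CA-CB bond
})

test_that("minimum heavy-atom distance matches brute force", {
  m <- toy_model(list(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)))
  expect_equal(min_heavy_atom_distance(m, 1, 2), 5)  # 3-4-5 triangle
  expect_equal(min_heavy_atom_distance(m, 1, 1), 0)

  set.seed(61)
  res <- lapply(1:4, function(i) matrix(rnorm(9, mean = 3 * i), 3))
  m2 <- toy_model(res)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      brute <- Inf
      for (p in 1:3) for (q in 1:3) {
        brute <- min(brute, sqrt(sum((res[[i]][p, ] - res[[j]][q, ])^2)))
      }
      expect_equal(min_heavy_atom_distance(m2, i, j), brute,
                   tolerance = 1e-12)
      expect_equal(min_heavy_atom_distance(m2, j, i),
                   min_heavy_atom_distance(m2, i, j))
    }
  }
  expect_error(min_heavy_atom_distance(m2, 1, 9), "missing")
})

test_that("interface flags use a strict 6 A heavy-atom cutoff", {
  m <- toy_model(list(matrix(c(0, 0, 0), 1), matrix(c(20, 0, 0), 1)))
  partner <- matrix(c(5.9, 0, 0), 1)
  flags <- interface_positions(m, partner)
  expect_true(flags["1"])    # 5.9 < 6
  expect_false(flags["2"])   # 14.1 away
  expect_false(interface_positions(m, matrix(c(6.0, 0, 0), 1))["1"])
  expect_error(interface_positions(m, matrix(numeric(0), 0, 3)), "empty")

  # brute-force scan agreement on a toy complex
  set.seed(67)
  res <- lapply(1:5, function(i) matrix(rnorm(6, mean = 2 * i), 2))
  mc <- toy_model(res)
  part <- matrix(rnorm(9, mean = 5), 3)
  flags2 <- interface_positions(mc, part)
  for (i in 1:5) {
    brute <- FALSE
    for (p in 1:2) for (q in 1:3) {
      if (sqrt(sum((res[[i]][p, ] - part[q, ])^2)) < 6) brute <- TRUE
    }
    expect_equal(unname(flags2[as.character(i)]), brute)
  }
})

test_that("superposition RMSD removes rigid motion exactly", {
  set.seed(71)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(p, p), 0)
  for (rep in 1:20) {
    r <- random_rotation()
    q <- p %*% t(r) + matrix(rnorm(3), 10, 3, byrow = TRUE)
    expect_lt(superpose_rmsd(p, q), 1e-6)
  }
  # known displacement of a 3-point set: one point moved along a direction
  # orthogonal to the plane through the centroid cannot be rotated away
  tri <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  moved <- tri
  moved[3, ] <- c(0, 2, 0)  # stretch one vertex
  got <- superpose_rmsd(tri, moved)
  expect_gt(got, 0)
  # oracle: numerical minimization over Euler angles from several starts
  a1 <- sweep(tri, 2, colMeans(tri))
  a2 <- sweep(moved, 2, colMeans(moved))
  euler <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    rx %*% ry %*% rz
  }
  obj <- function(ang) sqrt(mean(rowSums((a1 %*% euler(ang) - a2)^2)))
  best <- min(vapply(1:20, function(s) {
    stats::optim(runif(3, 0, 2 * pi), obj)$value
  }, numeric(1)))
  expect_equal(got, best, tolerance = 1e-4)
})

test_that("ensemble structural variation behaves at its fixed points", {
  base <- generate_structure(12, seed = 5)
  ens0 <- generate_structure_ensemble(12, n_models = 5, jitter = 0, seed = 5)
  expect_equal(structural_variation(ens0), 0)

  # rigidly transformed copies: variation still 0
  rot_model <- function(model, r, shift) {
    at <- model$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(r)
    at$x <- xyz[, 1] + shift[1]
    at$y <- xyz[, 2] + shift[2]
    at$z <- xyz[, 3] + shift[3]
    structure_model(at)
  }
  set.seed(73)
  ens_rigid <- c(list(base), lapply(1:4, function(k) {
    rot_model(base, random_rotation(), rnorm(3, sd = 10))
  }))
  expect_lt(structural_variation(ens_rigid), 1e-6)

  # seeded subsampling is reproducible and respects `sample`
  ens <- generate_structure_ensemble(12, n_models = 15, jitter = 0.4, seed = 9)
  v1 <- structural_variation(ens, sample = 10, seed = 42)
  v2 <- structural_variation(ens, sample = 10, seed = 42)
  expect_equal(v1, v2)
  expect_gt(v1, 0)
  expect_error(structural_variation(ens[1]), "at least 2")
  bad <- c(ens[1:2], list(generate_structure(8, seed = 1)))
  expect_error(structural_variation(bad), "residue count")
})
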