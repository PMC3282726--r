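test_that("the tetrahedron is regular with the documented vertex coordinates", {
  v <- fj_vertices()
  expect_equal(v["A", ], c(x = -1, y = 1, z = -1))
  expect_equal(v["C", ], c(x = 1, y = -1, z = -1))
  d <- dist(v)
  expect_true(all(abs(d - 2 * sqrt(2)) < 1e-12))
  expect_equal(unname(colMeans(v)), c(0, 0, 0))
})

test_that("FJ-Curve follows the midpoint map and stays in the tetrahedron", {
  # G-homopolymer converges to the G vertex: P_k = (1 - 2^-k) (1,1,1)
  crv <- fj_curve("GGG")
  expect_equal(unname(crv$points[1, ]), c(0, 0, 0))
  expect_equal(unname(crv$points[4, ]), rep(1 - 2^-3, 3))
  # hand iteration for "GT"
  gt <- fj_curve("GT")
  expect_equal(unname(gt$points[2, ]), c(0.5, 0.5, 0.5))
  expect_equal(unname(gt$points[3, ]), c(-0.25, -0.25, 0.75))
  # containment on random sequences, including a long one
  set.seed(12)
  for (len in c(1, 2, 17, 200, 2000)) {
    pts <- fj_curve(random_dna(len))$points
    expect_true(all(in_tetrahedron(pts)))
    expect_true(all(abs(pts) <= 1))
    # consecutive points never coincide
    expect_true(min(sqrt(rowSums(diff(pts)^2))) > 0)
  }
  expect_error(fj_curve("ACGU"), "encoding error")
})

test_that("centroid descriptors average the sequence points only", {
  expect_equal(unname(centroid_descriptors(fj_curve("GT"))),
               c(0.125, 0.125, 0.625))
  # length-1 sequence: centroid is P_1 itself
  expect_equal(unname(centroid_descriptors(fj_curve("A"))), c(-0.5, 0.5, -0.5))
  # homopolymer centroid approaches the vertex monotonically
  cen20 <- centroid_descriptors(fj_curve(strrep("G", 20)))
  cen60 <- centroid_descriptors(fj_curve(strrep("G", 60)))
  expect_true(all(cen60 > cen20) && all(cen60 < 1))
  # G vs C mirrors the y,z signs and keeps x
  cg <- centroid_descriptors(fj_curve(strrep("C", 20)))
  expect_equal(unname(cg), unname(cen20) * c(1, -1, -1))
})

test_that("L/L and M/M matrices match hand computations and identities", {
  right_angle <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  ll <- ll_matrix(right_angle)
  mm <- mm_matrix(right_angle)
  expect_equal(ll[1, 3], sqrt(2) / 2)
  expect_equal(mm[1, 3], sqrt(2) / 2)
  expect_equal(ll[1, 2], 1)            # adjacent points: Euclid = path
  expect_equal(mm[2, 3], 1)            # adjacent points: segment length
  expect_true(isSymmetric(unclass(ll)))
  expect_equal(unname(diag(ll)), rep(0, 3))

  # random curve: entries in (0,1], 1 iff straight sub-path
  set.seed(31)
  crv <- fj_curve(random_dna(60))
  llr <- ll_matrix(crv)
  off <- llr[upper.tri(llr)]
  expect_true(all(off > 0 & off <= 1 + 1e-12))

  # equal-segment zigzag: mm = d * ll entrywise
  zig <- cbind(0:5, c(0, 1, 0, 1, 0, 1), 0)  # segments all sqrt(2)
  expect_equal(unclass(mm_matrix(zig)), sqrt(2) * unclass(ll_matrix(zig)),
               ignore_attr = TRUE)
})

test_that("leading eigenvalues match closed forms and dense-solver oracle", {
  expect_equal(leading_eigenvalue(rbind(c(0, 1), c(1, 0))), 1)
  # collinear equally spaced points: L/L is all-ones off-diagonal, eigenvalue N
  n <- 7
  line <- cbind(0:n, 0, 0)
  expect_equal(leading_eigenvalue(ll_matrix(line)), n, tolerance = 1e-10)
  # Rayleigh bound (ones vector) and row-sum bound for non-negative matrices
  set.seed(9)
  for (i in 1:10) {
    m <- ll_matrix(fj_curve(random_dna(sample(5:40, 1))))
    lam <- leading_eigenvalue(m)
    expect_gte(lam + 1e-10, mean(rowSums(m)))
    expect_lte(lam - 1e-10, max(rowSums(m)))
    expect_equal(lam, max(eigen(unclass(m))$values), tolerance = 1e-8)
  }
  expect_error(leading_eigenvalue(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("the FJ characterization is the documented 5-vector", {
  v <- fj_feature_vector("A")
  expect_length(v, 5L)
  expect_equal(unname(v[1:3]), c(-0.5, 0.5, -0.5))
  # 2x2 ratio matrices of a 1 bp curve: lambda = single off-diagonal entry
  expect_equal(unname(v[4]), 1)                      # straight 2-point path
  expect_equal(unname(v[5]), sqrt(3) / 2)            # |P_1 - P_0| = sqrt(3)/2
  # C-rich sequence clusters near vertex C
  f <- fj_feature_vector("GCCTCCGCCCAGACTTCTTC")
  cen <- f[1:3]
  d <- sqrt(rowSums((fj_vertices() -
                       matrix(cen, 4, 3, byrow = TRUE))^2))
  expect_equal(names(which.min(d)), "C")
  # reversal sensitivity: the curve is order-dependent
  s <- "AACGTGGTC"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_false(isTRUE(all.equal(fj_curve(s)$points,
                                fj_curve(rev_s)$points[rev(1:10), ])))
})

test_that("PCA drops low-variance components and round-trips the fit set", {
  set.seed(20)
  # data varying along one axis -> exactly 1 retained component
  x1 <- cbind(rnorm(50), 0.5, -1)
  t1 <- fit_pca(x1)
  expect_equal(t1$retained, 1L)
  # threshold 0: every positive-variance component kept
  x2 <- matrix(rnorm(100 * 5), 100)
  t0 <- fit_pca(x2, threshold = 0)
  expect_equal(t0$retained, 5L)
  expect_true(all(t0$ratios >= 0) && abs(sum(t0$ratios) - 1) < 1e-12)
  # retained ratios each >= threshold; reconstruction error = dropped ratios
  x3 <- cbind(matrix(rnorm(200 * 3), 200) %*% matrix(rnorm(9), 3),
              0.02 * rnorm(200), 0.02 * rnorm(200))
  tr <- fit_pca(x3, threshold = 0.01)
  expect_true(all(tr$ratios[seq_len(tr$retained)] >= 0.01))
  z <- scale(x3, center = tr$center, scale = tr$scale)
  recon <- apply_pca(tr, x3) %*% t(tr$rotation)
  rel_err <- sum((z - recon)^2) / sum(scale(z, scale = FALSE)^2)
  expect_equal(rel_err, sum(tr$ratios[-seq_len(tr$retained)]),
               tolerance = 1e-8)
  # against a brute-force covariance eigendecomposition
  ev <- eigen(cov(z), symmetric = TRUE)$values
  expect_equal(tr$ratios, ev / sum(ev), tolerance = 1e-10)

  # projection of the mean is the zero vector
  expect_equal(unname(apply_pca(tr, tr$center)), rep(0, tr$retained))
  expect_error(fit_pca(matrix(1, 5, 3)), "degenerate variance")
  expect_error(apply_pca(tr, 1:3), "dimension mismatch")
  # JSON persistence round-trip
  p <- withr::local_tempfile(fileext = ".json")
  write_pca_transform(tr, p)
  back <- read_pca_transform(p)
  expect_equal(unname(apply_pca(back, x3[3, ])), unname(apply_pca(tr, x3[3, ])),
               tolerance = 1e-12)
})
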