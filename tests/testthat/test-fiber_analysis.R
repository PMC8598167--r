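# Fiber-level statistics against closed forms and brute-force oracles.

test_that("sedimentation coefficient reproduces the mononucleosome limits", {
  one <- matrix(0, 1, 3)
  expect_equal(sedimentation_coefficient(
    one, sedimentation_params(lh_conc = 1)), 12)
  expect_equal(sedimentation_coefficient(
    one, sedimentation_params(lh_conc = 0)), 11.1)
  # two cores 10 nm apart, no LH: 11.1 * (1 + 2.75 * 0.2) = 17.205
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(sedimentation_coefficient(
    two, sedimentation_params(lh_conc = 0)), 17.205, tolerance = 1e-12)
  expect_error(sedimentation_coefficient(
    rbind(c(0, 0, 0), c(0, 0, 0)), sedimentation_params(lh_conc = 0)),
    "coincident")
})

test_that("radius of gyration matches symmetry cases and brute force", {
  expect_equal(radius_of_gyration(matrix(5, 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(10, 0, 0))), 5)
  set.seed(12)
  p <- matrix(rnorm(150, sd = 8), 50, 3)
  ctr <- colMeans(p)
  brute <- sqrt(sum(apply(p, 1, function(r) sum((r - ctr)^2))) / 50)
  expect_equal(radius_of_gyration(p), brute, tolerance = 1e-12)
})

test_that("axis length and packing ratio satisfy analytic cases and scaling", {
  # 20 collinear cores spanning 110 nm at zero smoothing
  line <- cbind(seq(0, 110, length.out = 20), 0, 0)
  expect_equal(fiber_axis_length(line, spar = 0), 110, tolerance = 1e-6)
  expect_equal(packing_ratio(line, spar = 0), 2, tolerance = 1e-6)
  # doubling coordinates doubles length and halves the packing ratio
  set.seed(4)
  pts <- cbind(cumsum(runif(15, 2, 4)), cumsum(rnorm(15)), cumsum(rnorm(15)))
  l1 <- fiber_axis_length(pts, spar = 0.3)
  expect_equal(fiber_axis_length(2 * pts, spar = 0.3), 2 * l1,
               tolerance = 1e-9)
  expect_equal(packing_ratio(2 * pts, spar = 0.3),
               packing_ratio(pts, spar = 0.3) / 2, tolerance = 1e-9)
  # noisy helix arc length approaches a dense polyline oracle as spar -> 0
  t <- seq(0, 6 * pi, length.out = 60)
  helix <- cbind(10 * cos(t), 10 * sin(t), 2 * t)
  dense_t <- seq(0, 6 * pi, length.out = 6000)
  oracle <- sum(sqrt(rowSums(diff(
    cbind(10 * cos(dense_t), 10 * sin(dense_t), 2 * dense_t))^2)))
  expect_lt(abs(fiber_axis_length(helix, spar = 0) - oracle) / oracle, 0.02)
  expect_error(fiber_axis_length(matrix(0, 1, 3)), "at least 2")
})

test_that("alpha-shape volume matches hulls of known solids", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(alpha_shape_volume(cube, Inf), 1, tolerance = 1e-6)
  # random tetrahedron: |det| / 6
  set.seed(9)
  tet <- matrix(rnorm(12), 4, 3)
  vol_tet <- abs(det(cbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                           tet[4, ] - tet[1, ]))) / 6
  expect_equal(alpha_shape_volume(tet, Inf), vol_tet, tolerance = 1e-6)
  # volume is monotone non-decreasing in alpha
  set.seed(10)
  cloud <- matrix(rnorm(90, sd = 5), 30, 3)
  alphas <- c(2, 4, 8, 16, Inf)
  vols <- vapply(alphas, function(a) alpha_shape_volume(cloud, a), 1.0)
  expect_true(all(diff(vols) >= -1e-9))
  expect_error(alpha_shape_volume(cbind(rnorm(10), rnorm(10), 0)),
               "coplanar")
})

test_that("convex-hull volume matches a brute-force facet-enumeration oracle", {
  # oracle: enumerate all point triples; a triple is a hull facet when every
  # other point lies (weakly) on one side; volume by the divergence theorem
  hull_volume_oracle <- function(p) {
    n <- nrow(p)
    ctr <- colMeans(p)
    vol <- 0
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      nrm <- pracma_cross(p[j, ] - p[i, ], p[k, ] - p[i, ])
      if (sum(nrm^2) < 1e-18) next
      s <- drop((p %*% nrm) - sum(nrm * p[i, ]))
      if (all(s <= 1e-9) || all(s >= -1e-9)) {
        # the centroid is interior, so summing |tet(centroid, facet)| over
        # all hull facets gives the hull volume
        vol <- vol + abs(det(cbind(p[i, ] - ctr, p[j, ] - ctr,
                                   p[k, ] - ctr))) / 6
      }
    }
    vol
  }
  pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])
  set.seed(21)
  p <- matrix(rnorm(36, sd = 3), 12, 3)  # generic position: no coplanar ties
  expect_equal(alpha_shape_volume(p, Inf), hull_volume_oracle(p),
               tolerance = 1e-6)
})

test_that("density-based clustering matches the analytic cases and an oracle", {
  # 10 cores mutually within 20 nm: one cluster of size 10
  set.seed(2)
  tight <- matrix(rnorm(30, sd = 3), 10, 3)
  cl <- cluster_nucleosomes(tight)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$max_size, 10L)
  # 25 nm line spacing: nobody has 3 neighbors within 20 nm
  line <- cbind(seq(0, 225, by = 25), 0, 0)
  cl2 <- cluster_nucleosomes(line)
  expect_equal(cl2$n_clusters, 0)
  expect_true(all(cl2$labels == 0))
  # independent oracle: connected components over core points
  oracle_dbscan <- function(p, eps, minn) {
    d <- as.matrix(dist(p)); diag(d) <- Inf
    core <- rowSums(d <= eps) >= minn
    lab <- integer(nrow(p)); cl <- 0
    adj <- d <= eps
    for (s in which(core)) {
      if (lab[s] != 0) next
      cl <- cl + 1
      comp <- s
      repeat {
        grow <- which(core & lab == 0 &
                        apply(adj[, comp, drop = FALSE], 1, any))
        grow <- setdiff(grow, comp)
        if (!length(grow)) break
        lab[grow] <- cl
        comp <- c(comp, grow)
      }
      lab[s] <- cl
    }
    for (b in which(!core & lab == 0)) {
      cn <- which(core & adj[b, ])
      if (length(cn)) lab[b] <- lab[cn[which.min(d[b, cn])]]
    }
    lab
  }
  set.seed(33)
  p <- matrix(rnorm(600, sd = 18), 200, 3)
  got <- dbscan_labels(p, 20, 3)
  want <- oracle_dbscan(p, 20, 3)
  # same partition up to label renaming
  expect_equal(got == 0, want == 0)
  tab <- table(got[got > 0], want[got > 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("neighbor profile I(k) matches diagonal sums and normalizes to 1", {
  # only first-off-diagonal entries: I(1) = 1
  m <- matrix(0, 6, 6)
  for (i in 1:5) { m[i, i + 1] <- 2; m[i + 1, i] <- 2 }
  prof <- neighbor_profile(m)
  expect_equal(prof$intensity[prof$k == 1], 1)
  expect_equal(sum(prof$intensity), 1)
  # uniform map: I(k) proportional to the number of (i, i+k) elements
  u <- matrix(1, 7, 7)
  pu <- neighbor_profile(u)
  counts <- (7 - pu$k)
  expect_equal(pu$intensity, counts / sum(counts), tolerance = 1e-12)
  # random symmetric map against a direct diagonal-sum oracle
  set.seed(8)
  r <- matrix(runif(64), 8); r <- r + t(r); diag(r) <- 0
  pr <- neighbor_profile(r)
  for (k in 1:7) {
    i <- seq_len(8 - k)
    expect_equal(pr$intensity[pr$k == k],
                 2 * sum(r[cbind(i, i + k)]) / sum(r), tolerance = 1e-12)
  }
  expect_equal(sum(pr$intensity), 1, tolerance = 1e-12)
  expect_error(neighbor_profile(matrix(0, 4, 4)), "all-zero")
})
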