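# Synthetic generators: nucleosome tracks, contact pairs, anchors, volumes.

test_that("nucleosome tracks respect spacing, flags and determinism", {
  # zero-jitter case: all inter-dyad distances exactly at the repeat length
  tr <- generate_nucleosome_track(
    fiber_spec(200, mean_repeat_length = 165, repeat_jitter_sd = 0))
  expect_equal(nrow(tr), 200)
  expect_true(all(diff(tr$dyad) == 165))

  # degenerate single nucleosome, no flags
  tr1 <- generate_nucleosome_track(fiber_spec(1, acetylation_density = 0))
  expect_equal(nrow(tr1), 1)
  expect_false(any(tr1$acetylated))

  # LH flags drawn at the stated density (0.29 on 228 nucleosomes);
  # binomial 3-sigma band around the expectation of ~66
  tr2 <- generate_nucleosome_track(
    fiber_spec(228, lh_density = 0.29, seed = 42))
  expected <- 228 * 0.29
  tol <- 3 * sqrt(228 * 0.29 * 0.71)
  expect_lt(abs(sum(tr2$lh) - expected), tol)

  # jittered tracks never violate the 147 bp core footprint
  for (s in 1:5) {
    trj <- generate_nucleosome_track(
      fiber_spec(150, repeat_jitter_sd = 30, seed = s))
    expect_true(all(diff(trj$dyad) >= 147))
  }

  # pure function of spec + seed
  a <- generate_nucleosome_track(fiber_spec(50, repeat_jitter_sd = 10,
                                            acetylation_density = 0.3,
                                            lh_density = 0.2, seed = 9))
  b <- generate_nucleosome_track(fiber_spec(50, repeat_jitter_sd = 10,
                                            acetylation_density = 0.3,
                                            lh_density = 0.2, seed = 9))
  expect_identical(a, b)

  # NFRs insert gaps with no dyads
  trn <- generate_nucleosome_track(
    fiber_spec(50, nfr_positions = list(c(3000, 500)), seed = 2))
  gap_at <- which(diff(trn$dyad) > 400)
  expect_length(gap_at, 1)

  expect_error(fiber_spec(10, acetylation_density = 1.2), "acetylation")
  expect_error(fiber_spec(10, lh_density = -0.1), "lh_density")
})

test_that("track round-trips through its tab-separated format", {
  tr <- generate_nucleosome_track(
    fiber_spec(30, acetylation_density = 0.4, lh_density = 0.3, seed = 5))
  path <- tempfile(fileext = ".tsv")
  write_track(tr, path)
  back <- read_track(path)
  expect_equal(back$dyad, tr$dyad)
  expect_equal(back$acetylated, tr$acetylated)
  expect_equal(back$lh, tr$lh)
})

test_that("contact pairs follow the configured mixture", {
  cs <- c(chrA = 5e5)
  # all neighbor mass at k=1, repeat 165, no jitter or other components:
  # the distance histogram mode sits at 165 bp
  sp <- contact_spec(cs, 2e4, neighbor_weights = 1, repeat_length = 165,
                     distance_jitter_sd = 0, long_range_weight = 0,
                     background_weight = 0, infacing_fraction = 0, seed = 3)
  ps <- generate_contact_pairs(sp)
  expect_equal(nrow(ps), 2e4)
  d <- ps$pos2 - ps$pos1
  expect_equal(as.integer(names(which.max(table(d)))), 165)
  expect_true(all(ps$pos1 >= 1 & ps$pos2 <= 5e5))
  expect_true(all(ps$pos1 <= ps$pos2))

  # infacing_fraction = 0: classifier finds zero in-facing pairs
  cls <- classify_and_filter_pairs(ps, drop_infacing = FALSE)
  expect_equal(sum(cls$orientation == "in"), 0)

  # determinism
  expect_identical(generate_contact_pairs(sp), generate_contact_pairs(sp))

  # empirical mixture matches configuration: chi-square over neighbor modes
  sp2 <- contact_spec(cs, 1e5, neighbor_weights = c(2, 1, 1), repeat_length = 200,
                      distance_jitter_sd = 0, long_range_weight = 0,
                      background_weight = 0, infacing_fraction = 0, seed = 8)
  ps2 <- generate_contact_pairs(sp2)
  counts <- table(factor(ps2$pos2 - ps2$pos1, levels = c(200, 400, 600)))
  chi <- stats::chisq.test(as.integer(counts), p = c(0.5, 0.25, 0.25))
  expect_gt(chi$p.value, 0.001)

  expect_error(contact_spec(cs, 0), "n_pairs")
  expect_error(contact_spec(c(chrA = 1e5), 10, anchor_loop_fraction = 0.1),
               "anchor")
})

test_that("in-facing fraction is honored within binomial error", {
  sp <- contact_spec(c(chrA = 1e6), 1e5, infacing_fraction = 0.3, seed = 11)
  ps <- generate_contact_pairs(sp)
  cls <- classify_and_filter_pairs(ps, drop_infacing = TRUE)
  surviving <- nrow(cls) / nrow(ps)
  tol <- 3 * sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(surviving - 0.7), tol)
})

test_that("anchors are sorted, spaced and deterministic", {
  expect_equal(nrow(generate_anchors(c(chrA = 1e6), 0)), 0)
  a <- generate_anchors(c(chrA = 1e6), 5, min_spacing = 4e4, seed = 2)
  expect_equal(nrow(a), 5)
  expect_true(all(diff(a$pos) >= 4e4))
  expect_false(is.unsorted(a$pos))
  expect_identical(a, generate_anchors(c(chrA = 1e6), 5, min_spacing = 4e4,
                                       seed = 2))
  expect_error(generate_anchors(c(chrA = 1e5), 10, min_spacing = 5e4),
               "cannot place")
  # BED round trip
  path <- tempfile(fileext = ".bed")
  write_anchors_bed(a, path)
  expect_equal(read_anchors_bed(path)$pos, a$pos)
})

test_that("pairs round-trip through the pairs text dialect", {
  sp <- contact_spec(c(chrA = 1e5, chrB = 5e4), 500, seed = 4)
  ps <- generate_contact_pairs(sp)
  path <- tempfile(fileext = ".pairs")
  write_pairs(ps, path)
  back <- read_pairs(path)
  expect_equal(back$pos1, ps$pos1)
  expect_equal(back$strand2, ps$strand2)
  expect_equal(attr(back, "chrom_sizes"), attr(ps, "chrom_sizes"))
})

test_that("tube volumes match analytic cylinder volume and are deterministic", {
  vol <- generate_tube_volume(diameter = 30, length = 40, voxel_size = 2)
  v_analytic <- pi * 15^2 * 40 / 2^3          # voxels
  expect_lt(abs(sum(vol) - v_analytic) / v_analytic, 0.05)
  expect_error(generate_tube_volume(0, 40, 2), "diameter")
  expect_error(generate_tube_volume(10, 40, 12), "voxel_size")
  n1 <- generate_tube_volume(20, 30, 2, noise_fraction = 0.01, seed = 6)
  n2 <- generate_tube_volume(20, 30, 2, noise_fraction = 0.01, seed = 6)
  expect_identical(unclass(n1), unclass(n2))
})
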