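# Fiber construction and the energy model.

test_that("fiber topology bookkeeping follows the track", {
  tr <- generate_nucleosome_track(
    fiber_spec(12, mean_repeat_length = 165, seed = 1))
  tr$lh <- rep(c(TRUE, FALSE), 6)
  tr$acetylated <- rep(FALSE, 12)
  cfg <- build_initial_fiber(tr)
  expect_equal(cfg$n_cores, 12)
  expect_length(cfg$tails, 120)            # 2 copies x 5 kinds x 12 cores
  # LH beads (6 globular + 22 CTD for H1e) only on flagged cores
  lh_beads <- which(cfg$type == 4L)
  expect_equal(length(lh_beads), 6 * 28)
  expect_true(all(cfg$core_of[lh_beads] %in% which(tr$lh)))
  # 18 bp linkers at 9 bp/bead: 2 DNA beads between consecutive cores
  expect_equal(sum(cfg$type == 2L), 22)
  # tail bead counts follow the residue arithmetic (5/5/3/2/5 per copy)
  expect_equal(sum(cfg$type == 3L), 12 * 2 * (5 + 5 + 3 + 2 + 5))
  expect_error(build_initial_fiber(tr, b_twist = 5), "b_twist")
})

test_that("acetylation flags fold H3/H4 tails and stiffen their constants", {
  tr <- generate_nucleosome_track(fiber_spec(2, seed = 1))
  tr$acetylated <- c(TRUE, FALSE)
  cfg <- build_initial_fiber(tr)
  flagged <- vapply(cfg$tails, function(t) t$acetylated, TRUE)
  kinds <- vapply(cfg$tails, function(t) t$kind_name, "")
  cores <- vapply(cfg$tails, function(t) t$core, 1L)
  expect_true(all(kinds[flagged] %in% c("H3", "H4")))
  expect_true(all(cores[flagged] == 1L))
  expect_equal(sum(flagged), 4)            # 2 x H3 + 2 x H4 on core 1
  folded <- vapply(cfg$tails, function(t) t$folded, TRUE)
  expect_equal(folded, flagged)            # folded iff acetylation-flagged
  t1 <- cfg$tails[[which(flagged)[1]]]
  expect_equal(cfg$bond_k[t1$bond_ids[1]],
               cfg$ff$tail_h * cfg$ff$acetyl_rigidity)
})

test_that("bonded energy matches closed forms and a pure-R oracle", {
  # two beads at the equilibrium bond length: all components zero
  cfg <- minimal_config(pos = rbind(c(0, 0, 0), c(3, 0, 0)),
                        type = c(2L, 2L),
                        bonds = rbind(c(1L, 2L)), bond_l0 = 3, bond_k = 100)
  expect_equal(unname(bonded_energy(cfg)), c(0, 0, 0),
               ignore_attr = TRUE)
  # stretching one bond by dl: h dl^2 / 2
  cfg$pos[2, 1] <- 3.7
  expect_equal(unname(bonded_energy(cfg))[1], 100 * 0.7^2 / 2,
               tolerance = 1e-12)
  # straight triple has zero bend; right angle costs g (pi/2)^2 / 2
  cfg2 <- minimal_config(pos = rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0)),
                         type = rep(2L, 3),
                         angles = rbind(c(1L, 2L, 3L)), angle_g = 10)
  expect_equal(unname(bonded_energy(cfg2))[2], 10 * (pi / 2)^2 / 2,
               tolerance = 1e-12)
  # twist register off its set point
  cfg3 <- minimal_config(pos = matrix(0, 1, 3), type = 2L,
                         twist_phi = 0.3, twist_phi0 = 0.1, twist_s = 25)
  expect_equal(unname(bonded_energy(cfg3))[3], 25 * 0.2^2 / 2,
               tolerance = 1e-12)
  # full fiber against the independent R oracle
  tr <- generate_nucleosome_track(fiber_spec(4, seed = 2))
  fib <- build_initial_fiber(tr)
  fib$pos <- fib$pos + matrix(rnorm(length(fib$pos), sd = 0.05),
                              ncol = 3)
  expect_equal(unname(bonded_energy(fib)), unname(r_bonded_oracle(fib)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # NaN coordinates rejected
  fib$pos[5, 1] <- NaN
  expect_error(bonded_energy(fib), "NaN")
})

test_that("nonbonded energy matches the screened-Coulomb closed form", {
  # two unit charges 2 nm apart, LJ off: lB q1 q2 exp(-kr)/r exactly
  cfg <- minimal_config(pos = rbind(c(0, 0, 0), c(2, 0, 0)),
                        type = c(3L, 4L), charge = c(1, 1),
                        core_of = c(1L, 2L))
  e <- nonbonded_energy(cfg)
  expect_equal(unname(e[1]), 0.713 * exp(-1.27 * 2) / 2, tolerance = 1e-15)
  expect_equal(unname(e[2]), 0)
  # beyond the cutoff both terms vanish
  cfg$pos[2, 1] <- 7.5
  expect_equal(unname(nonbonded_energy(cfg)), c(0, 0), ignore_attr = TRUE)
  # LJ closed form at r with well depth and diameters set
  cfg2 <- minimal_config(pos = rbind(c(0, 0, 0), c(2.2, 0, 0)),
                         type = c(3L, 4L), diam = c(2, 3),
                         core_of = c(1L, 2L), lj_eps = 0.001)
  sr6 <- (2.5 / 2.2)^6
  expect_equal(unname(nonbonded_energy(cfg2)[2]),
               4 * 0.001 * (sr6^2 - sr6), tolerance = 1e-15)
})

test_that("Mg mode screens DNA-DNA electrostatics harder", {
  mk <- function(mg) minimal_config(pos = rbind(c(0, 0, 0), c(3, 0, 0)),
                                    type = c(2L, 2L), charge = c(-7, -7),
                                    core_of = c(1L, 2L), mg_mode = mg)
  e_mg <- nonbonded_energy(mk(TRUE))[1]
  e_no <- nonbonded_energy(mk(FALSE))[1]
  expect_lt(e_mg, e_no)                    # kappa_dd > kappa
  expect_equal(unname(e_mg), 0.713 * 49 * exp(-2.5 * 3) / 3,
               tolerance = 1e-12)
  expect_equal(unname(e_no), 0.713 * 49 * exp(-1.27 * 3) / 3,
               tolerance = 1e-12)
  # Mg mode also shortens the bending persistence length (50 -> 30 nm)
  tr <- generate_nucleosome_track(fiber_spec(3, seed = 1))
  g_mg <- build_initial_fiber(tr, cond = sim_conditions(mg_mode = TRUE))
  g_no <- build_initial_fiber(tr, cond = sim_conditions(mg_mode = FALSE))
  dna_mid <- which(g_mg$type[g_mg$angles[, 2]] == 2L)[1]
  expect_equal(g_mg$angle_g[dna_mid], 30 / 3)
  expect_equal(g_no$angle_g[dna_mid], 50 / 3)
})

test_that("energy is invariant under rigid motion of the whole fiber", {
  tr <- generate_nucleosome_track(fiber_spec(3, acetylation_density = 0.5,
                                             lh_density = 0.5, seed = 6))
  cfg <- build_initial_fiber(tr)
  e0 <- c(bonded_energy(cfg), nonbonded_energy(cfg))
  ax <- c(1, 2, 3) / sqrt(14)
  moved <- cfg
  moved$pos <- chromofold:::rodrigues(cfg$pos, origin = c(4, -2, 1), axis = ax,
                         angle = 0.83)
  moved$pos <- sweep(moved$pos, 2, c(12.3, -7.1, 5.5), `+`)
  e1 <- c(bonded_energy(moved), nonbonded_energy(moved))
  expect_equal(unname(e1), unname(e0), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("folded tails do not interact with anything", {
  tr <- generate_nucleosome_track(fiber_spec(2, seed = 4))
  tr$acetylated <- c(TRUE, FALSE)
  cfg <- build_initial_fiber(tr)
  folded_beads <- which(cfg$folded_bead)
  expect_gt(length(folded_beads), 0)
  e0 <- nonbonded_energy(cfg)
  # teleporting all folded-tail beads far away changes no nonbonded term
  far <- cfg
  far$pos[folded_beads, ] <- far$pos[folded_beads, ] + 500
  expect_equal(unname(nonbonded_energy(far)), unname(e0), tolerance = 1e-12)
})
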