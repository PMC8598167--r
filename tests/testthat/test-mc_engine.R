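# Sampler-level correctness of the Monte Carlo engine.

test_that("Metropolis rule is exact downhill and Boltzmann uphill", {
  rng <- chromofold:::local_rng(1)
  expect_true(metropolis_accept(-3.2, rng))
  expect_true(metropolis_accept(0, rng))
  expect_message(got <- metropolis_accept(NaN, rng), "non-finite")
  expect_false(got)
  # acceptance frequency at dE = 1 kBT: e^-1 within binomial 3 sigma
  n <- 1e5
  acc <- sum(vapply(seq_len(n), function(i) metropolis_accept(1, rng), TRUE))
  p <- exp(-1)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("pivot proposals are rigid on the moved side, identity elsewhere", {
  cfg <- tiny_fiber(4, lh = TRUE)
  for (s in 1:6) {
    prop <- pivot_move(cfg, max_angle = 30, rng = s)
    moved <- prop$moved
    if (length(moved) == 0) next   # pivot at a chain end: null proposal
    kept <- setdiff(seq_len(nrow(cfg$pos)), moved)
    expect_identical(prop$config$pos[kept, ], cfg$pos[kept, ])
    # intra-set distances preserved to 1e-10
    if (length(moved) > 1) {
      d0 <- dist(cfg$pos[moved, ])
      d1 <- dist(prop$config$pos[moved, ])
      expect_lt(max(abs(d0 - d1)), 1e-10)
    }
    # the shorter side moves
    expect_lte(length(intersect(moved, which(cfg$type %in% c(0L, 2L)))),
               ceiling(sum(cfg$type %in% c(0L, 2L)) / 2))
  }
})

test_that("pivot tie at the exact chain midpoint rotates the lower-index side", {
  cfg <- tiny_fiber(3)             # path: 3 cores + 2x2 DNA beads = 7 nodes
  path <- which(cfg$type %in% c(0L, 2L))
  path <- path[order(cfg$path_pos[path])]
  P <- length(path)
  expect_equal(P %% 2, 1)          # odd: a true midpoint exists
  mid_rank <- (P + 1) / 2
  # find a seed whose cut lands on the midpoint by replaying the rng
  for (s in 1:200) {
    rng <- chromofold:::local_rng(s)
    if (1L + rng$sample_int(P - 1L, 1L) == mid_rank) {
      prop <- pivot_move(cfg, rng = s)
      cutpos <- cfg$path_pos[path[mid_rank]]
      expect_true(all(cfg$path_pos[prop$moved] < cutpos))
      return(invisible(NULL))
    }
  }
  fail("no seed hit the midpoint cut")
})

test_that("local moves change exactly one bead or one twist register", {
  cfg <- tiny_fiber(3, lh = TRUE)
  prop <- local_move(cfg, amplitude = 0.5, rng = 2, kind = "translate")
  delta <- rowSums(abs(prop$config$pos - cfg$pos))
  expect_equal(which(delta > 0), prop$bead)
  expect_true(cfg$type[prop$bead] %in% c(2L, 4L))
  expect_true(all(abs(prop$config$pos[prop$bead, ] -
                        cfg$pos[prop$bead, ]) <= 0.5))
  # amplitude ~0: proposal is numerically the current state
  null_prop <- local_move(cfg, amplitude = 1e-12, rng = 3)
  expect_equal(null_prop$config$pos, cfg$pos, tolerance = 1e-10)
  rot <- local_move(cfg, amplitude = 10, rng = 4, kind = "rotate")
  expect_equal(sum(rot$config$twist_phi != cfg$twist_phi), 1)
  expect_identical(rot$config$pos, cfg$pos)
})

test_that("fold swap is an exact involution with the advertised energy change", {
  cfg <- tiny_fiber(2, acetylated = TRUE)
  prop <- fold_swap(cfg, rng = 1)
  expect_false(isTRUE(prop$skipped))
  back <- chromofold:::swap_tail_state(prop$config, prop$tail)
  expect_equal(back$pos, cfg$pos)
  expect_equal(back$bond_l0, cfg$bond_l0)
  expect_equal(back$tails[[prop$tail]]$alt_pos,
               cfg$tails[[prop$tail]]$alt_pos)
  # delta energy decomposes into the nonbonded change plus bonded change
  e_b0 <- sum(bonded_energy(cfg)); e_n0 <- sum(nonbonded_energy(cfg))
  e_b1 <- sum(bonded_energy(prop$config))
  e_n1 <- sum(nonbonded_energy(prop$config))
  expect_equal(prop$delta_energy, (e_b1 - e_b0) + (e_n1 - e_n0),
               tolerance = 1e-9)
  # a fiber without flagged tails skips the move
  cfg0 <- tiny_fiber(2, acetylated = FALSE)
  expect_true(fold_swap(cfg0, rng = 1)$skipped)
})

test_that("tail regrowth never selects folded tails and accepts freely in zero field", {
  # all interactions off: W_new == W_old, every proposal accepted
  ff0 <- force_field(q_dna = 0, q_core_bead = 0, q_tail = 0, q_lh_glob = 0,
                     q_lh_ctd = 0, lj_eps = 0, tail_g = 0)
  tr <- generate_nucleosome_track(fiber_spec(2, seed = 2))
  cfg <- build_initial_fiber(tr, ff = ff0)
  for (s in 1:10) {
    prop <- tail_regrow(cfg, rng = s, k = 4)
    expect_true(prop$accepted)
    expect_equal(prop$log_ratio, 0, tolerance = 1e-9)
  }
  # locality: only the regrown tail's beads move
  prop <- tail_regrow(cfg, rng = 3, k = 4)
  moved <- which(rowSums(abs(prop$config$pos - cfg$pos)) > 0)
  expect_true(all(moved %in% cfg$tails[[prop$tail]]$beads))
  # folded tails are never selected
  tr2 <- generate_nucleosome_track(fiber_spec(2, seed = 2))
  tr2$acetylated <- c(TRUE, TRUE)
  cfg2 <- build_initial_fiber(tr2)
  folded <- which(vapply(cfg2$tails, function(t) t$folded, TRUE))
  for (s in 1:20) {
    prop <- tail_regrow(cfg2, rng = s, k = 2)
    expect_false(prop$tail %in% folded)
  }
})

test_that("trajectory bookkeeping: save counts, determinism, counters", {
  cfg <- tiny_fiber(3, lh = TRUE)
  sch <- move_schedule(total_steps = 1e4, save_interval = 1e3, seed = 42)
  traj <- run_trajectory(cfg, sch)
  expect_length(traj$saves, 10)
  expect_equal(traj$series$step, seq(1e3, 1e4, by = 1e3))
  expect_equal(sum(traj$acceptance[, "attempts"]), 1e4)
  expect_true(all(traj$acceptance[, "accepts"] <=
                    traj$acceptance[, "attempts"]))
  # bit-identical rerun under the same seed
  traj2 <- run_trajectory(cfg, sch)
  expect_identical(traj$saves, traj2$saves)
  expect_identical(traj$series, traj2$series)
  # different seed diverges
  sch3 <- move_schedule(total_steps = 1e4, save_interval = 1e3, seed = 43)
  traj3 <- run_trajectory(cfg, sch3)
  expect_false(identical(traj$saves[[10]], traj3$saves[[10]]))
  expect_error(move_schedule(1e4, 1e3, p_pivot = 0.5), "sum to 1")
})

test_that("a harmonically tethered bead samples the Boltzmann variance", {
  # one immobile anchor + one DNA bead on a zero-length spring of stiffness
  # h: each coordinate is Gaussian with variance kBT/h
  h <- 4
  cfg <- minimal_config(pos = rbind(c(0, 0, 0), c(0.1, 0, 0)),
                        type = c(0L, 2L), bonds = rbind(c(1L, 2L)),
                        bond_l0 = 0, bond_k = h, core_idx = 1L)
  sch <- move_schedule(total_steps = 2e6, save_interval = 100,
                       p_pivot = 0, p_translate = 1, p_rotate = 0,
                       p_regrow = 0, p_foldswap = 0,
                       amp_translate = 1.2, seed = 5)
  traj <- run_trajectory(cfg, sch)
  xyz <- t(vapply(traj$saves, function(p) p[2, ], numeric(3)))
  v <- mean(apply(xyz, 2, var))
  expect_lt(abs(v - 1 / h) / (1 / h), 0.02)
})

test_that("fold-swap occupancies match the two-state Boltzmann ratio", {
  # a single acetylation-flagged tail toggling between its folded and
  # unfolded templates under fold-swap moves only
  tr <- generate_nucleosome_track(fiber_spec(1, seed = 3))
  tr$acetylated <- TRUE
  cfg <- build_initial_fiber(tr)
  flagged <- which(vapply(cfg$tails, function(t) t$acetylated, TRUE))
  for (t in flagged[-1]) {          # leave exactly one swappable tail
    cfg$tails[[t]]$acetylated <- FALSE
  }
  t1 <- flagged[1]
  e_folded <- total_energy(cfg)
  unf <- chromofold:::swap_tail_state(cfg, t1)
  e_unfolded <- total_energy(unf)
  dE <- e_unfolded - e_folded
  p_unfolded <- 1 / (1 + exp(dE))
  sch <- move_schedule(total_steps = 4e4, save_interval = 10,
                       p_pivot = 0, p_translate = 0, p_rotate = 0,
                       p_regrow = 0, p_foldswap = 1, seed = 8)
  traj <- run_trajectory(cfg, sch)
  occ_unfolded <- mean(!traj$folded_saves[, t1])
  n <- nrow(traj$folded_saves)
  tol <- 3 * sqrt(p_unfolded * (1 - p_unfolded) / n)  # saves decorrelate fast
  expect_lt(abs(occ_unfolded - p_unfolded), max(tol, 0.02))
})

test_that("equilibrium averages are stable under doubling the regrow trials", {
  tr <- generate_nucleosome_track(fiber_spec(1, seed = 5))
  cfg <- build_initial_fiber(tr)
  tip_extent <- function(k, seed) {
    sch <- move_schedule(total_steps = 2e4, save_interval = 200,
                         p_pivot = 0, p_translate = 0, p_rotate = 0,
                         p_regrow = 1, p_foldswap = 0,
                         regrow_trials = k, seed = seed)
    traj <- run_trajectory(cfg, sch)
    tips <- vapply(cfg$tails, function(t) t$beads[length(t$beads)], 1L)
    anchors <- vapply(cfg$tails, function(t) t$anchor, 1L)
    mean(vapply(traj$saves[10:100], function(p)
      mean(sqrt(rowSums((p[tips, ] - p[anchors, ])^2))), 1.0))
  }
  a <- vapply(1:3, function(s) tip_extent(4L, s), 1.0)
  b <- vapply(1:3, function(s) tip_extent(8L, s), 1.0)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_lt(abs(mean(a) - mean(b)), max(3 * se, 0.05 * mean(a)))
})

test_that("convergence report flags drift and short trajectories", {
  const <- data.frame(total = rep(5, 100), rg = rep(2, 100),
                      inv_rij_sum = rep(1, 100))
  rep1 <- convergence_report(const, window = 20)
  expect_equal(rep1$status, "ok")
  expect_true(rep1$pass)
  expect_true(all(rep1$table$drift == 0))
  # linear series: drift equals the analytic window-mean difference
  lin <- data.frame(total = 1:100, rg = seq(0, 9.9, by = 0.1),
                    inv_rij_sum = rep(1, 100))
  rep2 <- convergence_report(lin, window = 25, tol = 0.01)
  expect_equal(rep2$table$drift[rep2$table$series == "total"], 25)
  expect_false(rep2$pass)
  short <- convergence_report(const[1:10, ], window = 20)
  expect_equal(short$status, "insufficient")
  expect_true(is.na(short$pass))
})
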