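#' Monte Carlo move schedule
#'
#' Mixture probabilities and amplitudes for the five tailored moves: global
#' pivot, local bead translation, local rotation (twist register), Rosenbluth
#' tail regrowth, and the fold-swap move for acetylated tails. The default
#' mixture (0.2/0.3/0.2/0.2/0.1) and amplitudes target 30-50% acceptance on
#' desk-scale fibers; all are configurable.
#'
#' @param total_steps Total MC steps.
#' @param save_interval Steps between saved configurations.
#' @param p_pivot,p_translate,p_rotate,p_regrow,p_foldswap Move selection
#'   probabilities; must sum to 1.
#' @param amp_pivot Maximum pivot rotation (degrees).
#' @param amp_translate Maximum per-axis bead translation (nm).
#' @param amp_rotate Maximum twist-register rotation (degrees).
#' @param regrow_trials Trial positions per bead in the regrowth move.
#' @param seed Integer seed; one generator per trajectory, no global state.
#' @return List of class `move_schedule`.
#' @export
move_schedule <- function(total_steps, save_interval,
                          p_pivot = 0.2, p_translate = 0.3, p_rotate = 0.2,
                          p_regrow = 0.2, p_foldswap = 0.1,
                          amp_pivot = 40, amp_translate = 0.4,
                          amp_rotate = 20, regrow_trials = 8L, seed = 1L) {
  p <- c(p_pivot, p_translate, p_rotate, p_regrow, p_foldswap)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("move probabilities must be >= 0 and sum to 1")
  if (amp_pivot <= 0 || amp_translate <= 0 || amp_rotate <= 0)
    stop("move amplitudes must be positive")
  if (total_steps < 1 || save_interval < 1 || save_interval > total_steps)
    stop("need 1 <= save_interval <= total_steps")
  structure(list(total_steps = as.numeric(total_steps),
                 save_interval = as.numeric(save_interval),
                 p_pivot = p_pivot, p_translate = p_translate,
                 p_rotate = p_rotate, p_regrow = p_regrow,
                 p_foldswap = p_foldswap,
                 amp_pivot = amp_pivot, amp_translate = amp_translate,
                 amp_rotate = amp_rotate,
                 regrow_trials = as.integer(regrow_trials),
                 seed = as.numeric(seed)),
            class = "move_schedule")
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-delta_energy))`; consumes exactly
#' one uniform draw when `delta_energy > 0` and none otherwise. A
#' non-finite energy difference rejects the move (with a message).
#'
#' @param delta_energy Energy difference in kBT.
#' @param rng A generator from `local_rng()` (internal), or an integer seed.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_energy, rng) {
  if (is.numeric(rng)) rng <- local_rng(rng)
  if (is.na(delta_energy) || !is.finite(delta_energy)) {
    message("metropolis_accept: non-finite delta energy, move rejected")
    return(FALSE)
  }
  if (delta_energy <= 0) return(TRUE)
  rng$unif(1) < exp(-delta_energy)
}

# ---- R-level single-move proposals ----------------------------------------
# These mirror the compiled engine move-by-move; the engine runs the same
# logic in C++ for throughput. They are the reference path used in tests.

rodrigues <- function(p, origin, axis, angle) {
  v <- sweep(p, 2, origin)
  k <- axis / sqrt(sum(axis^2))
  cosa <- cos(angle); sina <- sin(angle)
  kv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
              k[3] * v[, 1] - k[1] * v[, 3],
              k[1] * v[, 2] - k[2] * v[, 1])
  dotv <- drop(v %*% k)
  sweep(v * cosa + kv * sina + outer(dotv * (1 - cosa), k), 2, origin, `+`)
}

#' Pivot move proposal
#'
#' Chooses a random position along the fiber path (cores and linker-DNA
#' beads in fiber order) and rigidly rotates the shorter side of the
#' bisected chain - together with all beads attached to its nucleosomes -
#' by a uniform angle about a uniformly random axis through that point.
#' When both sides have equal length the lower-index side rotates.
#'
#' @param config A `fiber_config`.
#' @param max_angle Maximum rotation (degrees).
#' @param rng A `local_rng()` generator or integer seed.
#' @return List: `config` (proposal), `moved` (bead indices), `pivot_bead`,
#'   `axis`, `angle` (radians).
#' @export
pivot_move <- function(config, max_angle = 25, rng = 1L) {
  if (is.numeric(rng)) rng <- local_rng(rng)
  path <- which(config$type %in% c(0L, 2L))
  path <- path[order(config$path_pos[path])]
  P <- length(path)
  if (P < 2) stop("fiber has fewer than 2 path segments")
  cut <- 1L + rng$sample_int(P - 1L, 1L)   # rank 2..P
  pb <- path[cut]
  cutpos <- config$path_pos[pb]
  n_right <- P - cut
  n_left <- cut - 1L
  rotate_right <- n_right < n_left         # tie -> lower-index side
  moved <- if (rotate_right) which(config$path_pos > cutpos)
           else which(config$path_pos < cutpos)
  ax <- rng$norm(3L)
  while (sum(ax^2) < 1e-12) ax <- rng$norm(3L)
  ax <- ax / sqrt(sum(ax^2))
  ang <- rng$unif(1, -max_angle, max_angle) * pi / 180
  new <- config
  if (length(moved))
    new$pos[moved, ] <- rodrigues(config$pos[moved, , drop = FALSE],
                                  config$pos[pb, ], ax, ang)
  list(config = new, moved = moved, pivot_bead = pb, axis = ax, angle = ang)
}

#' Local move proposal (translate a DNA/LH bead, or rotate a twist register)
#'
#' Translation displaces one uniformly chosen DNA or linker-histone bead
#' within the amplitude cube; rotation perturbs the twist register of one
#' uniformly chosen DNA segment. All other coordinates are untouched.
#'
#' @param config A `fiber_config`.
#' @param amplitude Maximum displacement (nm) or rotation (degrees).
#' @param rng A `local_rng()` generator or integer seed.
#' @param kind "translate" or "rotate".
#' @return List: `config` (proposal), `bead` (index, translate) or
#'   `segment` (index, rotate), `kind`.
#' @export
local_move <- function(config, amplitude, rng = 1L,
                       kind = c("translate", "rotate")) {
  kind <- match.arg(kind)
  if (is.numeric(rng)) rng <- local_rng(rng)
  new <- config
  if (kind == "translate") {
    mob <- which(config$type %in% c(2L, 4L))
    if (!length(mob)) stop("no DNA or LH beads to move")
    i <- mob[rng$sample_int(length(mob), 1L)]
    new$pos[i, ] <- config$pos[i, ] + rng$unif(3L, -amplitude, amplitude)
    list(config = new, bead = i, kind = kind)
  } else {
    if (!length(config$twist_phi)) stop("no twist segments")
    s <- rng$sample_int(length(config$twist_phi), 1L)
    new$twist_phi[s] <- config$twist_phi[s] +
      rng$unif(1, -amplitude, amplitude) * pi / 180
    list(config = new, segment = s, kind = kind)
  }
}

# swap one tail's fold state in an R-level config (exact involution)
swap_tail_state <- function(config, t) {
  T <- config$tails[[t]]
  cur <- config$pos[T$beads, , drop = FALSE]
  config$pos[T$beads, ] <- T$alt_pos
  T$alt_pos <- cur
  l0_cur <- config$bond_l0[T$bond_ids[1]]
  h_cur <- config$bond_k[T$bond_ids[1]]
  g_cur <- if (length(T$angle_ids)) config$angle_g[T$angle_ids[1]] else 0
  config$bond_l0[T$bond_ids] <- T$l0_alt
  config$bond_k[T$bond_ids] <- T$h_alt
  config$angle_g[T$angle_ids] <- T$g_alt
  T$l0_alt <- l0_cur; T$h_alt <- h_cur; T$g_alt <- g_cur
  T$folded <- !T$folded
  config$tails[[t]] <- T
  config$folded_bead[T$beads] <- T$folded
  config
}

#' Fold-swap move proposal
#'
#' Picks a random acetylation-flagged tail and exchanges its coordinates and
#' equilibrium constants with its stored alternate (folded vs unfolded)
#' template. Swapping twice restores the configuration exactly. The caller
#' applies Metropolis acceptance on `delta_energy`.
#'
#' @param config A `fiber_config`.
#' @param rng A `local_rng()` generator or integer seed.
#' @param tail Optional tail index (defaults to a random flagged tail).
#' @return List: `config` (proposal), `tail`, `delta_energy` (kBT), or
#'   `list(skipped = TRUE)` when no tail carries the acetylation flag.
#' @export
fold_swap <- function(config, rng = 1L, tail = NULL) {
  if (is.numeric(rng)) rng <- local_rng(rng)
  flagged <- which(vapply(config$tails, function(t) t$acetylated, TRUE))
  if (!length(flagged)) return(list(skipped = TRUE))
  t <- if (is.null(tail)) flagged[rng$sample_int(length(flagged), 1L)]
       else tail
  e0 <- total_energy(config)
  new <- swap_tail_state(config, t)
  list(config = new, tail = t, delta_energy = total_energy(new) - e0)
}

#' Run a Monte Carlo trajectory
#'
#' Samples the configured move mixture for `total_steps` steps (compiled
#' inner loop), saving the configuration every `save_interval` steps
#' together with scalar series (energy components, radius of gyration, the
#' pairwise inverse-distance sum entering the sedimentation coefficient) and
#' per-move acceptance counters. Deterministic given the schedule seed.
#'
#' When the fiber has no acetylation-flagged tails the fold-swap probability
#' is folded into local translation (the move would always be skipped).
#'
#' @param initial A `fiber_config` (see [build_initial_fiber()]).
#' @param schedule A [move_schedule()].
#' @return Object of class `fiber_trajectory`: `saves` (list of bead
#'   position matrices), `folded_saves` (saves x tails logical), `series`
#'   (data.frame), `acceptance` (5 x 2 counts), `final` (a `fiber_config`),
#'   `schedule`, `initial_track`, `n_cores`, plus bead metadata columns
#'   needed by the analysis functions.
#' @export
run_trajectory <- function(initial, schedule) {
  stopifnot(inherits(initial, "fiber_config"),
            inherits(schedule, "move_schedule"))
  sched <- unclass(schedule)
  n_acet <- sum(vapply(initial$tails, function(t) t$acetylated, TRUE))
  if (n_acet == 0 && sched$p_foldswap > 0) {
    sched$p_translate <- sched$p_translate + sched$p_foldswap
    sched$p_foldswap <- 0
  }
  sched$amp_pivot <- sched$amp_pivot * pi / 180
  sched$amp_rotate <- sched$amp_rotate * pi / 180
  res <- cf_run_trajectory(initial, sched)
  if (isTRUE(res$aborted))
    warning("trajectory aborted on non-finite energy; ",
            "last valid state retained")

  final <- initial
  final$pos <- res$final_pos
  final$twist_phi <- as.numeric(res$final_twist)
  final$bond_l0 <- as.numeric(res$bond_l0)
  final$bond_k <- as.numeric(res$bond_k)
  final$angle_g <- as.numeric(res$angle_g)
  for (t in seq_along(final$tails)) {
    final$tails[[t]]$folded <- res$folded_final[t]
    final$tails[[t]]$alt_pos <- res$alt_final[[t]]
    final$tails[[t]]$l0_alt <- res$alt_consts[t, 1]
    final$tails[[t]]$h_alt <- res$alt_consts[t, 2]
    final$tails[[t]]$g_alt <- res$alt_consts[t, 3]
    final$folded_bead[final$tails[[t]]$beads] <- res$folded_final[t]
  }

  n_saved <- as.integer(res$n_saved)
  series <- as.data.frame(res$series)[seq_len(n_saved), , drop = FALSE]
  structure(list(
    saves = res$saves[seq_len(n_saved)],
    folded_saves = res$folded_saves[seq_len(n_saved), , drop = FALSE],
    series = series,
    acceptance = res$acceptance,
    final = final,
    schedule = schedule,
    aborted = isTRUE(res$aborted),
    n_cores = initial$n_cores,
    core_idx = initial$core_idx,
    type = initial$type, core_of = initial$core_of,
    tail_of = initial$tail_of, dna_owner = initial$dna_owner,
    tails = initial$tails,
    track = initial$track),
    class = "fiber_trajectory")
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  acc <- x$acceptance
  rates <- ifelse(acc[, 1] > 0, acc[, 2] / acc[, 1], NA)
  cat(sprintf("<fiber_trajectory> %d nucleosomes, %d saved configurations\n",
              x$n_cores, length(x$saves)))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", rownames(acc), rates), collapse = ", "), "\n")
  invisible(x)
}

#' Analysis window of a trajectory
#'
#' Returns the save indices retained for equilibrium analysis: the final
#' `keep_fraction` of the run (default 1/6, mirroring the use of the last
#' sixth of each production trajectory), or all saves when
#' `keep_fraction = 1`.
#'
#' @param trajectory A `fiber_trajectory`.
#' @param keep_fraction Fraction of the trajectory tail to keep.
#' @return Integer vector of save indices.
#' @export
analysis_window <- function(trajectory, keep_fraction = 1 / 6) {
  ns <- length(trajectory$saves)
  first <- max(1L, ns - max(1L, floor(ns * keep_fraction)) + 1L)
  seq.int(first, ns)
}

#' Convergence report for a trajectory
#'
#' Splits each monitored series (total energy, radius of gyration, the
#' inverse-distance sum behind the sedimentation coefficient) into windows
#' of `window` saves, and compares the last two windows: `drift` is the
#' difference of window means, `rel_drift` the difference relative to the
#' penultimate window mean. A series passes when `|rel_drift| <= tol`.
#'
#' @param trajectory A `fiber_trajectory`, or a data.frame of series.
#' @param window Window length in saves (default: one fifth of the series).
#' @param tol Relative drift tolerance.
#' @return List of class `convergence_report`: `status` ("ok" or
#'   "insufficient"), `table` (per-series window means, drift, pass), and
#'   `pass` (logical over all series; NA when insufficient).
#' @export
convergence_report <- function(trajectory, window = NULL, tol = 0.02) {
  series <- if (inherits(trajectory, "fiber_trajectory"))
    trajectory$series[, c("total", "rg", "inv_rij_sum")] else trajectory
  n <- nrow(series)
  if (is.null(window)) window <- max(1L, n %/% 5L)
  n_win <- n %/% window
  if (n_win < 2) {
    return(structure(list(status = "insufficient", table = NULL, pass = NA),
                     class = "convergence_report"))
  }
  tab <- do.call(rbind, lapply(names(series), function(cn) {
    v <- series[[cn]]
    means <- vapply(seq_len(n_win), function(w)
      mean(v[((w - 1) * window + 1):(w * window)]), 1.0)
    m_prev <- means[n_win - 1]; m_last <- means[n_win]
    drift <- m_last - m_prev
    rel <- drift / max(abs(m_prev), 1e-12)
    data.frame(series = cn, mean_prev = m_prev, mean_last = m_last,
               drift = drift, rel_drift = rel, pass = abs(rel) <= tol)
  }))
  structure(list(status = "ok", table = tab, pass = all(tab$pass),
                 window = window, tol = tol),
            class = "convergence_report")
}

# screened-Coulomb + LJ energies of bead i against beads js (no exclusions
# applied here)
r_pair_energies <- function(config, i, js) {
  if (!length(js)) return(numeric(0))
  fc <- config$ff_consts
  dv <- sweep(config$pos[js, , drop = FALSE], 2, config$pos[i, ])
  r <- sqrt(rowSums(dv^2))
  out <- numeric(length(js))
  inside <- r < fc$cutoff
  if (!any(inside)) return(out)
  rr <- r[inside]
  jj <- js[inside]
  kap <- rep(fc$kappa, length(jj))
  if (fc$mg_mode) kap[config$type[i] == 2L & config$type[jj] == 2L] <- fc$kappa_dd
  e_el <- fc$lB * config$charge[i] * config$charge[jj] * exp(-kap * rr) / rr
  sig <- (config$diam[i] + config$diam[jj]) / 2
  sr6 <- (sig / rr)^6
  out[inside] <- e_el + 4 * fc$lj_eps * (sr6^2 - sr6)
  out
}

# nonbonded partners of bead i: active, not excluded by a bond/angle
r_partners <- function(config, i) {
  js <- which(config$type %in% 1:4 & !config$folded_bead)
  js <- setdiff(js, i)
  brows <- config$bonds[, 1] == i | config$bonds[, 2] == i
  excl <- unique(as.vector(config$bonds[brows, , drop = FALSE]))
  arows <- config$angles[, 1] == i | config$angles[, 2] == i |
    config$angles[, 3] == i
  excl <- unique(c(excl, as.vector(config$angles[arows, , drop = FALSE])))
  js <- setdiff(js, excl)
  # linker DNA and LH beads do not interact with the charge beads of their
  # own core (continuity with wrapped DNA; chromatosome tether)
  if (config$type[i] == 2L)
    js <- js[!(config$type[js] == 1L &
                 config$core_of[js] == config$dna_owner[i])]
  else if (config$type[i] == 4L)
    js <- js[!(config$type[js] == 1L &
                 config$core_of[js] == config$core_of[i])]
  else if (config$type[i] == 1L)
    js <- js[!((config$type[js] == 2L &
                  config$dna_owner[js] == config$core_of[i]) |
                 (config$type[js] == 4L &
                    config$core_of[js] == config$core_of[i]))]
  js
}

#' Tail regrowth move (configurational-bias / Rosenbluth)
#'
#' Regrows one unfolded histone tail bead by bead from the bead closest to
#' the core, with `k` trial positions per bead. Trial bond lengths are drawn
#' from the internal (stretch) Boltzmann density, so trial weights carry only
#' the external energy (nonbonded plus the bending angle closed by the
#' placed bead); the move is accepted with probability
#' `min(1, W_new / W_old)`. Folded tails are never selected. In a zero
#' external field every regrowth is accepted.
#'
#' @param config A `fiber_config`.
#' @param rng A `local_rng()` generator or integer seed.
#' @param k Trial positions per bead.
#' @param tail Optional tail index (defaults to a random unfolded tail).
#' @return List: `config` (new state if accepted, else the input),
#'   `accepted`, `log_ratio` (`log(W_new/W_old)`), `tail`; or
#'   `list(skipped = TRUE)` when every tail is folded or all trial weights
#'   vanish (hard overlap).
#' @export
tail_regrow <- function(config, rng = 1L, k = 8L, tail = NULL) {
  if (is.numeric(rng)) rng <- local_rng(rng)
  unfolded <- which(!vapply(config$tails, function(t) t$folded, TRUE))
  if (!length(unfolded)) return(list(skipped = TRUE))
  t <- if (is.null(tail)) unfolded[rng$sample_int(length(unfolded), 1L)]
       else tail
  T <- config$tails[[t]]
  if (T$folded) stop("cannot regrow a folded tail")
  nb <- length(T$beads)
  l0 <- config$bond_l0[T$bond_ids[1]]
  h <- config$bond_k[T$bond_ids[1]]
  sigma <- 1 / sqrt(max(h, 1e-9))
  lmax <- l0 + 6 * sigma
  draw_len <- function() {
    repeat {
      l <- l0 + sigma * rng$norm(1)
      if (l > 0 && l <= lmax && rng$unif(1) < (l / lmax)^2) return(l)
    }
  }
  sphere <- function() {
    v <- rng$norm(3L)
    while (sum(v^2) < 1e-12) v <- rng$norm(3L)
    v / sqrt(sum(v^2))
  }
  work <- config
  old_pos <- config$pos[T$beads, , drop = FALSE]
  # external energy of tail bead b at position p: nonbonded against
  # everything except unplaced beads of this tail, plus the bending angle
  # whose outermost vertex is bead b
  ext_e <- function(b, p, placed) {
    i <- T$beads[b]
    work$pos[i, ] <<- p
    js <- r_partners(work, i)
    later <- T$beads[seq_len(nb) > placed]
    js <- setdiff(js, later)
    e <- sum(r_pair_energies(work, i, js))
    for (a in T$angle_ids) {
      if (work$angles[a, 3] != i) next
      v1 <- work$pos[work$angles[a, 1], ]
      v2 <- work$pos[work$angles[a, 2], ]
      v3 <- work$pos[work$angles[a, 3], ]
      u <- v1 - v2; w <- v3 - v2
      cth <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
      e <- e + 0.5 * work$angle_g[a] *
        (acos(pmin(pmax(cth, -1), 1)) - work$angle_t0[a])^2
    }
    e
  }
  logW_new <- 0; logW_old <- 0
  newp <- matrix(0, nb, 3)
  for (b in seq_len(nb)) {
    prev_new <- if (b == 1) config$pos[T$anchor, ] else newp[b - 1, ]
    prev_old <- if (b == 1) config$pos[T$anchor, ] else old_pos[b - 1, ]
    # new growth (already-placed new beads are in `work`)
    for (q in seq_len(b - 1)) work$pos[T$beads[q], ] <- newp[q, ]
    w <- numeric(k); cand <- matrix(0, k, 3)
    for (tr in seq_len(k)) {
      cand[tr, ] <- prev_new + draw_len() * sphere()
      e <- ext_e(b, cand[tr, ], placed = b)
      w[tr] <- if (e < 500) exp(-e) else 0
    }
    if (sum(w) <= 0) return(list(skipped = TRUE))
    pick <- findInterval(rng$unif(1) * sum(w), cumsum(w),
                         left.open = TRUE) + 1L
    newp[b, ] <- cand[pick, ]
    logW_new <- logW_new + log(sum(w))
    # old retrace
    for (q in seq_len(nb)) work$pos[T$beads[q], ] <- old_pos[q, ]
    e_old <- ext_e(b, old_pos[b, ], placed = b)
    w_old <- if (e_old < 500) exp(-e_old) else 0
    if (k > 1) for (tr in seq_len(k - 1)) {
      p <- prev_old + draw_len() * sphere()
      e <- ext_e(b, p, placed = b)
      w_old <- w_old + (if (e < 500) exp(-e) else 0)
    }
    # ext_e wrote into work; restore old coords for the next iteration
    for (q in seq_len(nb)) work$pos[T$beads[q], ] <- old_pos[q, ]
    if (w_old <= 0) w_old <- 1e-300
    logW_old <- logW_old + log(w_old)
  }
  log_ratio <- logW_new - logW_old
  accepted <- log_ratio >= 0 || rng$unif(1) < exp(log_ratio)
  out_cfg <- config
  if (accepted) out_cfg$pos[T$beads, ] <- newp
  list(config = out_cfg, accepted = accepted, log_ratio = log_ratio,
       tail = t)
}

#' Persist / restore a trajectory
#'
#' Trajectories are plain R objects; these helpers wrap RDS serialization
#' so file handling stays symmetric with the other writers.
#'
#' @param trajectory A `fiber_trajectory`.
#' @param path File path (`.rds`).
#' @export
save_trajectory <- function(trajectory, path) {
  saveRDS(trajectory, path)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) readRDS(path)
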