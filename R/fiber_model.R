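#' Force-field parameters for the mesoscale chromatin model
#'
#' The fiber combines four coarse-grained elements: the nucleosome core (a
#' rigid body carrying surface charge beads), linker DNA (worm-like chain of
#' beads, ~9 bp each), flexible histone tails (five residues per bead), and
#' linker histones (6 globular beads plus a 22-bead H1e or 21-bead H1c
#' C-terminal domain). Bonded interactions are harmonic stretching, bending
#' and twisting; nonbonded interactions are Debye-Hueckel screened
#' electrostatics and 12-6 Lennard-Jones excluded volume. Acetylated tails
#' are modeled folded and rigid: their force constants are multiplied by
#' `acetyl_rigidity` (100) and they are excluded from every nonbonded
#' interaction.
#'
#' All energies are in kBT, lengths in nm, charges in elementary charges.
#' The charge magnitudes and Lennard-Jones parameters are stand-in defaults
#' of the right order of magnitude, exposed here rather than hard-coded;
#' `config_metadata` flags them as such.
#'
#' @param stretch_h DNA stretching constant (kBT/nm^2).
#' @param dna_l0 Equilibrium DNA segment length (nm); one bead per
#'   `bp_per_bead` bp.
#' @param bp_per_bead Base pairs per DNA bead.
#' @param core_dna_l0 Equilibrium core-center to first-linker-bead bond (nm).
#' @param persistence_length DNA bending persistence length (nm); 50 by
#'   default, reduced to 30 under Mg (see [sim_conditions()]).
#' @param persistence_length_mg Persistence length in Mg mode (nm).
#' @param torsional_persistence Torsional persistence length (nm).
#' @param epsilon_r Relative dielectric constant of water.
#' @param kappa Inverse Debye length (1/nm); `NULL` computes it from the
#'   salt concentration (1.27/nm at 150 mM monovalent).
#' @param kappa_dd Raised inverse Debye length applied to DNA-DNA
#'   electrostatics in Mg mode (1/nm).
#' @param lj_eps Lennard-Jones well depth (kBT).
#' @param cutoff Nonbonded cutoff (nm).
#' @param acetyl_rigidity Multiplier on folded-tail force constants.
#' @param q_dna,q_core_bead,q_lh_glob,q_lh_ctd Per-bead charges (e).
#' @param q_tail Tail bead charge (e); a scalar, or a named vector per tail
#'   kind. The basic H3/H4 tails carry the largest charge: they are the
#'   dominant internucleosome bridgers (the H4 basic patch in particular),
#'   and their folding upon acetylation is what decompacts the fiber.
#' @param d_charge,d_dna,d_tail,d_lh Per-type bead diameters (nm).
#' @param n_core_charge_beads Surface charge beads per core.
#' @param core_radius,core_half_height Charge-bead cylinder geometry (nm).
#' @param tail_beads Named integer vector: beads per tail copy.
#' @param tail_l0,tail_h,tail_g Unfolded tail bond length (nm), stretch
#'   (kBT/nm^2) and bend (kBT/rad^2) constants.
#' @param fold_l0 Folded-tail equilibrium bond length (nm).
#' @param lh_l0,lh_h,lh_g Linker-histone chain constants.
#' @param lh_globular_beads,lh_ctd_beads_h1e,lh_ctd_beads_h1c LH bead counts.
#' @param lh_subtype "H1e" or "H1c".
#' @return List of class `force_field`.
#' @export
force_field <- function(stretch_h = 100, dna_l0 = 3.0, bp_per_bead = 9L,
                        core_dna_l0 = 6.0,
                        persistence_length = 50, persistence_length_mg = 30,
                        torsional_persistence = 75,
                        epsilon_r = 80, kappa = NULL, kappa_dd = 2.5,
                        lj_eps = 0.001, cutoff = 7.0, acetyl_rigidity = 100,
                        q_dna = -7.0, q_core_bead = -3.0,
                        q_tail = c(H3 = 2.8, H4 = 2.8, `H2A-N` = 1.0,
                                   `H2A-C` = 1.0, H2B = 1.0),
                        q_lh_glob = 5.5, q_lh_ctd = 5.5,
                        d_charge = 2.4, d_dna = 2.4, d_tail = 1.0, d_lh = 1.0,
                        n_core_charge_beads = 48L, core_radius = 5.0,
                        core_half_height = 2.2,
                        tail_beads = c(H3 = 5L, H4 = 5L, `H2A-N` = 3L,
                                       `H2A-C` = 2L, H2B = 5L),
                        tail_l0 = 1.5, tail_h = 20, tail_g = 2,
                        fold_l0 = 0.9,
                        lh_l0 = 0.6, lh_h = 20, lh_g = 2,
                        lh_globular_beads = 6L, lh_ctd_beads_h1e = 22L,
                        lh_ctd_beads_h1c = 21L, lh_subtype = "H1e") {
  stopifnot(all(c(d_charge, d_dna, d_tail, d_lh) > 0),
            persistence_length %in% c(50, 30) ||
              persistence_length > 0,  # 50 default, 30 Mg-mode; others allowed
            acetyl_rigidity > 0, cutoff > 0,
            lh_subtype %in% c("H1e", "H1c"))
  ff <- as.list(environment())
  ff$config_metadata <- paste(
    "charge magnitudes and LJ parameters are order-of-magnitude stand-ins,",
    "not values re-derived from atomistic surface-charge optimization")
  class(ff) <- "force_field"
  ff
}

#' Simulation conditions
#'
#' Defaults match the physiological setup: 293 K, 150 mM monovalent salt,
#' Mg present. Mg mode reduces the DNA persistence length from 50 to 30 nm
#' and raises the inverse Debye length for DNA-DNA electrostatics.
#'
#' @param temperature Kelvin.
#' @param salt_mM Monovalent salt concentration (mM).
#' @param mg_mode Logical; Mg(2+) phenomenology on/off.
#' @return List of class `sim_conditions`.
#' @export
sim_conditions <- function(temperature = 293, salt_mM = 150, mg_mode = TRUE) {
  stopifnot(temperature > 0, salt_mM > 0)
  structure(list(temperature = temperature, salt_mM = salt_mM,
                 mg_mode = isTRUE(mg_mode)),
            class = "sim_conditions")
}

# Bjerrum length (nm) and inverse Debye length (1/nm) in water
bjerrum_length <- function(epsilon_r, temperature) {
  1.671e4 / (epsilon_r * temperature)
}
debye_kappa <- function(lB, salt_mM) {
  sqrt(8 * pi * lB * 6.022e-4 * salt_mM)
}

# resolved numeric constants handed to the C++ kernels
ff_consts <- function(ff, cond) {
  lB <- bjerrum_length(ff$epsilon_r, cond$temperature)
  kap <- if (is.null(ff$kappa)) debye_kappa(lB, cond$salt_mM) else ff$kappa
  list(lB = lB, kappa = kap, kappa_dd = ff$kappa_dd, lj_eps = ff$lj_eps,
       cutoff = ff$cutoff, mg_mode = cond$mg_mode)
}

#' Build the initial fiber configuration
#'
#' Places nucleosome cores on an ideal two-start zigzag, threads linker DNA
#' beads (one per ~9 bp of linker, with nucleosome-free regions lengthening
#' the linkers), attaches ten histone tails per core (two copies each of H3,
#' H4, H2A N-, H2A C-terminal and H2B), puts linker-histone chains on
#' LH-flagged cores, and assigns the folded template to the tails of
#' acetylation-flagged nucleosomes (H3 and H4 tails carry the acetylation
#' flag; see the package vignette). Every DNA segment starts at its B-twist
#' register `b_twist`, one of -12, 0 or +12 degrees.
#'
#' @param track A `nucleosome_track` (see [generate_nucleosome_track()]).
#' @param ff A [force_field()].
#' @param cond A [sim_conditions()].
#' @param b_twist B-twist offset in degrees; must be -12, 0 or +12.
#' @param seed Integer seed (reserved for randomized variants of the start).
#' @return Object of class `fiber_config`: bead arrays (`pos`, `type`,
#'   `charge`, `diam`, `core_of`, `tail_of`, `dna_owner`, `path_pos`,
#'   `folded_bead`), bonded tables (`bonds`/`bond_l0`/`bond_k`,
#'   `angles`/`angle_g`/`angle_t0`, `twist_*`), `tails` (per-tail records
#'   with alternate fold templates), `core_idx`, `ff`, `cond`, `ff_consts`,
#'   `track`. Bead types: 0 core center, 1 charge bead, 2 DNA, 3 tail,
#'   4 LH, 5 tail anchor, 6 LH anchor.
#' @export
build_initial_fiber <- function(track, ff = force_field(),
                                cond = sim_conditions(), b_twist = 0,
                                seed = 1L) {
  stopifnot(inherits(track, "nucleosome_track"))
  if (!b_twist %in% c(-12, 0, 12))
    stop("b_twist must be one of -12, 0, +12 degrees")
  n <- nrow(track)
  if (n < 1) stop("track is empty")
  linker_bp <- if (n > 1) diff(track$dyad) - 147 else integer(0)
  if (any(linker_bp < 0))
    stop("negative linker length: dyads closer than the 147 bp footprint")
  nb_linker <- as.integer(round(linker_bp / ff$bp_per_bead))

  # --- collect beads
  pos <- list(); type <- integer(0); charge <- numeric(0); diam <- numeric(0)
  core_of <- integer(0); tail_of <- integer(0); dna_owner <- integer(0)
  path_pos <- numeric(0)
  add_bead <- function(p, ty, q, d, co, to = 0L, owner = 0L, pp) {
    pos[[length(pos) + 1L]] <<- p
    type[length(type) + 1L] <<- ty
    charge[length(charge) + 1L] <<- q
    diam[length(diam) + 1L] <<- d
    core_of[length(core_of) + 1L] <<- co
    tail_of[length(tail_of) + 1L] <<- to
    dna_owner[length(dna_owner) + 1L] <<- owner
    path_pos[length(path_pos) + 1L] <<- pp
    length(pos)
  }

  zigzag_x <- 6.0; zigzag_rise <- 7.0
  centers <- cbind(zigzag_x * (-1)^(seq_len(n) - 1), 0,
                   (seq_len(n) - 1) * zigzag_rise)

  bonds <- list(); bond_l0 <- numeric(0); bond_k <- numeric(0)
  angles <- list(); angle_g <- numeric(0); angle_t0 <- numeric(0)
  add_bond <- function(i, j, l0, k) {
    bonds[[length(bonds) + 1L]] <<- c(i, j)
    bond_l0[length(bond_l0) + 1L] <<- l0
    bond_k[length(bond_k) + 1L] <<- k
    length(bonds)
  }
  add_angle <- function(i, j, k, g, t0 = pi) {
    angles[[length(angles) + 1L]] <<- c(i, j, k)
    angle_g[length(angle_g) + 1L] <<- g
    angle_t0[length(angle_t0) + 1L] <<- t0
    length(angles)
  }

  lp <- if (cond$mg_mode) ff$persistence_length_mg else ff$persistence_length
  g_dna <- lp / ff$dna_l0
  s_twist <- ff$torsional_persistence / ff$dna_l0
  phi0 <- b_twist * pi / 180

  core_idx <- integer(n)
  tails <- list()
  ncb <- ff$n_core_charge_beads
  ring_z <- c(-ff$core_half_height, 0, ff$core_half_height)
  per_ring <- rep(ncb %/% 3L, 3L)
  per_ring[seq_len(ncb %% 3L)] <- per_ring[seq_len(ncb %% 3L)] + 1L

  tail_kinds <- rep(names(ff$tail_beads), each = 2L)
  kind_code <- stats::setNames(seq_along(ff$tail_beads),
                               names(ff$tail_beads))

  # --- cores with rigid decorations
  for (i in seq_len(n)) {
    ctr <- centers[i, ]
    pp <- i * 1000  # path coordinate; linker beads interpolate between cores
    core_idx[i] <- add_bead(ctr, 0L, 0, 0, i, pp = pp)
    for (r in 1:3) {
      nr <- per_ring[r]
      th <- 2 * pi * (seq_len(nr) - 1) / nr + (r - 1) * pi / nr
      for (b in seq_len(nr))
        add_bead(ctr + c(ff$core_radius * cos(th[b]),
                         ff$core_radius * sin(th[b]), ring_z[r]),
                 1L, ff$q_core_bead, ff$d_charge, i, pp = pp)
    }
    # tails: anchors at radius 5.5, alternating faces; beads extend radially
    for (t in seq_along(tail_kinds)) {
      kind <- tail_kinds[t]
      nbt <- ff$tail_beads[[kind]]
      th <- (t - 0.5) * 2 * pi / length(tail_kinds)
      zo <- if (t %% 2 == 0) ff$core_half_height + 0.55 else
        -(ff$core_half_height + 0.55)
      u <- c(cos(th), sin(th), 0)
      anchor_p <- ctr + c(5.5 * u[1], 5.5 * u[2], zo)
      a_idx <- add_bead(anchor_p, 5L, 0, 0, i, pp = pp)
      acet <- track$acetylated[i] && kind %in% c("H3", "H4")
      # both initial templates stay near the parent core so neighboring
      # nucleosomes never interpenetrate at start; the unfolded arc (larger
      # radius, native spacing) relaxes through regrowth moves
      dthu <- 2 * asin(ff$tail_l0 / 2 / 6.2)
      unfolded <- t(vapply(seq_len(nbt), function(j)
        ctr + c(6.2 * cos(th + j * dthu), 6.2 * sin(th + j * dthu), zo),
        numeric(3)))
      dth <- 2 * asin(ff$fold_l0 / 2 / 5.8)
      folded <- t(vapply(seq_len(nbt), function(j)
        ctr + c(5.8 * cos(th + j * dth), 5.8 * sin(th + j * dth), zo),
        numeric(3)))
      start_folded <- acet
      tmpl <- if (start_folded) folded else unfolded
      alt <- if (start_folded) unfolded else folded
      q_t <- if (length(ff$q_tail) > 1) ff$q_tail[[kind]] else ff$q_tail
      bead_ids <- integer(nbt)
      for (j in seq_len(nbt))
        bead_ids[j] <- add_bead(tmpl[j, ], 3L, q_t, ff$d_tail, i,
                                to = length(tails) + 1L, pp = pp)
      l0_act <- if (start_folded) ff$fold_l0 else ff$tail_l0
      h_act <- if (start_folded) ff$tail_h * ff$acetyl_rigidity else ff$tail_h
      g_act <- if (start_folded) ff$tail_g * ff$acetyl_rigidity else ff$tail_g
      bid <- add_bond(a_idx, bead_ids[1], l0_act, h_act)
      bond_ids <- bid
      for (j in seq_len(nbt - 1))
        bond_ids <- c(bond_ids, add_bond(bead_ids[j], bead_ids[j + 1],
                                         l0_act, h_act))
      angle_ids <- integer(0)
      chain <- c(a_idx, bead_ids)
      for (j in seq_len(length(chain) - 2))
        angle_ids <- c(angle_ids, add_angle(chain[j], chain[j + 1],
                                            chain[j + 2], g_act))
      tails[[length(tails) + 1L]] <- list(
        beads = bead_ids, anchor = a_idx, kind = unname(kind_code[kind]),
        kind_name = kind, core = i, acetylated = acet, folded = start_folded,
        alt_pos = alt,
        l0_alt = if (start_folded) ff$tail_l0 else ff$fold_l0,
        h_alt = if (start_folded) ff$tail_h
                else ff$tail_h * ff$acetyl_rigidity,
        g_alt = if (start_folded) ff$tail_g
                else ff$tail_g * ff$acetyl_rigidity,
        bond_ids = bond_ids, angle_ids = angle_ids)
    }
    # linker histone chain on flagged cores
    if (track$lh[i]) {
      n_ctd <- if (ff$lh_subtype == "H1e") ff$lh_ctd_beads_h1e
               else ff$lh_ctd_beads_h1c
      u <- c(sign(ctr[1] + 1e-9), 0, 0)
      a_idx <- add_bead(ctr + 6.0 * u, 6L, 0, 0, i, pp = pp)
      nlh <- ff$lh_globular_beads + n_ctd
      ids <- integer(nlh)
      for (j in seq_len(nlh)) {
        q <- if (j <= ff$lh_globular_beads) ff$q_lh_glob else ff$q_lh_ctd
        ids[j] <- add_bead(ctr + (6.0 + j * ff$lh_l0) * u, 4L, q, ff$d_lh,
                           i, pp = pp)
      }
      chain <- c(a_idx, ids)
      for (j in seq_len(nlh)) add_bond(chain[j], chain[j + 1], ff$lh_l0,
                                       ff$lh_h)
      for (j in seq_len(nlh - 1))
        add_angle(chain[j], chain[j + 1], chain[j + 2], ff$lh_g)
    }
  }

  # --- linker DNA between consecutive cores
  n_twist <- 0L
  twist_phi <- numeric(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    nb <- nb_linker[i]
    p1 <- centers[i, ]; p2 <- centers[i + 1, ]
    seg_l0 <- c(ff$core_dna_l0, rep(ff$dna_l0, max(nb - 1, 0)),
                ff$core_dna_l0)
    if (nb == 0) seg_l0 <- 2 * ff$core_dna_l0  # direct core-core spring
    L <- sum(seg_l0)
    D <- sqrt(sum((p2 - p1)^2))
    ids <- integer(nb)
    if (nb > 0) {
      cum <- cumsum(seg_l0)[seq_len(nb)]
      if (D >= L) {
        pts <- t(sapply(cum / L, function(f) p1 + f * (p2 - p1)))
      } else {
        # two-segment tent path of total length L, apex bowed in +-y
        hgt <- sqrt(max((L / 2)^2 - (D / 2)^2, 0))
        perp <- c(0, (-1)^i, 0)
        apex <- (p1 + p2) / 2 + hgt * perp
        pts <- t(sapply(cum, function(s) {
          if (s <= L / 2) p1 + (s / (L / 2)) * (apex - p1)
          else apex + ((s - L / 2) / (L / 2)) * (p2 - apex)
        }))
      }
      owner <- ifelse(seq_len(nb) <= nb / 2, i, i + 1L)
      for (j in seq_len(nb))
        ids[j] <- add_bead(pts[j, ], 2L, ff$q_dna, ff$d_dna, owner[j],
                           owner = owner[j],
                           pp = i * 1000 + j * 1000 / (nb + 1))
    }
    chain <- c(core_idx[i], ids, core_idx[i + 1])
    for (j in seq_len(length(chain) - 1)) {
      add_bond(chain[j], chain[j + 1],
               if (length(seg_l0) == 1) seg_l0 else seg_l0[j], ff$stretch_h)
      n_twist <- n_twist + 1L
    }
    # bending only where the middle vertex is a DNA bead (fiber can fold
    # freely at nucleosomes)
    if (length(chain) >= 3)
      for (j in seq_len(length(chain) - 2))
        add_angle(chain[j], chain[j + 1], chain[j + 2], g_dna)
  }
  twist_phi <- rep(phi0, n_twist)

  config <- list(
    pos = do.call(rbind, pos), type = type, charge = charge, diam = diam,
    core_of = core_of, tail_of = tail_of, dna_owner = dna_owner,
    path_pos = path_pos,
    folded_bead = vapply(seq_along(type), function(i) {
      type[i] == 3L && tails[[tail_of[i]]]$folded
    }, TRUE),
    bonds = do.call(rbind, bonds), bond_l0 = bond_l0, bond_k = bond_k,
    angles = do.call(rbind, angles), angle_g = angle_g, angle_t0 = angle_t0,
    twist_phi = twist_phi, twist_phi0 = rep(phi0, n_twist),
    twist_s = rep(s_twist, n_twist),
    tails = tails, core_idx = core_idx, n_cores = n,
    ff = ff, cond = cond, ff_consts = ff_consts(ff, cond),
    b_twist = b_twist, track = track, seed = as.integer(seed))
  storage.mode(config$bonds) <- "integer"
  storage.mode(config$angles) <- "integer"
  config$type <- as.integer(config$type)
  config$core_of <- as.integer(config$core_of)
  config$tail_of <- as.integer(config$tail_of)
  config$dna_owner <- as.integer(config$dna_owner)
  config$tails <- lapply(config$tails, function(t) {
    t$beads <- as.integer(t$beads)
    t$anchor <- as.integer(t$anchor)
    t$bond_ids <- as.integer(t$bond_ids)
    t$angle_ids <- as.integer(t$angle_ids)
    t
  })
  class(config) <- "fiber_config"
  config
}

#' @export
print.fiber_config <- function(x, ...) {
  cat(sprintf(
    "<fiber_config> %d nucleosomes, %d beads (%d DNA, %d tail, %d LH)\n",
    x$n_cores, nrow(x$pos), sum(x$type == 2L), sum(x$type == 3L),
    sum(x$type == 4L)))
  cat(sprintf("  %d bonds, %d angles, %d twist segments; b_twist %+d deg\n",
              nrow(x$bonds), nrow(x$angles), length(x$twist_phi), x$b_twist))
  cat(sprintf("  LH on %d cores, %d acetylation-flagged tails (%d folded)\n",
              sum(x$track$lh),
              sum(vapply(x$tails, function(t) t$acetylated, TRUE)),
              sum(vapply(x$tails, function(t) t$folded, TRUE))))
  invisible(x)
}

#' Bonded energy components of a configuration
#'
#' Harmonic stretching, bending and twisting energies in kBT. Folded
#' (acetylated) tails contribute through their stiffened constants.
#'
#' @param config A `fiber_config`.
#' @return Named numeric vector `stretch`, `bend`, `twist`, with attribute
#'   `total`.
#' @export
bonded_energy <- function(config) {
  e <- cf_bonded_energy(config)
  attr(e, "total") <- sum(e)
  e
}

#' Nonbonded energy components of a configuration
#'
#' Screened-Coulomb (Debye-Hueckel) electrostatics and Lennard-Jones
#' excluded volume over all non-bonded bead pairs within the cutoff, in kBT.
#' In Mg mode, DNA-DNA pairs are screened with the raised `kappa_dd`.
#' Folded tails are excluded from every pair list.
#'
#' @param config A `fiber_config`.
#' @return Named numeric vector `electrostatic`, `excluded_volume`, with
#'   attribute `total`.
#' @export
nonbonded_energy <- function(config) {
  e <- cf_nonbonded_energy(config)
  attr(e, "total") <- sum(e)
  e
}

#' Total configurational energy (kBT)
#' @param config A `fiber_config`.
#' @return Scalar total energy.
#' @export
total_energy <- function(config) {
  sum(cf_bonded_energy(config)) + sum(cf_nonbonded_energy(config))
}

#' Write / read force field and conditions as a YAML config
#'
#' Serializes every tunable constant of a [force_field()] and
#' [sim_conditions()] pair to one YAML file (requires the yaml package),
#' so a simulation's parameterization travels with its outputs.
#'
#' @param ff A `force_field`.
#' @param cond A `sim_conditions`.
#' @param path Config file path.
#' @export
write_ff_config <- function(ff, cond, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config I/O")
  obj <- list(force_field = unclass(ff), conditions = unclass(cond))
  obj$force_field$tail_beads <- as.list(ff$tail_beads)
  obj$force_field$q_tail <- as.list(ff$q_tail)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ff_config
#' @export
read_ff_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config I/O")
  obj <- yaml::read_yaml(path)
  ff <- obj$force_field
  ff$tail_beads <- unlist(ff$tail_beads)
  ff$q_tail <- unlist(ff$q_tail)
  class(ff) <- "force_field"
  cond <- obj$conditions
  class(cond) <- "sim_conditions"
  list(ff = ff, cond = cond)
}
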