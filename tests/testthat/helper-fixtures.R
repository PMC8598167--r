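# Shared fixtures: everything is generated in code at test time.

# a small deterministic pairs table with known strands/coordinates
toy_pairs <- function() {
  df <- data.frame(
    readID = sprintf("r%d", 1:6),
    chrom1 = "chrT", pos1 = c(100L, 500L, 900L, 210L, 40L, 700L),
    strand1 = c("+", "-", "+", "+", "-", "-"),
    chrom2 = "chrT", pos2 = c(300L, 450L, 1200L, 210L, 400L, 750L),
    strand2 = c("-", "+", "+", "-", "-", "+"),
    stringsAsFactors = FALSE)
  attr(df, "chrom_sizes") <- c(chrT = 2000)
  class(df) <- c("pairs_table", "data.frame")
  df
}

# tiny two-nucleosome fiber (fast energy / move tests)
tiny_fiber <- function(n = 2, acetylated = FALSE, lh = FALSE, seed = 1) {
  tr <- generate_nucleosome_track(
    fiber_spec(n, mean_repeat_length = 165, seed = seed))
  tr$acetylated <- rep(acetylated, length.out = n)
  tr$lh <- rep(lh, length.out = n)
  build_initial_fiber(tr)
}

# brute-force contact-probability decay from raw pairs (independent of the
# package's binned-diagonal path)
oracle_decay <- function(pairs, chrom_len, bin = 10) {
  b1 <- (pairs$pos1 - 1) %/% bin
  b2 <- (pairs$pos2 - 1) %/% bin
  d <- abs(b2 - b1)
  nb <- ceiling(chrom_len / bin)
  tab <- table(d)
  dd <- as.integer(names(tab))
  p <- as.numeric(tab) / (nb - dd)
  data.frame(distance = dd * bin, probability = p / sum(p))
}

# hand-built minimal configuration for closed-form energy and sampler tests;
# all fields the engine expects, nothing derived from a track
minimal_config <- function(pos, type, charge = rep(0, nrow(pos)),
                           diam = rep(1, nrow(pos)),
                           bonds = matrix(integer(0), 0, 2),
                           bond_l0 = numeric(0), bond_k = numeric(0),
                           angles = matrix(integer(0), 0, 3),
                           angle_g = numeric(0),
                           twist_phi = numeric(0), twist_phi0 = numeric(0),
                           twist_s = numeric(0),
                           core_of = rep(1L, nrow(pos)),
                           lj_eps = 0, cutoff = 7, kappa = 1.27,
                           kappa_dd = 2.5, mg_mode = TRUE, lB = 0.713,
                           core_idx = integer(0)) {
  n <- nrow(pos)
  storage.mode(bonds) <- "integer"
  storage.mode(angles) <- "integer"
  cfg <- list(
    pos = pos, type = as.integer(type), charge = charge, diam = diam,
    core_of = as.integer(core_of), tail_of = rep(0L, n),
    dna_owner = rep(0L, n), path_pos = as.numeric(seq_len(n)),
    folded_bead = rep(FALSE, n),
    bonds = bonds, bond_l0 = bond_l0, bond_k = bond_k,
    angles = angles, angle_g = angle_g, angle_t0 = rep(pi, nrow(angles)),
    twist_phi = twist_phi, twist_phi0 = twist_phi0, twist_s = twist_s,
    tails = list(), core_idx = as.integer(core_idx),
    n_cores = length(core_idx),
    ff_consts = list(lB = lB, kappa = kappa, kappa_dd = kappa_dd,
                     lj_eps = lj_eps, cutoff = cutoff, mg_mode = mg_mode),
    track = data.frame(chrom = character(0), dyad = integer(0),
                       acetylated = logical(0), lh = logical(0)))
  class(cfg) <- "fiber_config"
  cfg
}

# pure-R bonded energy oracle (independent of the compiled kernel)
r_bonded_oracle <- function(cfg) {
  stretch <- 0
  for (b in seq_len(nrow(cfg$bonds))) {
    l <- sqrt(sum((cfg$pos[cfg$bonds[b, 1], ] - cfg$pos[cfg$bonds[b, 2], ])^2))
    stretch <- stretch + 0.5 * cfg$bond_k[b] * (l - cfg$bond_l0[b])^2
  }
  bend <- 0
  for (a in seq_len(nrow(cfg$angles))) {
    u <- cfg$pos[cfg$angles[a, 1], ] - cfg$pos[cfg$angles[a, 2], ]
    v <- cfg$pos[cfg$angles[a, 3], ] - cfg$pos[cfg$angles[a, 2], ]
    th <- acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
    bend <- bend + 0.5 * cfg$angle_g[a] * (th - cfg$angle_t0[a])^2
  }
  twist <- sum(0.5 * cfg$twist_s * (cfg$twist_phi - cfg$twist_phi0)^2)
  c(stretch = stretch, bend = bend, twist = twist)
}
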