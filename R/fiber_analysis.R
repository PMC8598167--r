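#' Sedimentation parameters
#'
#' Constants of the sedimentation-coefficient relation: the mononucleosome
#' values with and without linker histone, the nucleosome spherical radius,
#' and the LH occupancy of the fiber.
#'
#' @param S0 Mononucleosome sedimentation coefficient with LH bound
#'   (Svedberg).
#' @param S1 Mononucleosome sedimentation coefficient without LH (Svedberg).
#' @param R1 Nucleosome spherical radius (nm).
#' @param lh_conc LH per nucleosome, in `[0, 1]`; `NULL` derives it from the
#'   fiber's LH flags.
#' @return List of class `sedimentation_params`.
#' @export
sedimentation_params <- function(S0 = 12, S1 = 11.1, R1 = 5.5,
                                 lh_conc = NULL) {
  if (!is.null(lh_conc) && (lh_conc < 0 || lh_conc > 1))
    stop("lh_conc must be in [0, 1]")
  structure(list(S0 = S0, S1 = S1, R1 = R1, lh_conc = lh_conc),
            class = "sedimentation_params")
}

core_positions <- function(x) {
  if (inherits(x, "fiber_config")) x$pos[x$core_idx, , drop = FALSE]
  else as.matrix(x)
}

#' Sedimentation coefficient of a fiber configuration
#'
#' Hydrodynamic compaction proxy in Svedbergs:
#' \deqn{S_{w,20} = [S_1 + (S_0 - S_1)\,LH_{conc}]\,
#'   \Big(1 + \frac{R_1}{N_C} \sum_i \sum_{j \ne i} \frac{1}{R_{ij}}\Big)}
#' with the double sum over ordered pairs of nucleosome centers. The bracket
#' interpolates the mononucleosome limits: 12 S at full LH occupancy and
#' 11.1 S at zero.
#'
#' @param x A `fiber_config` or an n x 3 matrix of nucleosome centers (nm).
#' @param params A [sedimentation_params()]. When its `lh_conc` is `NULL`
#'   and `x` is a `fiber_config`, LH occupancy is taken from the fiber
#'   (flagged nucleosomes / total); otherwise `lh_conc = 0`.
#' @return Sedimentation coefficient (Svedberg).
#' @export
sedimentation_coefficient <- function(x, params = sedimentation_params()) {
  p <- core_positions(x)
  nc <- nrow(p)
  if (nc < 1) stop("need at least one nucleosome")
  lh <- params$lh_conc
  if (is.null(lh))
    lh <- if (inherits(x, "fiber_config")) mean(x$track$lh) else 0
  s <- 0
  if (nc > 1) {
    d <- as.matrix(stats::dist(p))
    off <- d[upper.tri(d)]
    if (any(off == 0)) stop("coincident nucleosome centers (R_ij = 0)")
    s <- 2 * sum(1 / off)  # ordered pairs: each unordered pair twice
  }
  (params$S1 + (params$S0 - params$S1) * lh) * (1 + params$R1 / nc * s)
}

#' Radius of gyration of the nucleosome centers
#'
#' Root-mean-square distance of each nucleosome center from their mean
#' position (nm).
#'
#' @param x A `fiber_config` or an n x 3 matrix of centers.
#' @return Radius of gyration (nm).
#' @export
radius_of_gyration <- function(x) {
  p <- core_positions(x)
  if (nrow(p) < 1) stop("need at least one nucleosome")
  ctr <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
}

#' Fiber axis length and packing ratio
#'
#' The fiber axis is a cubic smoothing spline through the nucleosome centers
#' ordered by fiber index (one spline per coordinate against the index);
#' its arc length (nm) is evaluated on a dense parameter grid. The packing
#' ratio is the number of nucleosomes per 11 nm of axis length:
#' `11 * N_C / length`.
#'
#' @param x A `fiber_config` or n x 3 matrix of centers (fiber order).
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   (0 = interpolating, larger = smoother axis).
#' @param n_grid Parameter grid multiplier for the arc-length quadrature.
#' @return `fiber_axis_length`: length in nm. `packing_ratio`: nucleosomes
#'   per 11 nm.
#' @export
fiber_axis_length <- function(x, spar = 0.5, n_grid = 25L) {
  p <- core_positions(x)
  nc <- nrow(p)
  if (nc < 2) stop("axis length needs at least 2 nucleosomes")
  t <- seq_len(nc)
  grid <- seq(1, nc, length.out = max(nc * n_grid, 100L))
  pred <- vapply(1:3, function(d) {
    if (nc < 4) {
      stats::approx(t, p[, d], xout = grid)$y
    } else {
      fit <- stats::smooth.spline(t, p[, d], spar = spar)
      stats::predict(fit, grid)$y
    }
  }, numeric(length(grid)))
  sum(sqrt(rowSums(diff(pred)^2)))
}

#' @rdname fiber_axis_length
#' @export
packing_ratio <- function(x, spar = 0.5, n_grid = 25L) {
  p <- core_positions(x)
  if (nrow(p) < 2) stop("packing ratio needs at least 2 nucleosomes")
  11 * nrow(p) / fiber_axis_length(p, spar = spar, n_grid = n_grid)
}

#' Fiber volume (alpha shape of the nucleosome centers)
#'
#' Volume (nm^3) of the alpha-shape envelope of the nucleosome centers;
#' `alpha = Inf` gives the convex hull. See [alpha_shape_volume()].
#'
#' @param x A `fiber_config` or n x 3 matrix of centers (n >= 4,
#'   non-coplanar).
#' @param alpha Alpha radius (nm).
#' @return Volume in nm^3.
#' @export
fiber_volume <- function(x, alpha = Inf) {
  p <- core_positions(x)
  if (nrow(p) < 4) stop("volume needs at least 4 nucleosomes")
  alpha_shape_volume(p, alpha)
}

#' Clustering parameters for nucleosome clutches
#'
#' @param neighborhood_radius Search radius (nm), default 20.
#' @param min_neighbors Minimum neighbors within the radius, default 3.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(neighborhood_radius = 20, min_neighbors = 3L) {
  stopifnot(neighborhood_radius > 0, min_neighbors >= 1)
  structure(list(neighborhood_radius = neighborhood_radius,
                 min_neighbors = as.integer(min_neighbors)),
            class = "cluster_params")
}

#' Density-based nucleosome clustering of a configuration
#'
#' DBSCAN-style clustering of the nucleosome centers (20 nm neighborhood,
#' 3 neighbors by default). Noise nucleosomes belong to no cluster.
#'
#' @param x A `fiber_config` or n x 3 matrix of centers.
#' @param params A [cluster_params()].
#' @return List: `labels` (0 = noise), `n_clusters`, `mean_size`,
#'   `max_size` (sizes 0 when no cluster forms).
#' @export
cluster_nucleosomes <- function(x, params = cluster_params()) {
  p <- core_positions(x)
  labels <- dbscan_labels(p, params$neighborhood_radius,
                          params$min_neighbors)
  sizes <- if (any(labels > 0)) as.integer(table(labels[labels > 0]))
           else integer(0)
  list(labels = labels, n_clusters = length(sizes),
       mean_size = if (length(sizes)) mean(sizes) else 0,
       max_size = if (length(sizes)) max(sizes) else 0L)
}

#' Contact definitions for trajectory analyses
#'
#' @param contact_cutoff Tail/charge bead contact distance (nm), default 2.
#' @param record_interval Steps between contact-map records, default 10,000.
#' @param tail_stat_interval Steps between tail-statistic records, default
#'   100,000.
#' @return List of class `contact_defs`.
#' @export
contact_defs <- function(contact_cutoff = 2, record_interval = 10000,
                         tail_stat_interval = 100000) {
  stopifnot(contact_cutoff > 0, record_interval > 0, tail_stat_interval > 0)
  structure(list(contact_cutoff = contact_cutoff,
                 record_interval = record_interval,
                 tail_stat_interval = tail_stat_interval),
            class = "contact_defs")
}

# save indices of a trajectory at (multiples of) a step cadence
saves_at_cadence <- function(trajectory, interval) {
  steps <- trajectory$series$step
  idx <- which(steps %% interval == 0)
  if (!length(idx)) idx <- seq_along(steps)  # cadence coarser than saves
  idx
}

# per-save folded-bead mask from the folded tail flags at that save
folded_mask_at <- function(trajectory, isave) {
  fb <- rep(FALSE, length(trajectory$type))
  for (t in seq_along(trajectory$tails))
    if (trajectory$folded_saves[isave, t])
      fb[trajectory$tails[[t]]$beads] <- TRUE
  fb
}

#' Internucleosome contact map of one or more trajectories
#'
#' A configuration puts nucleosomes i and j "in contact" when any tail or
#' charge bead of i lies within `contact_cutoff` of a tail or charge bead of
#' j (folded tails excluded). Binary contacts are recorded at the
#' `record_interval` cadence and accumulated; each trajectory's count matrix
#' is normalized by its maximal entry, and the normalized matrices are
#' summed across trajectories.
#'
#' @param trajectories A `fiber_trajectory` or list of them (same topology).
#' @param defs A [contact_defs()].
#' @return Symmetric numeric matrix (N_C x N_C); attribute
#'   `n_configurations` counts the sampled configurations.
#' @export
internucleosome_contact_map <- function(trajectories, defs = contact_defs()) {
  if (inherits(trajectories, "fiber_trajectory"))
    trajectories <- list(trajectories)
  nc <- trajectories[[1]]$n_cores
  total <- matrix(0, nc, nc)
  nconf <- 0L
  for (traj in trajectories) {
    if (!length(traj$saves)) stop("empty trajectory")
    idx <- saves_at_cadence(traj, defs$record_interval)
    counts <- matrix(0, nc, nc)
    for (i in idx) {
      fb <- folded_mask_at(traj, i)
      counts <- counts + cf_contact_matrix(traj$saves[[i]], traj$type,
                                           traj$core_of, fb, nc,
                                           defs$contact_cutoff)
    }
    nconf <- nconf + length(idx)
    m <- max(counts)
    if (m > 0) total <- total + counts / m
  }
  attr(total, "n_configurations") <- nconf
  total
}

#' Neighbor interaction profile I(k)
#'
#' Projects an internucleosome interaction matrix onto the separation axis:
#' `I(k)` is the summed intensity between nucleosomes k apart along the
#' fiber, normalized so that `sum(I) = 1`. Dominant `I(1)` indicates an
#' extended fiber; mass at larger k indicates local folding.
#'
#' @param contact_map Square symmetric matrix (diagonal ignored).
#' @return `data.frame` with columns `k`, `intensity`.
#' @export
neighbor_profile <- function(contact_map) {
  nc <- nrow(contact_map)
  if (nc != ncol(contact_map)) stop("matrix must be square")
  off <- contact_map
  diag(off) <- 0
  denom <- sum(off)
  if (denom == 0) stop("all-zero interaction map: profile undefined")
  ks <- seq_len(nc - 1)
  intensity <- vapply(ks, function(k) {
    i <- seq_len(nc - k)
    (sum(off[cbind(i, i + k)]) + sum(off[cbind(i + k, i)])) / denom
  }, 1.0)
  data.frame(k = ks, intensity = intensity)
}

#' Tail-interaction matrices T' and T
#'
#' For each sampled configuration, every unfolded tail is assigned to at
#' most one "separate nucleosome" element class - core (charge beads), DNA
#' (linker beads), or tail - when the shortest bead-to-bead distance to that
#' class is smaller than to any other class and below `contact_cutoff`
#' (2 nm); otherwise the tail is free. `T'(t, e)` is the fraction of sampled
#' (configuration, nucleosome) instances of tail kind t assigned to class e;
#' `T` row-normalizes `T'`, so each nonzero row sums to one. With several
#' trajectories, per-trajectory matrices give means and standard deviations.
#'
#' @param trajectories A `fiber_trajectory` or list of them.
#' @param defs A [contact_defs()]; sampling cadence `tail_stat_interval`.
#' @return List of class `tail_interaction_matrix`: `T_raw` (mean T'),
#'   `T_norm` (mean row-normalized T, NA rows where T' is all zero),
#'   `sd_raw`, `sd_norm` (across trajectories), `n_trajectories`,
#'   `n_instances` (sampled unfolded-tail instances per kind).
#' @export
tail_interaction_matrix <- function(trajectories, defs = contact_defs()) {
  if (inherits(trajectories, "fiber_trajectory"))
    trajectories <- list(trajectories)
  kinds <- c("H3", "H4", "H2A-N", "H2A-C", "H2B")
  classes <- c("core", "dna", "tail")
  per_raw <- list(); per_norm <- list()
  n_inst_total <- stats::setNames(numeric(length(kinds)), kinds)
  for (traj in trajectories) {
    idx <- saves_at_cadence(traj, defs$tail_stat_interval)
    ntails <- length(traj$tails)
    kind_of <- vapply(traj$tails, function(t) t$kind_name, "")
    tcore <- vapply(traj$tails, function(t) t$core, 1L)
    counts <- matrix(0, length(kinds), length(classes),
                     dimnames = list(kinds, classes))
    denom <- stats::setNames(numeric(length(kinds)), kinds)
    for (i in idx) {
      fb <- folded_mask_at(traj, i)
      tfold <- traj$folded_saves[i, ]
      md <- cf_tail_min_dist(traj$saves[[i]], traj$type, traj$core_of,
                             traj$tail_of, fb, traj$dna_owner, ntails,
                             tcore, tfold)
      for (t in seq_len(ntails)) {
        if (tfold[t]) next
        kn <- kind_of[t]
        denom[kn] <- denom[kn] + 1
        d <- md[t, ]
        if (all(!is.finite(d))) next
        best <- which.min(d)
        if (d[best] < defs$contact_cutoff)
          counts[kn, best] <- counts[kn, best] + 1
      }
    }
    raw <- counts / ifelse(denom > 0, denom, NA)
    rs <- rowSums(raw)
    norm <- raw / ifelse(rs > 0, rs, NA)
    per_raw[[length(per_raw) + 1L]] <- raw
    per_norm[[length(per_norm) + 1L]] <- norm
    n_inst_total <- n_inst_total + denom
  }
  stack <- function(lst) array(unlist(lst),
                               dim = c(length(kinds), length(classes),
                                       length(lst)))
  a_raw <- stack(per_raw); a_norm <- stack(per_norm)
  mean_no_nan <- function(a) apply(a, c(1, 2), mean)
  sd_or_zero <- function(a) {
    if (dim(a)[3] < 2) array(0, dim(a)[1:2]) else apply(a, c(1, 2), stats::sd)
  }
  out <- list(T_raw = mean_no_nan(a_raw), T_norm = mean_no_nan(a_norm),
              sd_raw = sd_or_zero(a_raw), sd_norm = sd_or_zero(a_norm),
              n_trajectories = length(trajectories),
              n_instances = n_inst_total)
  dimnames(out$T_raw) <- dimnames(out$T_norm) <-
    dimnames(out$sd_raw) <- dimnames(out$sd_norm) <-
    list(kinds, classes)
  class(out) <- "tail_interaction_matrix"
  out
}

#' Equilibrium compaction summary of one or more trajectories
#'
#' Evaluates the compaction statistics over the analysis window (final sixth
#' of each trajectory by default): radius of gyration, sedimentation
#' coefficient, packing ratio, alpha-shape volume, cluster statistics, and
#' the fraction of unfolded tails in contact with a separate nucleosome
#' core. Per-trajectory means with across-trajectory standard errors.
#'
#' @param trajectories A `fiber_trajectory` or list of them.
#' @param sed A [sedimentation_params()].
#' @param clus A [cluster_params()].
#' @param defs A [contact_defs()] (tail-contact fraction cadence).
#' @param keep_fraction Analysis window (see [analysis_window()]).
#' @return `data.frame` with one row per statistic: `mean`, `se` (pooled
#'   across trajectories), `n` (trajectories).
#' @export
compaction_summary <- function(trajectories, sed = sedimentation_params(),
                               clus = cluster_params(),
                               defs = contact_defs(),
                               keep_fraction = 1 / 6) {
  if (inherits(trajectories, "fiber_trajectory"))
    trajectories <- list(trajectories)
  per <- lapply(trajectories, function(traj) {
    idx <- analysis_window(traj, keep_fraction)
    lh <- mean(traj$track$lh)
    p <- sed; p$lh_conc <- if (is.null(p$lh_conc)) lh else p$lh_conc
    vals <- vapply(idx, function(i) {
      cores <- traj$saves[[i]][traj$core_idx, , drop = FALSE]
      cl <- cluster_nucleosomes(cores, clus)
      c(rg = radius_of_gyration(cores),
        sedimentation = sedimentation_coefficient(cores, p),
        packing_ratio = packing_ratio(cores),
        volume = tryCatch(fiber_volume(cores), error = function(e) NA_real_),
        n_clusters = cl$n_clusters, mean_cluster_size = cl$mean_size,
        max_cluster_size = cl$max_size)
    }, numeric(7))
    tim <- tail_interaction_matrix(traj, defs)
    tail_core <- stats::weighted.mean(tim$T_raw[, "core"],
                                      w = tim$n_instances, na.rm = TRUE)
    c(rowMeans(vals, na.rm = TRUE), tail_core_fraction = tail_core)
  })
  m <- do.call(rbind, per)
  data.frame(statistic = colnames(m),
             mean = colMeans(m, na.rm = TRUE),
             se = apply(m, 2, function(v)
               stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))),
             n = nrow(m), row.names = NULL)
}
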