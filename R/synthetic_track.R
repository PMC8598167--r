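#' Specification of a synthetic nucleosome track
#'
#' Describes a stretch of chromatin as dyad positions with per-nucleosome
#' acetylation and linker-histone (LH) occupancy flags. The defaults emulate
#' budding-yeast chromatin: a nucleosome repeat length of ~165 bp (147 bp core
#' plus short linkers), occasional nucleosome-free regions (NFRs), and
#' Bernoulli acetylation/LH flags at condition-specific densities (for
#' example 0.05 LH/nucleosome in exponentially growing cells versus 0.29 in
#' quiescent cells).
#'
#' @param n_nucleosomes Number of nucleosomes (>= 1).
#' @param mean_repeat_length Mean dyad-to-dyad distance in bp.
#' @param repeat_jitter_sd Standard deviation of the repeat-length jitter (bp).
#'   Jitter never brings two dyads closer than 147 bp (core footprint).
#' @param nfr_positions List of `c(position, length)` pairs (bp): after each
#'   dyad that would fall beyond `position`, an extra gap of `length` bp is
#'   inserted once, emulating a nucleosome-free region.
#' @param acetylation_density Fraction of nucleosomes carrying an acetylation
#'   flag, in `[0, 1]`.
#' @param lh_density Fraction of nucleosomes carrying a linker-histone flag,
#'   in `[0, 1]`.
#' @param chrom Chromosome name used when the track is written to disk.
#' @param start Genomic position (bp, 1-based) of the first dyad.
#' @param seed Integer seed; generation is a pure function of spec and seed.
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(n_nucleosomes,
                       mean_repeat_length = 165,
                       repeat_jitter_sd = 0,
                       nfr_positions = list(),
                       acetylation_density = 0,
                       lh_density = 0,
                       chrom = "chrS",
                       start = 1000L,
                       seed = 1L) {
  stopifnot(length(n_nucleosomes) == 1, n_nucleosomes >= 1,
            mean_repeat_length >= 147, repeat_jitter_sd >= 0)
  if (acetylation_density < 0 || acetylation_density > 1)
    stop("acetylation_density must be in [0, 1]")
  if (lh_density < 0 || lh_density > 1)
    stop("lh_density must be in [0, 1]")
  if (length(nfr_positions) && !all(vapply(nfr_positions, length, 1L) == 2))
    stop("nfr_positions must be a list of c(position, length) pairs")
  structure(list(n_nucleosomes = as.integer(n_nucleosomes),
                 mean_repeat_length = mean_repeat_length,
                 repeat_jitter_sd = repeat_jitter_sd,
                 nfr_positions = nfr_positions,
                 acetylation_density = acetylation_density,
                 lh_density = lh_density,
                 chrom = chrom, start = as.integer(start),
                 seed = as.integer(seed)),
            class = "fiber_spec")
}

#' Generate a nucleosome track
#'
#' Draws dyad positions at the configured repeat length (with jitter and NFR
#' gaps) and Bernoulli acetylation/LH flags at the configured densities. This
#' emulates the inputs a practitioner would derive from MNase-seq nucleosome
#' calls and ChIP-seq peak calls.
#'
#' @param spec A [fiber_spec()].
#' @return A `data.frame` of class `nucleosome_track` with columns `chrom`,
#'   `dyad` (bp, strictly increasing, spaced >= 147 bp), `acetylated`
#'   (logical), `lh` (logical); attribute `spec` stores the generating spec.
#' @export
generate_nucleosome_track <- function(spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  n <- spec$n_nucleosomes
  rng <- local_rng(spec$seed)
  gaps <- rep(spec$mean_repeat_length, max(n - 1L, 0L))
  if (spec$repeat_jitter_sd > 0 && n > 1L) {
    gaps <- gaps + rng$norm(n - 1L) * spec$repeat_jitter_sd
    gaps <- pmax(gaps, 147)
  }
  dyads <- spec$start + c(0, cumsum(gaps))
  # realize NFRs: one extra gap inserted after the first dyad beyond each position
  for (nfr in spec$nfr_positions) {
    pos <- nfr[[1]]; len <- nfr[[2]]
    if (len < 0) stop("NFR length must be >= 0")
    idx <- which(dyads > pos)
    if (length(idx) && idx[1] > 1L) {
      shift <- seq_along(dyads) >= idx[1]
      dyads[shift] <- dyads[shift] + len
    }
  }
  dyads <- round(dyads)
  if (n > 1L && any(diff(dyads) < 147))
    stop("internal error: dyads closer than the 147 bp core footprint")
  ac <- rng$unif(n) < spec$acetylation_density
  lh <- rng$unif(n) < spec$lh_density
  out <- data.frame(chrom = spec$chrom, dyad = as.integer(dyads),
                    acetylated = ac, lh = lh)
  attr(out, "spec") <- spec
  class(out) <- c("nucleosome_track", "data.frame")
  out
}

#' Write / read a nucleosome track as tab-separated text
#'
#' Columns: chrom, dyad, acetyl_flag, lh_flag (flags as 0/1).
#' @param track A `nucleosome_track`.
#' @param path Output file path.
#' @export
write_track <- function(track, path) {
  df <- data.frame(chrom = track$chrom, dyad = track$dyad,
                   acetyl_flag = as.integer(track$acetylated),
                   lh_flag = as.integer(track$lh))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = df$chrom, dyad = as.integer(df$dyad),
                    acetylated = df$acetyl_flag > 0, lh = df$lh_flag > 0)
  class(out) <- c("nucleosome_track", "data.frame")
  out
}
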