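#' Condition presets: log-like and quiescent-like chromatin
#'
#' Two fiber compositions bracketing the biology: exponentially growing
#' ("log") chromatin is heavily acetylated with scarce linker histone
#' (acetylation density 61/222 = 0.275, LH density 0.05/nucleosome), while
#' quiescent chromatin is deacetylated with abundant linker histone
#' (3/228 = 0.013 acetylated, 0.29 LH/nucleosome). Both use the ~165 bp
#' repeat length. `n_nucleosomes` defaults to a desk-scale fiber; the
#' full-scale systems are 222 (log) and 228 (quiescent) nucleosomes.
#'
#' @param n_nucleosomes Number of nucleosomes.
#' @param seed Integer seed.
#' @return A [fiber_spec()].
#' @export
log_like_fiber_spec <- function(n_nucleosomes = 12, seed = 1L) {
  fiber_spec(n_nucleosomes, mean_repeat_length = 165, repeat_jitter_sd = 6,
             acetylation_density = 61 / 222, lh_density = 0.05, seed = seed)
}

#' @rdname log_like_fiber_spec
#' @export
quiescent_like_fiber_spec <- function(n_nucleosomes = 12, seed = 1L) {
  fiber_spec(n_nucleosomes, mean_repeat_length = 165, repeat_jitter_sd = 6,
             acetylation_density = 3 / 228, lh_density = 0.29, seed = seed)
}

#' Contact-pair presets: log-like and quiescent-like distance mixtures
#'
#' Synthetic pair sets with the decay-curve signatures of the two states:
#' the log-like mixture is n+1-dominated (neighbor weights falling steeply
#' with k, little mass beyond 500 bp), while the quiescent-like mixture
#' flattens the short-range neighbor modes and moves weight into the
#' 500-1000 bp band, as expected for a locally folded fiber.
#'
#' @param chrom_sizes Named chromosome sizes (bp).
#' @param n_pairs Number of pairs.
#' @param infacing_fraction Fraction of in-facing (contaminant) pairs.
#' @param anchors Optional anchor set for loop/stripe structure; loops are
#'   prominent in the quiescent-like preset (condensin-anchored loop
#'   domains) and weak in the log-like one.
#' @param anchor_loop_fraction,stripe_fraction Structured-pair fractions
#'   used when `anchors` is supplied (defaults differ per preset).
#' @param seed Integer seed.
#' @return A [contact_spec()].
#' @export
log_like_contact_spec <- function(chrom_sizes = c(chrS = 1e6),
                                  n_pairs = 1e5, infacing_fraction = 0.25,
                                  anchors = NULL,
                                  anchor_loop_fraction = if (is.null(anchors)) 0 else 0.03,
                                  stripe_fraction = if (is.null(anchors)) 0 else 0.05,
                                  seed = 1L) {
  contact_spec(chrom_sizes, n_pairs,
               neighbor_weights = c(1, 0.35, 0.15, 0.07, 0.03),
               long_range_weight = 0.08, background_weight = 0.04,
               anchors = anchors,
               anchor_loop_fraction = anchor_loop_fraction,
               stripe_fraction = stripe_fraction,
               infacing_fraction = infacing_fraction, seed = seed)
}

#' @rdname log_like_contact_spec
#' @export
quiescent_like_contact_spec <- function(chrom_sizes = c(chrS = 1e6),
                                        n_pairs = 1e5,
                                        infacing_fraction = 0.25,
                                        anchors = NULL,
                                        anchor_loop_fraction = if (is.null(anchors)) 0 else 0.08,
                                        stripe_fraction = if (is.null(anchors)) 0 else 0.10,
                                        seed = 1L) {
  contact_spec(chrom_sizes, n_pairs,
               neighbor_weights = c(0.45, 0.45, 0.30, 0.20, 0.12),
               long_range_weight = 0.30, background_weight = 0.04,
               anchors = anchors,
               anchor_loop_fraction = anchor_loop_fraction,
               stripe_fraction = stripe_fraction,
               infacing_fraction = infacing_fraction, seed = seed)
}
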