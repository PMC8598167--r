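#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# nucleosome tracks for the two chromatin states, Micro-C style contact
# pairs with log-like and quiescent-like distance mixtures, condensin-peak
# style anchors, and segmented tube volumes for the erosion analysis.
# Outputs are plain text under results/inputs/.

library(chromofold)

out <- file.path("results", "inputs")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930

# --- nucleosome tracks: desk-scale fibers for simulation, plus the
# full-scale compositions (222 log / 228 quiescent nucleosomes) for the
# record. Acetylation 61/222 vs 3/228; LH 0.05 vs 0.29 per nucleosome.
tracks <- list(
  log_desk = log_like_fiber_spec(12, seed = seed),
  quiescent_desk = quiescent_like_fiber_spec(12, seed = seed + 1),
  log_full = log_like_fiber_spec(222, seed = seed + 2),
  quiescent_full = quiescent_like_fiber_spec(228, seed = seed + 3))
for (nm in names(tracks)) {
  tr <- generate_nucleosome_track(tracks[[nm]])
  write_track(tr, file.path(out, paste0("track_", nm, ".tsv")))
  message(sprintf("track %-15s %3d nucleosomes, %2d acetylated, %2d LH",
                  nm, nrow(tr), sum(tr$acetylated), sum(tr$lh)))
}

# --- anchors emulating condensin peaks / loop-domain boundaries; each
# chromatin state gets its own set (loop anchors are state-specific)
cs <- c(chrS = 1e6)
anchors <- list(
  log = generate_anchors(cs, 12, min_spacing = 4e4, margin = 12000,
                         seed = seed + 20),
  quiescent = generate_anchors(cs, 12, min_spacing = 4e4, margin = 12000,
                               seed = seed + 21))
for (state in names(anchors)) {
  write_anchors_bed(anchors[[state]],
                    file.path(out, sprintf("anchors_%s.bed", state)))
  message(sprintf("%d %s anchors written", nrow(anchors[[state]]), state))
}

# --- contact pairs: 1e5 pairs on a 1 Mb synthetic chromosome per state,
# two replicate seeds each (for the reproducibility analysis); quiescent
# samples carry prominent anchor loops and stripes, log samples weak ones
for (state in c("log", "quiescent")) {
  for (rep in 1:2) {
    spec_fun <- if (state == "log") log_like_contact_spec
                else quiescent_like_contact_spec
    ps <- generate_contact_pairs(spec_fun(cs, n_pairs = 1e5,
                                          anchors = anchors[[state]],
                                          seed = seed + 10 * rep))
    write_pairs(ps, file.path(out, sprintf("pairs_%s_rep%d.pairs",
                                           state, rep)))
  }
}
message("pairs written: 2 states x 2 replicates x 1e5 pairs")

# --- segmented tube volumes (20/30/40 nm) for the erosion estimator;
# volumes are rebuilt on the fly by later stages, only their parameters
# are recorded here
params <- data.frame(diameter_nm = c(20, 30, 40), length_nm = 60,
                     voxel_nm = 0.5, noise_fraction = 0)
write.table(params, file.path(out, "tube_volumes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done")
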