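#!/usr/bin/env Rscript
# Fiber compaction statistics from the sampled trajectories: radius of
# gyration, sedimentation coefficient, packing ratio, alpha-shape volume,
# DBSCAN cluster statistics, internucleosome contact maps with their I(k)
# neighbor profiles, and the tail-interaction matrices T'/T.
# Reads results/fibers/, writes results/stats/.

library(chromofold)

ind <- file.path("results", "fibers")
out <- file.path("results", "stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

summaries <- data.frame()
for (state in c("log", "quiescent")) {
  trajs <- readRDS(file.path(ind, paste0("trajectories_", state, ".rds")))

  cs <- compaction_summary(trajs)
  cs$state <- state
  summaries <- rbind(summaries, cs)

  cmap <- internucleosome_contact_map(trajs)
  write.table(cmap, file.path(out, paste0("contact_map_", state, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  prof <- neighbor_profile(cmap)
  write.table(prof, file.path(out, paste0("neighbor_profile_", state,
                                          ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: I(1) = %.3f, I(2) = %.3f, sum I(k>=3) = %.3f",
                  state, prof$intensity[1], prof$intensity[2],
                  sum(prof$intensity[-(1:2)])))

  tim <- tail_interaction_matrix(trajs)
  write.table(round(tim$T_raw, 4),
              file.path(out, paste0("tail_T_raw_", state, ".tsv")),
              sep = "\t", quote = FALSE)
  write.table(round(tim$T_norm, 4),
              file.path(out, paste0("tail_T_norm_", state, ".tsv")),
              sep = "\t", quote = FALSE)
}
write.table(summaries, file.path(out, "compaction_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("compaction summary (mean +- SE across seeds):")
print(summaries, digits = 4, row.names = FALSE)
message(paste(
  "expected directional pattern: the quiescent-like fiber has smaller Rg,",
  "larger sedimentation coefficient, larger packing ratio and a larger",
  "tail-core contact fraction than the log-like fiber"))
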