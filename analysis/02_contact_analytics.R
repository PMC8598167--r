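#!/usr/bin/env Rscript
# Micro-C style analytics on the synthetic pair sets: orientation filtering,
# contact-probability decay curves, long/short odds ratios, anchor pileups
# and the stratum-adjusted correlation coefficient (SCC) between samples.
# Reads results/inputs/, writes results/contacts/.

library(chromofold)

ind <- file.path("results", "inputs")
out <- file.path("results", "contacts")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

anchors <- list(
  log = read_anchors_bed(file.path(ind, "anchors_log.bed")),
  quiescent = read_anchors_bed(file.path(ind, "anchors_quiescent.bed")))
states <- c("log", "quiescent")

filtered <- list(); matrices200 <- list(); matrices5k <- list()
odds <- data.frame()
curves <- data.frame()
for (state in states) for (rep in 1:2) {
  key <- sprintf("%s_rep%d", state, rep)
  ps <- read_pairs(file.path(ind, sprintf("pairs_%s.pairs", key)))
  fl <- classify_and_filter_pairs(ps, drop_infacing = TRUE)
  filtered[[key]] <- fl
  matrices200[[key]] <- bin_pairs(fl, 200)
  matrices5k[[key]] <- bin_pairs(fl, 5000)
  cur <- decay_curve(fl, bin_size = 10)
  o <- odds_ratio(cur)
  odds <- rbind(odds, data.frame(sample = key,
                                 dropped_infacing = attr(fl, "n_dropped")[1],
                                 odds_ratio = o$odds,
                                 long_mass = o$long_mass,
                                 short_mass = o$short_mass))
  tand <- cur[cur$orientation == "tandem" & cur$distance <= 1500, ]
  tand$sample <- key
  curves <- rbind(curves, tand)
}
write.table(odds, file.path(out, "odds_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(curves, file.path(out, "decay_curves_tandem.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("odds ratios (long 500-1000 bp over short 50-500 bp):")
print(odds[, c("sample", "odds_ratio")], row.names = FALSE)
message("the quiescent-like mixture should sit well above the log-like one")

# --- pileups on the 200 bp matrices: intra- and inter-anchor aggregates,
# and the quiescent-minus-log difference map
for (state in states) {
  m <- matrices200[[paste0(state, "_rep1")]]
  for (mode in c("intra", "inter")) {
    p <- pileup(m, anchors[[state]], half_width = 10000,
                stat = "median", mode = mode)
    write.table(p$matrix,
                file.path(out, sprintf("pileup_%s_%s.tsv", state, mode)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    message(sprintf("pileup %s/%s: %d submatrices, %d edge anchors dropped",
                    state, mode, p$n_submatrices, p$n_edge_dropped))
  }
}
pq <- pileup(matrices200[["quiescent_rep1"]], anchors$quiescent,
             mode = "intra")
pl <- pileup(matrices200[["log_rep1"]], anchors$log, mode = "intra")
write.table(pileup_difference(pq, pl),
            file.path(out, "pileup_diff_quiescent_minus_log.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

# --- reproducibility: SCC between replicates (same state, high) and
# between states (lower), on 5 kb matrices up to 100 kb
scc <- data.frame(
  comparison = c("log_rep1_vs_rep2", "quiescent_rep1_vs_rep2",
                 "log_vs_quiescent"),
  scc = c(hicrep_scc(matrices5k[["log_rep1"]], matrices5k[["log_rep2"]])$median,
          hicrep_scc(matrices5k[["quiescent_rep1"]],
                     matrices5k[["quiescent_rep2"]])$median,
          hicrep_scc(matrices5k[["log_rep1"]],
                     matrices5k[["quiescent_rep1"]])$median))
write.table(scc, file.path(out, "scc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
print(scc, row.names = FALSE)
message("done")
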