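# Micro-C analytics: classification, binning, decay, odds ratio, pileups, SCC.

test_that("orientation classification and filtering follow the strand rules", {
  ps <- toy_pairs()
  out <- classify_and_filter_pairs(ps, drop_infacing = FALSE)
  # canonical +/- is "in", -/+ is "out", ++/-- are tandem; record 2 swaps
  # ends (500 > 450), turning -/+ into -/+ read pair at sorted coordinates
  expect_equal(as.character(out$orientation),
               c("in", "in", "tandem", "in", "tandem", "out"))
  # idempotence on a set with no in-facing pairs
  no_in <- out[out$orientation != "in", ]
  attr(no_in, "chrom_sizes") <- attr(ps, "chrom_sizes")
  class(no_in) <- class(ps)
  again <- classify_and_filter_pairs(no_in, drop_infacing = TRUE)
  expect_equal(nrow(again), nrow(no_in))
  # in-facing dropped when flagged
  dropped <- classify_and_filter_pairs(ps, drop_infacing = TRUE)
  expect_equal(nrow(dropped), 3)
  expect_equal(unname(attr(dropped, "n_dropped")["infacing"]), 3L)
  # exclusion regions remove overlapping pairs
  excl <- data.frame(chrom = "chrT", start = 1190, end = 1300)
  kept <- classify_and_filter_pairs(ps, drop_infacing = FALSE,
                                    exclude_regions = excl)
  expect_equal(nrow(kept), 5)
  # invalid strands are rejected with a record number
  bad <- ps; bad$strand1[3] <- "."
  expect_error(classify_and_filter_pairs(bad), "record 3")
})

test_that("binning matches coordinate arithmetic and conserves counts", {
  df <- data.frame(readID = "r", chrom1 = "c1", pos1 = 5L, strand1 = "+",
                   chrom2 = "c1", pos2 = 15L, strand2 = "+")
  attr(df, "chrom_sizes") <- c(c1 = 100)
  class(df) <- c("pairs_table", "data.frame")
  m <- bin_pairs(df, 10)
  expect_equal(m$bin1, 0L)
  expect_equal(m$bin2, 1L)
  expect_equal(m$count, 1L)

  # random pairs equal a dictionary-count oracle, totals conserved
  set.seed(31)
  n <- 1000
  ps <- data.frame(readID = sprintf("r%d", 1:n), chrom1 = "c1",
                   pos1 = sample.int(5000, n, TRUE), strand1 = "+",
                   chrom2 = "c1", pos2 = sample.int(5000, n, TRUE),
                   strand2 = "-")
  attr(ps, "chrom_sizes") <- c(c1 = 5000)
  class(ps) <- c("pairs_table", "data.frame")
  m2 <- bin_pairs(ps, 100)
  expect_equal(attr(m2, "total_count"), n)
  oracle <- new.env()
  for (i in seq_len(n)) {
    b <- sort(c((ps$pos1[i] - 1) %/% 100, (ps$pos2[i] - 1) %/% 100))
    key <- paste(b[1], b[2])
    oracle[[key]] <- (if (is.null(oracle[[key]])) 0 else oracle[[key]]) + 1
  }
  for (r in seq_len(nrow(m2))) {
    expect_equal(oracle[[paste(m2$bin1[r], m2$bin2[r])]], m2$count[r])
  }
  expect_equal(sum(m2$count), n)

  # positions beyond the chromosome are rejected
  bad <- ps; bad$pos2[7] <- 9999L
  expect_error(bin_pairs(bad, 100), "bounds")
})

test_that("decay curves are normalized and match the worked diagonal example", {
  # 1001-bin chromosome, 100 pairs at d=160, 50 at d=320:
  # (100/985) and (50/969), renormalized
  pos1 <- c(rep(1L, 100), rep(1L, 50))
  pos1 <- pos1 + as.integer(c(seq(0, 8200, length.out = 100),
                              seq(0, 6500, length.out = 50))) %/% 10L * 10L
  df <- data.frame(readID = sprintf("r%d", 1:150), chrom1 = "c1", pos1 = pos1,
                   strand1 = "+", chrom2 = "c1",
                   pos2 = pos1 + c(rep(160L, 100), rep(320L, 50)),
                   strand2 = "+")
  attr(df, "chrom_sizes") <- c(c1 = 10010)
  class(df) <- c("pairs_table", "data.frame")
  cur <- decay_curve(df, by_orientation = FALSE)
  expect_equal(sum(cur$probability), 1, tolerance = 1e-12)
  p160 <- (100 / 985); p320 <- (50 / 969)
  expect_equal(cur$probability[cur$distance == 160], p160 / (p160 + p320),
               tolerance = 1e-12)
  expect_equal(cur$probability[cur$distance == 320], p320 / (p160 + p320),
               tolerance = 1e-12)

  # all counts on one diagonal: that stratum has probability 1
  one <- df[1:100, ]; attr(one, "chrom_sizes") <- c(c1 = 10010)
  class(one) <- class(df)
  cur1 <- decay_curve(one, by_orientation = FALSE)
  expect_equal(cur1$probability[cur1$distance == 160], 1)

  # orientation-stratified curves each sum to one
  ps <- generate_contact_pairs(log_like_contact_spec(n_pairs = 2e4, seed = 2))
  cls <- classify_and_filter_pairs(ps)
  cur2 <- decay_curve(cls)
  sums <- tapply(cur2$probability, cur2$orientation, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # against an independent raw-distance oracle
  sub <- cls[cls$orientation == "tandem", ]
  attr(sub, "chrom_sizes") <- attr(ps, "chrom_sizes")
  class(sub) <- class(ps)
  got <- decay_curve(sub, by_orientation = FALSE)
  want <- oracle_decay(sub, 1e6)
  merged <- merge(got, want, by = "distance")
  expect_equal(merged$probability.x, merged$probability.y, tolerance = 1e-9)
})

test_that("decay curves are invariant to record order and chromosome labels", {
  ps <- generate_contact_pairs(
    contact_spec(c(a = 2e5, b = 2e5), 2e4, seed = 5))
  cls <- classify_and_filter_pairs(ps)
  cur <- decay_curve(cls, by_orientation = FALSE)
  # permuted records
  perm <- cls[sample.int(nrow(cls)), ]
  attr(perm, "chrom_sizes") <- attr(cls, "chrom_sizes")
  class(perm) <- class(cls)
  expect_equal(decay_curve(perm, by_orientation = FALSE)$probability,
               cur$probability, tolerance = 1e-12)
  # relabeled chromosomes
  rel <- cls
  rel$chrom1 <- ifelse(rel$chrom1 == "a", "z", "y")
  rel$chrom2 <- rel$chrom1
  cs <- attr(cls, "chrom_sizes"); names(cs) <- c("z", "y")
  attr(rel, "chrom_sizes") <- cs
  class(rel) <- class(cls)
  expect_equal(decay_curve(rel, by_orientation = FALSE)$probability,
               cur$probability, tolerance = 1e-12)
})

test_that("odds ratio uses half-open bands and flags degenerate input", {
  # uniform mass per 10 bp stratum over [50, 1000): 50 long / 45 short strata
  cur <- data.frame(distance = seq(50, 990, by = 10),
                    probability = 1 / 95)
  o <- odds_ratio(cur)
  expect_equal(o$odds, 50 / 45, tolerance = 1e-12)
  # all mass at 600 bp: short-range mass zero, explicitly undefined
  cur2 <- data.frame(distance = 600, probability = 1)
  o2 <- odds_ratio(cur2)
  expect_false(o2$defined)
  expect_true(is.na(o2$odds))
})

test_that("higher configured long-range mass raises the odds ratio", {
  odds_at <- function(w, seed) {
    sp <- contact_spec(c(chrA = 1e6), 1e5, long_range_weight = w,
                       background_weight = 0.05, seed = seed)
    ps <- classify_and_filter_pairs(generate_contact_pairs(sp))
    odds_ratio(decay_curve(ps))$odds
  }
  for (seed in 1:3) {
    expect_gt(odds_at(0.4, seed), odds_at(0.1, seed))
  }
})

test_that("pileups equal the brute-force submatrix aggregate", {
  cs <- c(chrA = 4e5)
  anchors <- generate_anchors(cs, 6, min_spacing = 5e4, margin = 15000,
                              seed = 3)
  sp <- contact_spec(cs, 3e4, anchor_loop_fraction = 0.2,
                     stripe_fraction = 0.1, anchors = anchors, seed = 7)
  ps <- classify_and_filter_pairs(generate_contact_pairs(sp))
  m200 <- bin_pairs(ps, 200)

  # single anchor, intra: the pileup is that window's own submatrix
  one <- anchors[3, , drop = FALSE]
  p1 <- pileup(m200, one, mode = "intra")
  expect_equal(p1$n_submatrices, 1)
  dm <- dense_matrix(m200, "chrA")
  b <- (one$pos - 1) %/% 200
  w <- 10000 / 200
  expect_equal(p1$matrix, dm[(b - w + 1):(b + w), (b - w + 1):(b + w)])

  # inter mode equals explicit enumeration over ordered anchor pairs
  p2 <- pileup(m200, anchors, mode = "inter")
  wins <- lapply(anchors$pos, function(p) {
    b <- (p - 1) %/% 200
    (b - w + 1):(b + w)
  })
  blocks <- list()
  for (i in seq_along(wins)) for (j in seq_along(wins)) {
    if (i != j) blocks[[length(blocks) + 1]] <- dm[wins[[i]], wins[[j]]]
  }
  expect_equal(p2$n_submatrices, length(blocks))
  arr <- array(unlist(blocks), dim = c(2 * w, 2 * w, length(blocks)))
  expect_equal(p2$matrix, apply(arr, c(1, 2), median))

  # identical submatrices: median equals mean equals any one of them
  p3m <- pileup(m200, one, mode = "intra", stat = "mean")
  expect_equal(p3m$matrix, p1$matrix)

  # edge anchors are dropped and counted
  edge <- rbind(anchors, data.frame(chrom = "chrA", pos = 300L))
  class(edge) <- class(anchors)
  p4 <- pileup(m200, edge, mode = "intra")
  expect_equal(p4$n_edge_dropped, 1)
})

test_that("pileup differences are antisymmetric and shape-checked", {
  cs <- c(chrA = 2e5)
  anchors <- generate_anchors(cs, 4, min_spacing = 3e4, margin = 11000,
                              seed = 1)
  ps <- classify_and_filter_pairs(generate_contact_pairs(
    contact_spec(cs, 2e4, seed = 1)))
  ps2 <- classify_and_filter_pairs(generate_contact_pairs(
    contact_spec(cs, 2e4, seed = 2)))
  a <- pileup(bin_pairs(ps, 200), anchors)
  b <- pileup(bin_pairs(ps2, 200), anchors)
  expect_equal(pileup_difference(a, a), matrix(0, 100, 100))
  expect_equal(pileup_difference(a, b), -pileup_difference(b, a))
  small <- pileup(bin_pairs(ps, 200), anchors, half_width = 5000)
  expect_error(pileup_difference(a, small), "shape")
})

test_that("SCC is 1 for identical and scaled matrices, symmetric in arguments", {
  cs <- c(chrA = 5e5, chrB = 3e5)
  ps <- classify_and_filter_pairs(generate_contact_pairs(
    contact_spec(cs, 5e4, seed = 9)))
  m <- bin_pairs(ps, 5000)
  self <- hicrep_scc(m, m)
  expect_equal(unname(self$per_chromosome), c(1, 1), tolerance = 1e-12)
  expect_equal(self$median, 1, tolerance = 1e-12)
  # scale invariance: 7x counts
  m7 <- m; m7$count <- m7$count * 7L
  attributes(m7) <- attributes(m)
  m7$count <- m$count * 7L
  expect_equal(hicrep_scc(m, m7)$median, 1, tolerance = 1e-12)
  # symmetry
  ps2 <- classify_and_filter_pairs(generate_contact_pairs(
    contact_spec(cs, 5e4, seed = 10)))
  m2 <- bin_pairs(ps2, 5000)
  expect_equal(hicrep_scc(m, m2)$median, hicrep_scc(m2, m)$median,
               tolerance = 1e-12)
})

test_that("SCC matches a direct weighted-correlation oracle on small toys", {
  # two single-chromosome 6x6 matrices, bin 1, no smoothing
  make_bm <- function(mat, chrom = "t") {
    idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
    df <- data.frame(chrom = chrom, bin1 = idx[, 1] - 1L,
                     bin2 = idx[, 2] - 1L, count = mat[idx])
    attr(df, "bin_size") <- 1
    attr(df, "chrom_sizes") <- stats::setNames(nrow(mat), chrom)
    attr(df, "n_bins") <- stats::setNames(nrow(mat), chrom)
    class(df) <- c("binned_matrix", "data.frame")
    df
  }
  set.seed(77)
  a <- matrix(rpois(36, 5), 6); a <- a + t(a)
  b <- matrix(rpois(36, 5), 6); b <- b + t(b)
  scc <- hicrep_scc(make_bm(a), make_bm(b), max_distance = 5, h = 0)
  # oracle: stratum-by-stratum weighted Pearson on normalized matrices
  an <- a / sum(a); bn <- b / sum(b)
  num <- 0; den <- 0
  for (d in 0:5) {
    i <- seq_len(6 - d)
    x <- an[cbind(i, i + d)]; y <- bn[cbind(i, i + d)]
    if (length(x) < 2 || var(x) == 0 || var(y) == 0) next
    wgt <- length(x) * sqrt(var(x) * var(y))
    num <- num + wgt * cor(x, y); den <- den + wgt
  }
  expect_equal(unname(scc$per_chromosome["t"]), num / den, tolerance = 1e-12)
})

test_that("pair counts are conserved through the pipeline", {
  cs <- c(chrA = 3e5)
  ps <- generate_contact_pairs(contact_spec(cs, 2e4, seed = 12))
  cls <- classify_and_filter_pairs(ps)
  m <- bin_pairs(cls, 200)
  dropped <- sum(attr(cls, "n_dropped")) + attr(m, "n_inter_dropped")
  expect_equal(attr(m, "total_count") + dropped, nrow(ps))
})
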