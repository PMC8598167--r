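#' Classify pair orientations and filter a pairs table
#'
#' Canonically orders each record so that `(chrom1, pos1) <= (chrom2, pos2)`
#' (swapping strands along with coordinates), then assigns the ligation-pair
#' orientation from the strand combination: `+/-` is "in" (reads pointing
#' toward each other), `-/+` is "out", and `++` or `--` is "tandem" (the
#' "same" class). In-facing pairs are the signature of undigested
#' di-nucleosomes and can be dropped. Pairs with either end inside an
#' exclusion region (for example an rDNA mask) are removed.
#'
#' @param pairs A `pairs_table` (see [read_pairs()] / [generate_contact_pairs()]).
#' @param drop_infacing Drop pairs classified "in" (default TRUE).
#' @param exclude_regions Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based, closed); pairs with either position inside any region are
#'   removed.
#' @return The filtered `pairs_table` with an added `orientation` column
#'   (factor: in/out/tandem) and attribute `n_dropped` (named count).
#' @export
classify_and_filter_pairs <- function(pairs, drop_infacing = TRUE,
                                      exclude_regions = NULL) {
  required <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(required %in% names(pairs)))
    stop("pairs table lacks required columns: ",
         paste(setdiff(required, names(pairs)), collapse = ", "))
  if (!all(pairs$strand1 %in% c("+", "-") & pairs$strand2 %in% c("+", "-"))) {
    bad <- which(!(pairs$strand1 %in% c("+", "-") &
                   pairs$strand2 %in% c("+", "-")))[1]
    stop(sprintf("missing/invalid strand at record %d", bad))
  }
  cs <- attr(pairs, "chrom_sizes")
  # canonical ordering: sort the two ends, carrying strands along
  swap <- (pairs$chrom1 > pairs$chrom2) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, c("chrom1", "pos1", "strand1")]
    pairs[swap, c("chrom1", "pos1", "strand1")] <-
      pairs[swap, c("chrom2", "pos2", "strand2")]
    pairs[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  orientation <- ifelse(pairs$strand1 == pairs$strand2, "tandem",
                        ifelse(pairs$strand1 == "+", "in", "out"))
  pairs$orientation <- factor(orientation, levels = c("in", "out", "tandem"))
  n0 <- nrow(pairs)
  n_in <- 0L
  if (drop_infacing) {
    keep <- pairs$orientation != "in"
    n_in <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
  }
  n_excl <- 0L
  if (!is.null(exclude_regions) && nrow(exclude_regions) > 0) {
    hit <- rep(FALSE, nrow(pairs))
    for (i in seq_len(nrow(exclude_regions))) {
      r <- exclude_regions[i, ]
      hit <- hit |
        (pairs$chrom1 == r$chrom & pairs$pos1 >= r$start & pairs$pos1 <= r$end) |
        (pairs$chrom2 == r$chrom & pairs$pos2 >= r$start & pairs$pos2 <= r$end)
    }
    n_excl <- sum(hit)
    pairs <- pairs[!hit, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  attr(pairs, "chrom_sizes") <- cs
  attr(pairs, "n_dropped") <- c(infacing = n_in, excluded = n_excl)
  class(pairs) <- c("pairs_table", "data.frame")
  pairs
}

#' Bin pairs into per-chromosome contact matrices
#'
#' Each intra-chromosomal pair increments the symmetric cell
#' `(floor((pos1-1)/bin), floor((pos2-1)/bin))`; bins are 0-based and the
#' matrix is stored sparsely as its upper triangle (`bin1 <= bin2`).
#' Inter-chromosomal pairs are not binned (counted as dropped).
#'
#' @param pairs A `pairs_table` (canonical order assumed; run
#'   [classify_and_filter_pairs()] first to classify orientations).
#' @param bin_size Bin width in bp (> 0); the analyses in this package use
#'   10, 200 and 5000 bp.
#' @param chrom_sizes Named chromosome sizes (bp); default from the table.
#' @return Object of class `binned_matrix`: a `data.frame` with columns
#'   `chrom`, `bin1`, `bin2`, `count`, plus attributes `bin_size`,
#'   `chrom_sizes`, `n_bins` (named per chromosome), `total_count`.
#' @export
bin_pairs <- function(pairs, bin_size,
                      chrom_sizes = attr(pairs, "chrom_sizes")) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (is.null(chrom_sizes)) stop("chrom_sizes required (attribute or argument)")
  intra <- pairs$chrom1 == pairs$chrom2
  df <- pairs[intra, c("chrom1", "pos1", "pos2")]
  if (nrow(df)) {
    bad <- df$pos1 < 1 | df$pos2 < 1 |
      df$pos1 > chrom_sizes[df$chrom1] | df$pos2 > chrom_sizes[df$chrom1]
    if (any(bad, na.rm = TRUE) || anyNA(bad))
      stop(sprintf("position outside chromosome bounds at intra-pair %d",
                   which(bad | is.na(bad))[1]))
  }
  dt <- data.table::data.table(
    chrom = df$chrom1,
    bin1 = (df$pos1 - 1L) %/% as.integer(bin_size),
    bin2 = (df$pos2 - 1L) %/% as.integer(bin_size))
  lo <- pmin(dt$bin1, dt$bin2); hi <- pmax(dt$bin1, dt$bin2)
  dt$bin1 <- lo; dt$bin2 <- hi
  agg <- dt[, .N, by = c("chrom", "bin1", "bin2")]
  data.table::setnames(agg, "N", "count")
  data.table::setorderv(agg, c("chrom", "bin1", "bin2"))
  out <- as.data.frame(agg)
  attr(out, "bin_size") <- bin_size
  attr(out, "chrom_sizes") <- chrom_sizes
  attr(out, "n_bins") <- stats::setNames(
    as.integer(ceiling(chrom_sizes / bin_size)), names(chrom_sizes))
  attr(out, "total_count") <- sum(out$count)
  attr(out, "n_inter_dropped") <- sum(!intra)
  class(out) <- c("binned_matrix", "data.frame")
  out
}

#' Extract one chromosome of a binned matrix as a dense symmetric matrix
#'
#' @param mat A `binned_matrix`.
#' @param chrom Chromosome name.
#' @return Dense symmetric numeric matrix (bins x bins).
#' @export
dense_matrix <- function(mat, chrom) {
  nb <- attr(mat, "n_bins")[[chrom]]
  if (is.null(nb)) stop("unknown chromosome: ", chrom)
  m <- matrix(0, nb, nb)
  sub <- mat[mat$chrom == chrom, ]
  if (nrow(sub)) {
    m[cbind(sub$bin1 + 1L, sub$bin2 + 1L)] <- sub$count
    m[cbind(sub$bin2 + 1L, sub$bin1 + 1L)] <- sub$count
  }
  m
}

#' Contact-probability decay curve
#'
#' For each genomic-distance stratum (one stratum per 10 bp diagonal by
#' default) the contact counts on that diagonal are summed and divided by the
#' number of elements in the diagonal; the resulting curve is normalized to
#' sum to one over all strata. When the input carries an `orientation`
#' column the curve is computed separately per orientation class.
#'
#' @param x A `pairs_table` (binned internally at `bin_size`) or a
#'   `binned_matrix`.
#' @param bin_size Stratum width in bp when `x` is a pairs table (default 10).
#' @param by_orientation Stratify by orientation class when available.
#' @param per_chromosome If TRUE normalize per chromosome; default pools
#'   diagonal sums and element counts genome-wide before normalizing.
#' @param max_distance Optional largest distance (bp) retained, applied
#'   before normalization over the retained strata.
#' @return `data.frame` of class `decay_curve` with columns `orientation`
#'   (factor, "all" when unstratified), `distance` (bp, the diagonal offset
#'   times the bin size), `probability`.
#' @export
decay_curve <- function(x, bin_size = 10, by_orientation = TRUE,
                        per_chromosome = FALSE, max_distance = NULL) {
  if (inherits(x, "binned_matrix")) {
    groups <- list(all = x)
  } else {
    if (by_orientation && !is.null(x$orientation)) {
      groups <- lapply(split(seq_len(nrow(x)), x$orientation, drop = TRUE),
                       function(i) {
                         g <- x[i, , drop = FALSE]
                         attr(g, "chrom_sizes") <- attr(x, "chrom_sizes")
                         class(g) <- class(x)
                         bin_pairs(g, bin_size)
                       })
    } else {
      groups <- list(all = bin_pairs(x, bin_size))
    }
  }
  res <- lapply(names(groups), function(g) {
    mat <- groups[[g]]
    if (sum(mat$count) == 0) stop("empty matrix: no contacts to normalize")
    bs <- attr(mat, "bin_size")
    nb <- attr(mat, "n_bins")
    d <- mat$bin2 - mat$bin1
    sums <- tapply(mat$count, list(chrom = mat$chrom, d = d), sum)
    per_chr <- lapply(rownames(sums), function(ch) {
      dd <- as.integer(colnames(sums))
      s <- sums[ch, ]
      keep <- !is.na(s)
      data.frame(chrom = ch, d = dd[keep], sum = unname(s[keep]),
                 n_elem = nb[[ch]] - dd[keep])
    })
    tab <- do.call(rbind, per_chr)
    if (!is.null(max_distance)) tab <- tab[tab$d * bs <= max_distance, ]
    if (per_chromosome) {
      parts <- lapply(split(tab, tab$chrom), function(t2) {
        p <- (t2$sum / t2$n_elem)
        data.frame(chrom = t2$chrom, distance = t2$d * bs,
                   probability = p / sum(p))
      })
      cur <- do.call(rbind, parts)
    } else {
      agg <- stats::aggregate(cbind(sum, n_elem) ~ d, data = tab, FUN = sum)
      p <- agg$sum / agg$n_elem
      cur <- data.frame(distance = agg$d * bs, probability = p / sum(p))
    }
    cur$orientation <- g
    cur
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$orientation <- factor(out$orientation)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Long/short contact-probability odds ratio
#'
#' Ratio of the cumulative contact probability in the long-range band
#' `[500, 1000)` bp to that in the short-range band `[50, 500)` bp
#' (half-open intervals). An elevated odds ratio is the decay-curve
#' signature of a locally folded fiber.
#'
#' @param curve A [decay_curve()]; if stratified, `orientation` selects the
#'   class ("tandem" by default, the class used for all headline curves).
#' @param short Two-element numeric, the short-range band (bp, half-open).
#' @param long Two-element numeric, the long-range band (bp, half-open).
#' @param orientation Orientation class to use when the curve is stratified.
#' @return List of class `odds_ratio`: `odds` (numeric, NA when undefined),
#'   `long_mass`, `short_mass`, `defined`.
#' @export
odds_ratio <- function(curve, short = c(50, 500), long = c(500, 1000),
                       orientation = NULL) {
  if (!is.null(curve$orientation) && nlevels(curve$orientation) > 1) {
    if (is.null(orientation))
      orientation <- if ("tandem" %in% levels(curve$orientation)) "tandem"
        else levels(curve$orientation)[1]
    curve <- curve[curve$orientation == orientation, , drop = FALSE]
  }
  s <- sum(curve$probability[curve$distance >= short[1] &
                             curve$distance < short[2]])
  l <- sum(curve$probability[curve$distance >= long[1] &
                             curve$distance < long[2]])
  if (s <= 0) {
    return(structure(list(odds = NA_real_, long_mass = l, short_mass = s,
                          defined = FALSE), class = "odds_ratio"))
  }
  structure(list(odds = l / s, long_mass = l, short_mass = s, defined = TRUE),
            class = "odds_ratio")
}

#' Anchor-centred pileup of a contact matrix
#'
#' Defines a window of `2 * half_width` centred on each anchor and aggregates
#' the window-by-window submatrices element-wise (median by default; the
#' median over an even number of submatrices is the mean of the two central
#' order statistics). `mode = "intra"` aggregates each window against itself;
#' `mode = "inter"` aggregates blocks between distinct same-chromosome anchor
#' windows (both orders, so the pileup stays symmetric for symmetric input).
#' Anchors whose window leaves the chromosome are dropped and counted.
#'
#' @param mat A `binned_matrix` (200 bp bins in the standard analysis).
#' @param anchors An `anchor_set`.
#' @param half_width Window half-width in bp (default 10 kb).
#' @param stat "median" or "mean".
#' @param mode "intra" or "inter".
#' @param include_interchrom Inter-chromosomal anchor pairs are excluded by
#'   default (and are never available from intra-chromosomal matrices).
#' @return Object of class `pileup`: list with `matrix` (dense, bins x bins),
#'   `n_submatrices`, `n_edge_dropped`, `stat`, `mode`, `bin_size`,
#'   `half_width`.
#' @export
pileup <- function(mat, anchors, half_width = 10000, stat = c("median", "mean"),
                   mode = c("intra", "inter"), include_interchrom = FALSE) {
  stat <- match.arg(stat); mode <- match.arg(mode)
  if (include_interchrom)
    stop("inter-chromosomal pileups are not supported for intra-chromosomal matrices")
  bs <- attr(mat, "bin_size")
  nb_all <- attr(mat, "n_bins")
  w <- as.integer(half_width / bs)          # bins per side
  if (w < 1) stop("half_width smaller than one bin")
  dense <- lapply(names(nb_all), function(ch) dense_matrix(mat, ch))
  names(dense) <- names(nb_all)

  # window rows for anchor at pos: bins [b - w, b + w - 1], b = 0-based bin
  win <- function(ch, pos) {
    b <- (pos - 1L) %/% as.integer(bs)
    lo <- b - w; hi <- b + w - 1L
    if (lo < 0 || hi >= nb_all[[ch]]) return(NULL)
    (lo:hi) + 1L
  }
  wins <- lapply(seq_len(nrow(anchors)),
                 function(i) win(anchors$chrom[i], anchors$pos[i]))
  ok <- !vapply(wins, is.null, TRUE)
  n_edge <- sum(!ok)
  wins <- wins[ok]
  chr <- anchors$chrom[ok]

  subs <- list()
  if (mode == "intra") {
    for (i in seq_along(wins))
      subs[[length(subs) + 1L]] <- dense[[chr[i]]][wins[[i]], wins[[i]]]
  } else {
    for (i in seq_along(wins)) for (j in seq_along(wins)) {
      if (i == j || chr[i] != chr[j]) next
      subs[[length(subs) + 1L]] <- dense[[chr[i]]][wins[[i]], wins[[j]]]
    }
  }
  if (length(subs) == 0) stop("no contributing submatrices")
  arr <- array(unlist(subs), dim = c(2L * w, 2L * w, length(subs)))
  agg <- apply(arr, c(1, 2), if (stat == "median") stats::median else mean)
  structure(list(matrix = agg, n_submatrices = length(subs),
                 n_edge_dropped = n_edge, stat = stat, mode = mode,
                 bin_size = bs, half_width = half_width),
            class = "pileup")
}

#' Difference between two pileups
#'
#' Element-wise `a - b`; shapes, bin sizes and statistics must match.
#' @param a,b `pileup` objects.
#' @return Numeric matrix.
#' @export
pileup_difference <- function(a, b) {
  if (!identical(dim(a$matrix), dim(b$matrix)))
    stop("pileup shapes differ")
  if (a$bin_size != b$bin_size || a$stat != b$stat)
    stop("pileups have different bin size or statistic")
  a$matrix - b$matrix
}

#' Stratum-adjusted correlation coefficient (SCC) between two contact maps
#'
#' HiCRep-style reproducibility score. Each matrix is normalized by its total
#' contact sum, optionally smoothed with a (2h+1)^2 mean filter, and compared
#' stratum by stratum: for each diagonal `d` up to `max_distance`, the Pearson
#' correlation `r_d` between the two diagonals is combined with weight
#' `w_d = N_d * sqrt(var_d(x) * var_d(y))`, giving
#' `SCC = sum(w_d r_d) / sum(w_d)`. Zero-variance strata carry zero weight.
#' The per-chromosome SCCs and their median are reported.
#'
#' @param m1,m2 `binned_matrix` objects on the same chromosomes and bin size
#'   (5000 bp in the standard analysis).
#' @param max_distance Largest genomic distance used (default 100 kb).
#' @param h Smoothing half-width in bins (default 1; 0 disables smoothing).
#' @return List of class `scc_result`: `per_chromosome` (named numeric),
#'   `median`, `max_distance`, `h`.
#' @export
hicrep_scc <- function(m1, m2, max_distance = 100000, h = 1) {
  bs <- attr(m1, "bin_size")
  if (!identical(bs, attr(m2, "bin_size")))
    stop("bin sizes differ")
  chroms <- names(attr(m1, "n_bins"))
  if (!setequal(chroms, names(attr(m2, "n_bins"))))
    stop("chromosome sets differ")
  if (max_distance %% bs != 0)
    stop("max_distance must be a multiple of the bin size")
  dmax <- as.integer(max_distance / bs)
  per <- vapply(chroms, function(ch) {
    a <- dense_matrix(m1, ch); b <- dense_matrix(m2, ch)
    if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
    a <- a / sum(a); b <- b / sum(b)
    if (h > 0) { a <- mean_filter(a, h); b <- mean_filter(b, h) }
    num <- 0; den <- 0
    for (d in 0:min(dmax, nrow(a) - 1L)) {
      i <- seq_len(nrow(a) - d)
      x <- a[cbind(i, i + d)]; y <- b[cbind(i, i + d)]
      vx <- stats::var(x); vy <- stats::var(y)
      if (length(x) < 2 || is.na(vx) || vx == 0 || vy == 0) next
      r <- stats::cor(x, y)
      wgt <- length(x) * sqrt(vx * vy)
      num <- num + wgt * r
      den <- den + wgt
    }
    if (den == 0) NA_real_ else num / den
  }, 1.0)
  structure(list(per_chromosome = per,
                 median = stats::median(per, na.rm = TRUE),
                 max_distance = max_distance, h = h),
            class = "scc_result")
}

# (2h+1)^2 moving-average filter with edge truncation (window clipped at the
# matrix border, divisor = actual window size)
mean_filter <- function(m, h) {
  n <- nrow(m); p <- ncol(m)
  # cs[i+1, j+1] = sum of m[1:i, 1:j]
  cs <- matrix(0, n + 1L, p + 1L)
  colcum <- apply(m, 2, cumsum)
  if (n == 1L) colcum <- matrix(colcum, nrow = 1L)
  cs[-1, -1] <- t(apply(colcum, 1, cumsum))
  i <- seq_len(n)
  lo_r <- pmax(i - h, 1L); hi_r <- pmin(i + h, n)
  j <- seq_len(p)
  lo_c <- pmax(j - h, 1L); hi_c <- pmin(j + h, p)
  out <- matrix(0, n, p)
  for (jj in j) {
    c1 <- lo_c[jj]; c2 <- hi_c[jj]
    block <- cs[hi_r + 1L, c2 + 1L] - cs[lo_r, c2 + 1L] -
      cs[hi_r + 1L, c1] + cs[lo_r, c1]
    out[, jj] <- block / ((hi_r - lo_r + 1L) * (c2 - c1 + 1L))
  }
  out
}

#' Write a binned matrix as bin-sparse TSV
#'
#' Columns: chrom, bin1, bin2, count; header lines carry bin size and
#' chromosome sizes.
#' @param mat A `binned_matrix`.
#' @param path File path.
#' @export
write_binned_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bin_size: %d", as.integer(attr(mat, "bin_size"))), con)
  cs <- attr(mat, "chrom_sizes")
  writeLines(sprintf("#chromsize: %s %d", names(cs), as.integer(cs)), con)
  utils::write.table(as.data.frame(mat), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_matrix
#' @export
read_binned_matrix <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- lines[startsWith(lines, "#")]
  bs <- as.integer(sub("^#bin_size:\\s*", "", grep("^#bin_size:", hdr,
                                                   value = TRUE)))
  cs_lines <- grep("^#chromsize:", hdr, value = TRUE)
  parts <- strsplit(sub("^#chromsize:\\s*", "", cs_lines), "\\s+")
  cs <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                        vapply(parts, `[`, "", 1L))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = length(hdr),
                          stringsAsFactors = FALSE)
  attr(df, "bin_size") <- bs
  attr(df, "chrom_sizes") <- cs
  attr(df, "n_bins") <- stats::setNames(as.integer(ceiling(cs / bs)),
                                        names(cs))
  attr(df, "total_count") <- sum(df$count)
  class(df) <- c("binned_matrix", "data.frame")
  df
}
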