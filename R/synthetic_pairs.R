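#' Specification of a synthetic nucleosome-contact pair set
#'
#' Describes the genomic-distance mixture of a synthetic Micro-C style pair
#' set. Non-background pair distances are drawn from a mixture of
#' nucleosome-neighbor modes (`neighbor_weights[k]` puts mass at
#' `k * repeat_length` bp, jittered), a long-range band (default 500-1000 bp,
#' the signature of a locally folded fiber), and a uniform background.
#' Optionally a fraction of pairs joins anchor points (loops) or an anchor to
#' a point in its surrounding domain (stripes). Strand orientations are
#' emitted so that a configurable fraction is "in-facing" (reads pointing
#' toward each other, the class removed as undigested di-nucleosome
#' contamination); the remainder splits evenly between out-facing and the two
#' tandem orientations.
#'
#' @param chrom_sizes Named numeric vector, chromosome -> length in bp.
#' @param n_pairs Number of pair records to emit (> 0).
#' @param neighbor_weights Numeric vector, `neighbor_weights[k]` is the
#'   relative mass of the n+k neighbor mode. Need not be normalized.
#' @param repeat_length bp per nucleosome step used to convert k to distance.
#' @param distance_jitter_sd SD (bp) of Gaussian jitter on neighbor distances.
#' @param long_range_weight Fraction of pairs drawn uniformly from `long_band`.
#' @param long_band Two-element vector, the long-distance band in bp.
#' @param background_weight Fraction of pairs with both ends uniform.
#' @param anchor_loop_fraction Fraction of pairs joining two distinct anchors.
#' @param stripe_fraction Fraction joining an anchor to a uniform point within
#'   `domain_size` of it.
#' @param anchors Optional anchor set (see [generate_anchors()]); required if
#'   `anchor_loop_fraction` or `stripe_fraction` is positive.
#' @param domain_size bp; extent of the stripe domain around an anchor.
#' @param infacing_fraction Fraction of pairs emitted with in-facing strands.
#' @param seed Integer seed.
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(chrom_sizes,
                         n_pairs,
                         neighbor_weights = c(1, 0.5, 0.25, 0.12, 0.06),
                         repeat_length = 165,
                         distance_jitter_sd = 15,
                         long_range_weight = 0.1,
                         long_band = c(500, 1000),
                         background_weight = 0.05,
                         anchor_loop_fraction = 0,
                         stripe_fraction = 0,
                         anchors = NULL,
                         domain_size = 20000,
                         infacing_fraction = 0.25,
                         seed = 1L) {
  if (length(chrom_sizes) == 0 || is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a non-empty named vector")
  if (n_pairs <= 0) stop("n_pairs must be positive")
  fr <- c(long_range_weight, background_weight, anchor_loop_fraction,
          stripe_fraction, infacing_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (any(neighbor_weights < 0)) stop("neighbor_weights must be >= 0")
  if (long_range_weight + background_weight + anchor_loop_fraction +
      stripe_fraction > 1)
    stop("component fractions sum to more than 1")
  if ((anchor_loop_fraction > 0 || stripe_fraction > 0) && is.null(anchors))
    stop("anchor-based components need an anchor set")
  structure(list(chrom_sizes = chrom_sizes, n_pairs = as.integer(n_pairs),
                 neighbor_weights = neighbor_weights,
                 repeat_length = repeat_length,
                 distance_jitter_sd = distance_jitter_sd,
                 long_range_weight = long_range_weight,
                 long_band = long_band,
                 background_weight = background_weight,
                 anchor_loop_fraction = anchor_loop_fraction,
                 stripe_fraction = stripe_fraction,
                 anchors = anchors,
                 domain_size = domain_size,
                 infacing_fraction = infacing_fraction,
                 seed = as.integer(seed)),
            class = "contact_spec")
}

#' Generate synthetic contact pairs
#'
#' Emits exactly `n_pairs` records drawn from the configured distance mixture.
#' Coordinates are 1-based and canonically ordered (`pos1 <= pos2` within a
#' chromosome); the orientation label of each pair follows from the emitted
#' strands.
#'
#' @param spec A [contact_spec()].
#' @return A `data.frame` of class `pairs_table` with columns `readID`,
#'   `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`; attribute
#'   `chrom_sizes`.
#' @export
generate_contact_pairs <- function(spec) {
  stopifnot(inherits(spec, "contact_spec"))
  rng <- local_rng(spec$seed)
  n <- spec$n_pairs
  sizes <- spec$chrom_sizes
  chroms <- names(sizes)

  nw <- spec$neighbor_weights
  p_neighbor <- 1 - spec$long_range_weight - spec$background_weight -
    spec$anchor_loop_fraction - spec$stripe_fraction
  comp_p <- c(neighbor = p_neighbor, long = spec$long_range_weight,
              background = spec$background_weight,
              loop = spec$anchor_loop_fraction, stripe = spec$stripe_fraction)
  comp <- rng$sample_int(5L, n, replace = TRUE, prob = comp_p)

  # chromosome per pair, proportional to size
  ci <- rng$sample_int(length(sizes), n, replace = TRUE, prob = sizes)
  chrom <- chroms[ci]
  len <- unname(sizes[ci])
  pos1 <- numeric(n); pos2 <- numeric(n)

  d <- numeric(n)
  is_n <- comp == 1L
  if (any(is_n)) {
    k <- rng$sample_int(length(nw), sum(is_n), replace = TRUE, prob = nw)
    dk <- k * spec$repeat_length
    if (spec$distance_jitter_sd > 0)
      dk <- dk + rng$norm(sum(is_n)) * spec$distance_jitter_sd
    d[is_n] <- pmax(round(dk), 1)
  }
  is_l <- comp == 2L
  if (any(is_l))
    d[is_l] <- floor(rng$unif(sum(is_l), spec$long_band[1], spec$long_band[2]))
  dist_based <- is_n | is_l
  if (any(dist_based)) {
    u <- rng$unif(sum(dist_based))
    m <- pmax(len[dist_based] - d[dist_based], 1)
    pos1[dist_based] <- floor(u * m) + 1
    pos2[dist_based] <- pmin(pos1[dist_based] + d[dist_based],
                             len[dist_based])
  }
  is_b <- comp == 3L
  if (any(is_b)) {
    pos1[is_b] <- floor(rng$unif(sum(is_b)) * len[is_b]) + 1
    pos2[is_b] <- floor(rng$unif(sum(is_b)) * len[is_b]) + 1
  }
  if (any(comp >= 4L)) {
    anc <- spec$anchors
    is_loop <- comp == 4L
    if (any(is_loop)) {
      m <- sum(is_loop)
      # pick two distinct anchors on the same chromosome where possible
      i1 <- rng$sample_int(nrow(anc), m, replace = TRUE)
      same <- split(seq_len(nrow(anc)), anc$chrom)
      i2 <- vapply(i1, function(i) {
        cand <- setdiff(same[[anc$chrom[i]]], i)
        if (length(cand) == 0) i else cand[rng$sample_int(length(cand), 1L)]
      }, 1L)
      chrom[is_loop] <- anc$chrom[i1]
      len[is_loop] <- unname(sizes[anc$chrom[i1]])
      pos1[is_loop] <- anc$pos[i1]
      pos2[is_loop] <- anc$pos[i2]
    }
    is_st <- comp == 5L
    if (any(is_st)) {
      m <- sum(is_st)
      i1 <- rng$sample_int(nrow(anc), m, replace = TRUE)
      off <- floor(rng$unif(m, -spec$domain_size, spec$domain_size))
      chrom[is_st] <- anc$chrom[i1]
      len[is_st] <- unname(sizes[anc$chrom[i1]])
      pos1[is_st] <- anc$pos[i1]
      pos2[is_st] <- pmin(pmax(anc$pos[i1] + off, 1), len[is_st])
    }
  }
  pos1 <- pmin(pmax(round(pos1), 1), len)
  pos2 <- pmin(pmax(round(pos2), 1), len)
  swap <- pos2 < pos1
  tmp <- pos1[swap]; pos1[swap] <- pos2[swap]; pos2[swap] <- tmp

  # strands: in-facing = (+,-) after canonical ordering; remainder splits
  # evenly among out-facing (-,+) and the two tandem classes (++ and --)
  u <- rng$unif(n)
  s1 <- character(n); s2 <- character(n)
  infc <- u < spec$infacing_fraction
  s1[infc] <- "+"; s2[infc] <- "-"
  rest <- !infc
  v <- rng$sample_int(3L, sum(rest), replace = TRUE)
  s1[rest] <- c("-", "+", "-")[v]
  s2[rest] <- c("+", "+", "-")[v]

  out <- data.frame(readID = sprintf("read%07d", seq_len(n)),
                    chrom1 = chrom, pos1 = as.integer(pos1), strand1 = s1,
                    chrom2 = chrom, pos2 = as.integer(pos2), strand2 = s2,
                    stringsAsFactors = FALSE)
  attr(out, "chrom_sizes") <- sizes
  class(out) <- c("pairs_table", "data.frame")
  out
}

#' Generate anchor points
#'
#' Places point anchors (emulating condensin ChIP peaks or loop-domain
#' boundaries) across chromosomes, sorted and pairwise separated by at least
#' `min_spacing`.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_anchors Total number of anchors (>= 0).
#' @param min_spacing Minimum pairwise distance between same-chromosome
#'   anchors (bp).
#' @param margin Keep anchors at least this far from chromosome ends (bp).
#' @param seed Integer seed.
#' @return `data.frame` of class `anchor_set` with columns `chrom`, `pos`,
#'   sorted by chromosome then position.
#' @export
generate_anchors <- function(chrom_sizes, n_anchors, min_spacing = 40000,
                             margin = 0, seed = 1L) {
  stopifnot(n_anchors >= 0, min_spacing >= 0)
  rng <- local_rng(seed)
  if (n_anchors == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0))
    class(out) <- c("anchor_set", "data.frame")
    return(out)
  }
  # allocate anchors to chromosomes proportionally to size
  alloc <- floor(n_anchors * chrom_sizes / sum(chrom_sizes))
  rem <- n_anchors - sum(alloc)
  if (rem > 0) {
    extra <- rng$sample_int(length(chrom_sizes), rem, replace = FALSE,
                            prob = chrom_sizes)
    alloc[extra] <- alloc[extra] + 1
  }
  res <- lapply(seq_along(chrom_sizes), function(i) {
    ni <- alloc[i]
    if (ni == 0) return(NULL)
    L <- chrom_sizes[i] - 2 * margin
    slack <- L - (ni - 1) * min_spacing
    if (slack <= 0)
      stop(sprintf("cannot place %d anchors with %g bp spacing on %s",
                   ni, min_spacing, names(chrom_sizes)[i]))
    u <- sort(rng$unif(ni, 0, slack))
    pos <- margin + floor(u + (seq_len(ni) - 1) * min_spacing) + 1
    data.frame(chrom = names(chrom_sizes)[i], pos = as.integer(pos))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Pairs and anchor file I/O
#'
#' Pairs are written in a 4DN pairs-style tab-separated dialect with a
#' `#columns:` header line; anchors as 6-column BED (0-based half-open,
#' single-bp intervals).
#'
#' @param pairs A `pairs_table`.
#' @param path File path.
#' @param chrom_sizes Named chromosome sizes; taken from the table's
#'   attribute when omitted.
#' @export
write_pairs <- function(pairs, path, chrom_sizes = attr(pairs, "chrom_sizes")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  if (!is.null(chrom_sizes))
    writeLines(sprintf("#chromsize: %s %d", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2", con)
  df <- data.frame(pairs$readID, pairs$chrom1, pairs$pos1, pairs$chrom2,
                   pairs$pos2, pairs$strand1, pairs$strand2)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  header <- character(0)
  con <- file(path, "r")
  repeat {
    line <- readLines(con, 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  cs_lines <- grep("^#chromsize:", header, value = TRUE)
  chrom_sizes <- NULL
  if (length(cs_lines)) {
    parts <- strsplit(sub("^#chromsize:\\s*", "", cs_lines), "\\s+")
    chrom_sizes <- stats::setNames(
      as.numeric(vapply(parts, `[`, "", 2L)),
      vapply(parts, `[`, "", 1L))
  }
  df <- data.table::fread(path, skip = length(header), header = FALSE,
                          col.names = c("readID", "chrom1", "pos1", "chrom2",
                                        "pos2", "strand1", "strand2"),
                          data.table = FALSE)
  if (!all(df$strand1 %in% c("+", "-")) || !all(df$strand2 %in% c("+", "-"))) {
    bad <- which(!(df$strand1 %in% c("+", "-") & df$strand2 %in% c("+", "-")))[1]
    stop(sprintf("missing/invalid strand at data line %d", bad))
  }
  out <- df[, c("readID", "chrom1", "pos1", "strand1",
                "chrom2", "pos2", "strand2")]
  attr(out, "chrom_sizes") <- chrom_sizes
  class(out) <- c("pairs_table", "data.frame")
  out
}

#' @rdname write_pairs
#' @param anchors An `anchor_set`.
#' @export
write_anchors_bed <- function(anchors, path) {
  df <- data.frame(anchors$chrom, anchors$pos - 1L, anchors$pos,
                   sprintf("anchor%03d", seq_len(nrow(anchors))), 0L, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_anchors_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], pos = as.integer(df[[3]]))
  class(out) <- c("anchor_set", "data.frame")
  out
}
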