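# Brute-force oracles used by the acceptance-level checks.

# all-pairs distance scan: binary internucleosome contact matrix from one
# saved configuration (tail/charge beads within cutoff; folded excluded)
oracle_contact_matrix <- function(pos, type, core_of, folded, nc, cutoff) {
  use <- which(type %in% c(1L, 3L) & !folded)
  M <- matrix(0L, nc, nc)
  for (a in seq_along(use)) {
    i <- use[a]
    for (b in seq_len(a - 1L)) {
      j <- use[b]
      ci <- core_of[i]; cj <- core_of[j]
      if (ci == cj || M[ci, cj] == 1L) next
      if (sum((pos[i, ] - pos[j, ])^2) <= cutoff^2) {
        M[ci, cj] <- 1L; M[cj, ci] <- 1L
      }
    }
  }
  M
}

# per-tail minimum distance to the three separate-nucleosome element
# classes, straight from definitions
oracle_tail_min_dist <- function(pos, type, core_of, tail_of, folded,
                                 dna_owner, tails, tail_folded) {
  nt <- length(tails)
  out <- matrix(Inf, nt, 3)
  for (t in seq_len(nt)) {
    if (tail_folded[t]) { out[t, ] <- NA; next }
    own <- tails[[t]]$core
    tb <- tails[[t]]$beads
    for (j in seq_along(type)) {
      cls <- if (type[j] == 1L && core_of[j] != own) 1L
        else if (type[j] == 2L && dna_owner[j] != own) 2L
        else if (type[j] == 3L && !folded[j] && core_of[j] != own) 3L
        else next
      d <- min(sqrt(colSums((t(pos[tb, , drop = FALSE]) - pos[j, ])^2)))
      if (d < out[t, cls]) out[t, cls] <- d
    }
  }
  out
}
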