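# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route from the package implementation.

# Exhaustive enumeration of every nested, loop-legal structure on [i, j]
# by the partner-of-i decomposition; returns the list of pair matrices.
enum_structures <- function(i, j, min_loop) {
  if (j - i < min_loop + 1L) {
    return(list(matrix(integer(0), 0, 2)))
  }
  out <- enum_structures(i + 1L, j, min_loop)   # i unpaired
  for (k in (i + min_loop + 1L):j) {
    inner <- enum_structures(i + 1L, k - 1L, min_loop)
    rest <- if (k < j) enum_structures(k + 1L, j, min_loop) else
      list(matrix(integer(0), 0, 2))
    for (a in inner) {
      for (b in rest) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
  }
  out
}

# Brute-force optimum: max total score over all enumerated structures
# (non-positive pairs are simply never beneficial, so no restriction needed).
enum_max_score <- function(s, min_loop) {
  structs <- enum_structures(1L, nrow(s), min_loop)
  best <- 0
  for (st in structs) {
    if (nrow(st) == 0L) next
    best <- max(best, sum(s[st]))
  }
  best
}

# Plug-in mutual information via the entropy route H_i + H_j - H_ij,
# computed straight from unweighted counts (lambda = 0).
entropy_mi_oracle <- function(rows, i, j) {
  ci <- substring(rows, i, i)
  cj <- substring(rows, j, j)
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  pi_ <- table(ci) / length(ci)
  pj_ <- table(cj) / length(cj)
  pij <- table(paste(ci, cj)) / length(ci)
  H(pi_) + H(pj_) - H(pij)
}

# Independent tertiary-pair exclusion filter (first matching rule):
# near-diagonal, then the 25-pair secondary-structure neighborhood.
brute_exclusion_reason <- function(i, j, ss_pairs) {
  if (abs(i - j) < 5L) return("near-diagonal")
  if (nrow(ss_pairs) > 0) {
    for (r in seq_len(nrow(ss_pairs))) {
      k <- ss_pairs[r, 1]; l <- ss_pairs[r, 2]
      for (dk in -2:2) {
        for (dl in -2:2) {
          a <- k + dk; b <- l + dl
          if ((i == min(a, b) && j == max(a, b))) return("ss-neighborhood")
        }
      }
    }
  }
  NA_character_
}

# Exact window-outcome enumeration: probability that Y i.i.d.
# Bernoulli(r0) draws contain at least T successes, via all 2^Y outcomes.
window_tail_oracle <- function(T, Y, r0) {
  if (T <= 0L) return(1)
  total <- 0
  for (mask in 0:(2^Y - 1L)) {
    bits <- as.integer(intToBits(mask))[1:Y]
    k <- sum(bits)
    if (k >= T) total <- total + r0^k * (1 - r0)^(Y - k)
  }
  total
}

# Exact Boltzmann distribution of a 2-site model over the 5-state alphabet.
two_site_boltzmann <- function(e_block, h1, h2) {
  w <- exp(outer(h1, h2, "+") + e_block)
  w / sum(w)
}

# Random nested loop-legal structure by rejection-free greedy sampling.
random_nested_structure <- function(n, min_loop = 3L, density = 0.4) {
  pairs <- matrix(integer(0), 0, 2)
  cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cand <- cand[cand[, 2] - cand[, 1] - 1L >= min_loop, , drop = FALSE]
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    if (stats::runif(1) > density) next
    trial <- rbind(pairs, cand[r, ])
    if (anyDuplicated(as.vector(trial))) next
    if (!rnadca:::is_nested(rnadca:::as_pair_matrix(trial))) next
    pairs <- trial
  }
  rnadca:::as_pair_matrix(pairs)
}

# Map column-coordinate pairs onto target coordinates through a column map,
# dropping pairs with an unmappable end.
map_pairs_to_target <- function(pairs, cmap) {
  if (nrow(pairs) == 0L) return(pairs)
  pi_ <- cmap$col_to_pos[pairs[, 1]]
  pj_ <- cmap$col_to_pos[pairs[, 2]]
  ok <- !is.na(pi_) & !is.na(pj_)
  rnadca:::as_pair_matrix(cbind(pi_[ok], pj_[ok]))
}
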