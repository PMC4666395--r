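#' Specification of a synthetic alignment generator
#'
#' Describes a ground-truth Potts model emulating the statistical structure
#' of a riboswitch-family alignment: strongly covarying Watson-Crick paired
#' columns (planted nested secondary structure), weaker directly-coupled
#' tertiary column pairs, background composition via single-site fields,
#' gaps as a disfavored fifth state, and phylogenetic redundancy as
#' duplication-plus-noise. Defaults (n = 70, M = 1000, pair strength 2.0,
#' tertiary strength 0.8, gap rate 0.05, redundancy 0.2, duplicate mutation
#' rate 0.02, burn-in 1000 sweeps) describe a family with comfortable
#' statistics; see the methods vignette for the reasoning.
#'
#' @param n target length (columns).
#' @param M number of sequences.
#' @param secondary 2-column matrix of planted nested base pairs, or
#'   `NULL` to plant helices automatically (about n/4 pairs in 2-4
#'   helices).
#' @param tertiary 2-column matrix of planted tertiary pairs, or `NULL`
#'   to plant `n %/% 14` pairs that by construction pass the `|i-j| >= 5`
#'   and secondary-neighborhood filters.
#' @param pair_strength coupling weight rewarding WC/wobble combinations in
#'   paired columns.
#' @param tertiary_strength coupling weight of tertiary pairs (weaker).
#' @param gap_rate target marginal gap frequency.
#' @param redundancy fraction of sequences that are near-duplicates of
#'   others.
#' @param dup_mutation per-column mutation probability when creating a
#'   near-duplicate.
#' @param burn_in Gibbs burn-in sweeps (one independent chain per
#'   sequence).
#' @param field_sd standard deviation of random background fields.
#' @return list of class `rna_genspec`.
#' @export
generator_spec <- function(n = 70L, M = 1000L, secondary = NULL,
                           tertiary = NULL, pair_strength = 2.0,
                           tertiary_strength = 0.8, gap_rate = 0.05,
                           redundancy = 0.2, dup_mutation = 0.02,
                           burn_in = 1000L, field_sd = 0.2) {
  if (n < 1L || M < 1L) stop_usage("n and M must be positive")
  if (redundancy < 0 || redundancy >= 1) {
    stop_usage("redundancy must be in [0, 1)")
  }
  structure(list(n = as.integer(n), M = as.integer(M),
                 secondary = if (!is.null(secondary)) as_pair_matrix(secondary),
                 tertiary = if (!is.null(tertiary)) as_pair_matrix(tertiary),
                 pair_strength = pair_strength,
                 tertiary_strength = tertiary_strength,
                 gap_rate = gap_rate, redundancy = redundancy,
                 dup_mutation = dup_mutation, burn_in = as.integer(burn_in),
                 field_sd = field_sd),
            class = "rna_genspec")
}

# deterministic helix planting: nested, loop-legal (>= 3 nt hairpin loops)
plant_secondary <- function(n) {
  pairs <- matrix(integer(0), 0, 2)
  # stack helices of length 3 along the sequence: (s..s+2) with (e-2..e)
  pos <- 2L
  while (pos + 11L <= n - 1L) {
    e <- min(pos + 13L, n - 1L)
    for (k in 0:2) pairs <- rbind(pairs, c(pos + k, e - k))
    pos <- e + 3L
  }
  as_pair_matrix(pairs)
}

# tertiary pairs that pass the |i-j|>=5 and +/-2 secondary-neighborhood
# filters by construction
plant_tertiary <- function(n, secondary, n_pairs) {
  blocked <- rep(FALSE, n)
  if (nrow(secondary) > 0) {
    for (r in seq_len(nrow(secondary))) {
      for (p in secondary[r, ]) {
        lo <- max(1L, p - 2L); hi <- min(n, p + 2L)
        blocked[lo:hi] <- TRUE
      }
    }
  }
  free <- which(!blocked)
  pairs <- matrix(integer(0), 0, 2)
  used <- integer(0)
  for (a in free) {
    if (nrow(pairs) >= n_pairs) break
    if (a %in% used) next
    bs <- free[free >= a + 5L & !(free %in% used)]
    if (length(bs) == 0L) next
    b <- bs[length(bs)]          # farthest partner: long-range contact
    pairs <- rbind(pairs, c(a, b))
    used <- c(used, a, b)
  }
  as_pair_matrix(pairs)
}

# WC/wobble-rewarding coupling block in zero-sum gauge, strength J
wc_coupling_block <- function(J) {
  blk <- matrix(0, 5, 5)
  blk[2:5, 2:5][.wc_table[2:5, 2:5]] <- J
  zero_sum_gauge(blk)
}

#' Gibbs sampler for a pairwise Potts model over the RNA alphabet
#'
#' Runs `M` independent single-site Gibbs chains (one per output sequence)
#' for `burn_in` full sweeps each and returns the final states; chains are
#' vectorised over sequences, so samples are exactly independent across
#' rows. Uses the current RNG stream (set the seed in the caller).
#'
#' @param n sites.
#' @param M chains (sequences).
#' @param edges list of `list(i, j, e)` with `e` a 5 x 5 coupling block
#'   (log scale).
#' @param h n x 5 field matrix.
#' @param burn_in sweeps before the state is taken.
#' @return M x n integer state matrix over `(-, A, C, G, U)` = 1..5.
#' @export
gibbs_sample_potts <- function(n, M, edges, h, burn_in = 1000L) {
  q <- 5L
  nbr <- vector("list", n)
  for (ed in edges) {
    nbr[[ed$i]] <- c(nbr[[ed$i]], list(list(j = ed$j, e = ed$e)))
    nbr[[ed$j]] <- c(nbr[[ed$j]], list(list(j = ed$i, e = t(ed$e))))
  }
  S <- matrix(sample.int(q, n * M, replace = TRUE), nrow = M, ncol = n)
  for (sw in seq_len(burn_in)) {
    for (i in seq_len(n)) {
      E <- matrix(h[i, ], nrow = q, ncol = M)
      for (nb in nbr[[i]]) E <- E + nb$e[, S[, nb$j], drop = FALSE]
      m <- pmax(E[1, ], E[2, ], E[3, ], E[4, ], E[5, ])
      E <- exp(E - rep(m, each = q))
      tot <- .colSums(E, q, M)
      u <- stats::runif(M) * tot
      c1 <- E[1, ]; c2 <- c1 + E[2, ]; c3 <- c2 + E[3, ]; c4 <- c3 + E[4, ]
      S[, i] <- 1L + (u > c1) + (u > c2) + (u > c3) + (u > c4)
    }
  }
  S
}

#' Sample a synthetic alignment with known ground truth
#'
#' Draws `M0 = round(M * (1 - redundancy))` independent sequences from the
#' ground-truth Potts model of a [generator_spec()] by Gibbs sampling, then
#' adds `M - M0` near-duplicates (a copy of a random row with each column
#' mutated with probability `dup_mutation`) to emulate phylogenetic
#' redundancy. Deterministic given `seed`.
#'
#' @param spec an `rna_genspec`.
#' @param seed integer RNG seed.
#' @return list with `msa` (an `rna_msa`, consensus structure set to the
#'   planted secondary pairs), and `truth`: planted `secondary` and
#'   `tertiary` pair matrices, the coupling `edges`, the field matrix `h`,
#'   and a `manifest` (seed, burn-in, chains, duplicates).
#' @export
sample_potts_alignment <- function(spec, seed = 1L) {
  if (!inherits(spec, "rna_genspec")) stop_usage("spec must be an rna_genspec")
  set.seed(seed)
  n <- spec$n
  secondary <- if (is.null(spec$secondary)) plant_secondary(n)
               else spec$secondary
  if (nrow(secondary) > 0 && !is_nested(secondary)) {
    stop_usage("planted secondary pairs must be nested")
  }
  if (nrow(secondary) > 0 &&
      any(secondary[, 2] - secondary[, 1] - 1L < 3L)) {
    stop_usage("planted secondary pairs must respect the hairpin loop")
  }
  tertiary <- if (is.null(spec$tertiary)) {
    plant_tertiary(n, secondary, max(1L, n %/% 14L))
  } else {
    spec$tertiary
  }
  edges <- list()
  if (nrow(secondary) > 0) {
    for (r in seq_len(nrow(secondary))) {
      edges[[length(edges) + 1L]] <-
        list(i = secondary[r, 1], j = secondary[r, 2],
             e = wc_coupling_block(spec$pair_strength))
    }
  }
  if (nrow(tertiary) > 0) {
    for (r in seq_len(nrow(tertiary))) {
      edges[[length(edges) + 1L]] <-
        list(i = tertiary[r, 1], j = tertiary[r, 2],
             e = wc_coupling_block(spec$tertiary_strength))
    }
  }
  # fields: random background composition over nucleotides, gap held at
  # its target rate via log-odds against the mean nucleotide frequency
  h <- matrix(0, n, 5)
  h[, 2:5] <- stats::rnorm(4L * n, 0, spec$field_sd)
  h[, 1] <- log(spec$gap_rate / ((1 - spec$gap_rate) / 4))
  M0 <- max(1L, round(spec$M * (1 - spec$redundancy)))
  S <- gibbs_sample_potts(n, M0, edges, h, burn_in = spec$burn_in)
  n_dup <- spec$M - M0
  if (n_dup > 0) {
    src <- sample.int(M0, n_dup, replace = TRUE)
    D <- S[src, , drop = FALSE]
    mut <- matrix(stats::runif(n_dup * n) < spec$dup_mutation,
                  nrow = n_dup)
    if (any(mut)) {
      D[mut] <- sample.int(5L, sum(mut), replace = TRUE)
    }
    S <- rbind(S, D)
  }
  rows <- apply(S, 1L, decode_row)
  msa <- new_msa(sprintf("synth%04d", seq_len(nrow(S))), rows,
                 consensus = secondary)
  list(msa = msa,
       truth = list(secondary = secondary, tertiary = tertiary,
                    edges = edges, h = h,
                    manifest = list(seed = seed, burn_in = spec$burn_in,
                                    chains = M0, duplicates = n_dup,
                                    sampler = "independent-chain Gibbs")))
}

#' Write a minimal synthetic PDB fixture with prescribed contacts
#'
#' Places one pseudo-atom (C1') per residue along a widely spaced line
#' (`spread` Angstrom apart, so unrelated residues are far), then moves
#' the second residue of every requested pair next to the first at the
#' requested distance, each pair along its own direction. Intended for
#' testing the PDB reader and contact labelling; the file is synthetic and
#' says so in its header.
#'
#' @param pairs_in_contact 2-column matrix of residue pairs to place in
#'   contact (optionally a third column of per-pair distances).
#' @param n number of residues.
#' @param sequence chain sequence (default: repeated ACGU).
#' @param distance default contact distance in Angstrom.
#' @param spread spacing of the backbone line in Angstrom.
#' @param path optional output file; when `NULL` the PDB text is returned.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
make_pdb_fixture <- function(pairs_in_contact = NULL, n = 10L,
                             sequence = NULL, distance = 3.0, spread = 20,
                             path = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(rep(c("A", "C", "G", "U"), length.out = n),
                      collapse = "")
  }
  if (nchar(sequence) != n) stop_usage("sequence length must equal n")
  coords <- cbind((seq_len(n) - 1L) * spread, 0, 0)
  if (!is.null(pairs_in_contact) && length(pairs_in_contact) > 0) {
    pm <- matrix(as.numeric(pairs_in_contact), ncol = ncol(as.matrix(pairs_in_contact)))
    dirs <- rbind(c(0, 0, 1), c(0, 1, 0), c(0, 0, -1), c(0, -1, 0),
                  c(0, 1, 1) / sqrt(2), c(0, 1, -1) / sqrt(2))
    for (r in seq_len(nrow(pm))) {
      i <- as.integer(pm[r, 1]); j <- as.integer(pm[r, 2])
      d <- if (ncol(pm) >= 3) pm[r, 3] else distance
      dir <- dirs[((r - 1L) %% nrow(dirs)) + 1L, ]
      coords[j, ] <- coords[i, ] + d * dir
    }
  }
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  lines <- c("REMARK synthetic fixture generated by rnadca",
             sprintf(paste0("ATOM  %5d  %-3s %3s %s%4d    ",
                            "%8.3f%8.3f%8.3f%6.2f%6.2f           %s"),
                     seq_len(n), "C1'", bases, "A", seq_len(n),
                     coords[, 1], coords[, 2], coords[, 3], 1, 0, "C"),
             "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
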