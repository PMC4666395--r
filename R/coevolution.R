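#' Sequence reweighting and effective sequence number
#'
#' Each sequence is down-weighted by the number of alignment rows (itself
#' included) with pairwise identity at or above `threshold`. Identity is the
#' fraction of columns with identical characters, counting gap-gap matches
#' as matches. `Meff`, the effective number of sequences, is the sum of
#' weights.
#'
#' @param msa an `rna_msa`.
#' @param threshold identity threshold in (0, 1]; the conventional value is
#'   0.9 (sequences at >= 90\% identity share weight).
#' @return list of class `rna_weights` with `weights` (length M, each in
#'   (0, 1]), `Meff`, and `threshold`.
#' @export
compute_weights <- function(msa, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop_usage("identity threshold must be in (0, 1]")
  }
  S <- msa$seq
  M <- msa$M
  L <- msa$L
  matches <- matrix(0, M, M)
  for (a in seq_along(rna_states)) {
    X <- (S == a) * 1
    matches <- matches + tcrossprod(X)
  }
  neighbours <- rowSums(matches / L >= threshold - 1e-12)
  w <- 1 / neighbours
  structure(list(weights = w, Meff = sum(w), threshold = threshold),
            class = "rna_weights")
}

#' @export
print.rna_weights <- function(x, ...) {
  cat(sprintf("Sequence weights: M = %d, Meff = %.2f (identity >= %g%%)\n",
              length(x$weights), x$Meff, 100 * x$threshold))
  invisible(x)
}

#' Reweighted, pseudocounted single- and pair-column frequencies
#'
#' Empirical marginals f_i(A) and f_ij(A,B) are computed from weighted
#' counts divided by Meff, then mixed with the uniform distribution:
#' `f = (1 - lambda) f_data + lambda/q` for single columns and
#' `lambda/q^2` for column pairs, which preserves marginal consistency by
#' construction (summing f_ij over one index returns f_i exactly).
#'
#' @param msa an `rna_msa`.
#' @param weights an `rna_weights` object, or `NULL` for uniform weights.
#' @param pseudocount relative pseudocount weight lambda in \[0, 1).
#' @return list of class `rna_freq` with `fi` (L x 5), `fij`
#'   (L x L x 5 x 5 array; diagonal blocks are `NA`), `lambda`, `Meff`,
#'   and `q = 5`.
#' @export
compute_frequencies <- function(msa, weights = NULL, pseudocount = 0.5) {
  lambda <- pseudocount
  if (!is.numeric(lambda) || lambda < 0 || lambda >= 1) {
    stop_usage("pseudocount weight must be in [0, 1)")
  }
  S <- msa$seq
  L <- msa$L
  q <- 5L
  w <- if (is.null(weights)) rep(1, msa$M) else weights$weights
  if (length(w) != msa$M) stop_usage("weights do not match alignment rows")
  Meff <- sum(w)
  X <- lapply(seq_len(q), function(a) (S == a) * 1)
  Xw <- lapply(X, function(x) x * w)
  fi <- vapply(seq_len(q), function(a) colSums(Xw[[a]]), numeric(L)) / Meff
  fi <- matrix(fi, nrow = L, ncol = q)
  fij <- array(NA_real_, dim = c(L, L, q, q))
  for (a in seq_len(q)) {
    for (b in seq_len(q)) {
      fij[, , a, b] <- crossprod(Xw[[a]], X[[b]]) / Meff
    }
  }
  fi <- (1 - lambda) * fi + lambda / q
  fij <- (1 - lambda) * fij + lambda / q^2
  for (i in seq_len(L)) fij[i, i, , ] <- NA_real_
  structure(list(fi = fi, fij = fij, lambda = lambda, Meff = Meff, q = q),
            class = "rna_freq")
}

#' Mean-field inference of direct couplings
#'
#' Builds the connected-correlation matrix
#' `C[(i,A),(j,B)] = f_ij(A,B) - f_i(A) f_j(B)` over the four non-gap states
#' (the gap is the reference state), inverts it, and reads the couplings as
#' `e_ij(A,B) = -(C^-1)[(i,A),(j,B)]` for i != j, zero-padded on the
#' reference state and shifted to the zero-sum gauge (all row and column
#' sums of every 5 x 5 coupling block vanish). Fields `h_i` are recovered
#' from the mean-field self-consistency
#' `h_i(A) = log(f_i(A)/f_i(-)) - sum_j e_ij(.,B) f_j(B)`; they are reported
#' but only the couplings feed contact scoring.
#'
#' @param freq an `rna_freq` with strictly positive entries (requires
#'   `pseudocount > 0`).
#' @return list of class `rna_couplings` with `e` (L x L x 5 x 5 zero-sum
#'   coupling array), `h` (L x 5 field matrix) and `gauge = "zero-sum"`.
#' @export
mean_field_couplings <- function(freq) {
  L <- nrow(freq$fi)
  q <- freq$q
  if (freq$lambda <= 0 && any(freq$fi <= 0)) {
    stop_rnadca("mean-field inversion needs strictly positive frequencies; ",
                "use a pseudocount > 0")
  }
  ns <- 2:q                         # non-gap states
  k <- length(ns)
  dim_c <- L * k
  C <- matrix(0, dim_c, dim_c)
  idx <- function(i, a) (i - 1L) * k + a      # a indexes ns
  for (i in seq_len(L)) {
    fi_i <- freq$fi[i, ns]
    block <- diag(fi_i, k) - tcrossprod(fi_i)
    rows <- idx(i, seq_len(k))
    C[rows, rows] <- block
    if (i < L) {
      for (j in (i + 1L):L) {
        blk <- freq$fij[i, j, ns, ns] - tcrossprod(freq$fi[i, ns],
                                                   freq$fi[j, ns])
        cols <- idx(j, seq_len(k))
        C[rows, cols] <- blk
        C[cols, rows] <- t(blk)
      }
    }
  }
  invC <- tryCatch(solve(C), error = function(e) {
    stop_rnadca("connected-correlation matrix is singular (",
                conditionMessage(e),
                "); raise the pseudocount weight")
  })
  e <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      blk <- matrix(0, q, q)
      blk[ns, ns] <- -invC[idx(i, seq_len(k)), idx(j, seq_len(k))]
      e[i, j, , ] <- zero_sum_gauge(blk)
    }
  }
  h <- matrix(0, L, q)
  for (i in seq_len(L)) {
    hi <- log(freq$fi[i, ] / freq$fi[i, 1])
    for (j in seq_len(L)) {
      if (j == i) next
      hi <- hi - e[i, j, , ] %*% freq$fi[j, ]
    }
    h[i, ] <- hi - mean(hi)
  }
  structure(list(e = e, h = h, gauge = "zero-sum"), class = "rna_couplings")
}

# shift a q x q coupling block to the zero-sum gauge
zero_sum_gauge <- function(blk) {
  blk - outer(rowMeans(blk), rep(1, ncol(blk))) -
    outer(rep(1, nrow(blk)), colMeans(blk)) + mean(blk)
}

#' Average product correction of a symmetric score matrix
#'
#' Subtracts `F(i,.) F(.,j) / F(.,.)` from every entry, where `F(i,.)` is
#' the mean score of column i over all other columns and `F(.,.)` the
#' overall off-diagonal mean. Removes per-column background (entropic and
#' phylogenetic) bias; any rank-one score matrix is annihilated exactly.
#'
#' @param S symmetric numeric matrix; the diagonal is ignored.
#' @return matrix of the same shape with `NA` diagonal.
#' @export
apc_correct <- function(S) {
  L <- nrow(S)
  diag(S) <- NA_real_
  mi <- rowMeans(S, na.rm = TRUE)
  mall <- mean(S[upper.tri(S)], na.rm = TRUE)
  out <- S - outer(mi, mi) / mall
  diag(out) <- NA_real_
  out
}

#' Frobenius-norm coupling score with average product correction (Fapc)
#'
#' Compresses each zero-sum-gauge coupling block into the scalar
#' `F(i,j) = ||e_ij||_F` (over all five states by default, or the four
#' nucleotide states with `include_gap = FALSE`), then applies the average
#' product correction.
#'
#' @param couplings an `rna_couplings` in zero-sum gauge.
#' @param include_gap include the gap state in the Frobenius norm.
#' @return symmetric L x L score matrix with `NA` diagonal and attribute
#'   `kind = "Fapc"`.
#' @export
frobenius_apc_score <- function(couplings, include_gap = TRUE) {
  if (!identical(couplings$gauge, "zero-sum")) {
    stop_usage("couplings must be in zero-sum gauge")
  }
  L <- dim(couplings$e)[1]
  states <- if (include_gap) 1:5 else 2:5
  FN <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      FN[i, j] <- sqrt(sum(couplings$e[i, j, states, states]^2))
    }
  }
  out <- apc_correct(FN)
  attr(out, "kind") <- "Fapc"
  out
}

#' Mutual information between alignment columns
#'
#' Plug-in mutual information (natural logarithm, nats) from the
#' reweighted, pseudocounted marginals:
#' `M_ij = sum_AB f_ij(A,B) log( f_ij(A,B) / (f_i(A) f_j(B)) )`, with
#' `0 log 0 = 0` so that exact zero counts (pseudocount 0) are legal.
#' With `apc = TRUE` the same average product correction as for the
#' Frobenius coupling score is subtracted.
#'
#' @param freq an `rna_freq`.
#' @param apc apply the average product correction.
#' @return symmetric L x L score matrix with `NA` diagonal and attribute
#'   `kind` = `"MI"` or `"MIapc"`.
#' @export
mutual_information <- function(freq, apc = FALSE) {
  L <- nrow(freq$fi)
  MI <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    MI[i, i] <- NA_real_
    if (i == L) next
    for (j in (i + 1L):L) {
      fab <- freq$fij[i, j, , ]
      ref <- tcrossprod(freq$fi[i, ], freq$fi[j, ])
      pos <- fab > 0
      MI[i, j] <- MI[j, i] <- sum(fab[pos] * log(fab[pos] / ref[pos]))
    }
  }
  if (apc) MI <- apc_correct(MI)
  attr(MI, "kind") <- if (apc) "MIapc" else "MI"
  MI
}
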