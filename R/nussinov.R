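#' Build the compatibility-masked pair-score matrix for a target sequence
#'
#' Follows the three-step construction used for covariance-guided folding:
#' (1) every cell (i, j) of the target is prefilled with -1 if the
#' nucleotides cannot form a Watson-Crick or wobble pair, 0 if they can;
#' (2) the covariance scores over alignment-column pairs are sorted and only
#' the `top_k` largest retained (default: the alignment length L, so the
#' matrix holds at most L positive entries and overpairing is avoided);
#' (3) each retained score is written into the corresponding target cell
#' only when both columns map onto target residues and those residues are
#' pair-compatible — non-mappable or incompatible pairs leave the prefill
#' untouched.
#'
#' @param scores symmetric L x L score matrix on alignment columns (e.g.
#'   from [frobenius_apc_score()] or [mutual_information()]).
#' @param cmap column map for the target (see [build_column_map()]).
#' @param top_k number of retained covariance scores (default: alignment
#'   length).
#' @return object of class `rna_pairscores`: list with `s` (n x n matrix,
#'   upper triangle meaningful), `provenance` (same shape: `"incompatible"`,
#'   `"compatible"` or `"covariance"`), `n`, and `target`.
#' @export
build_pair_scores <- function(scores, cmap, top_k = NULL) {
  L <- length(cmap$col_to_pos)
  if (nrow(scores) != L) stop_usage("score matrix does not match alignment")
  if (is.null(top_k)) top_k <- L
  if (!is.numeric(top_k) || top_k < 0) stop_usage("top_k must be >= 0")
  tgt <- strsplit(cmap$target, "", fixed = TRUE)[[1]]
  n <- length(tgt)
  s <- matrix(0, n, n)
  prov <- matrix("compatible", n, n)
  for (i in seq_len(n)) {
    bad <- !wc_compatible(rep(tgt[i], n), tgt)
    s[i, bad] <- -1
    prov[i, bad] <- "incompatible"
  }
  tab <- score_table_matrix(scores)
  tab <- tab[!is.na(tab$score), , drop = FALSE]
  tab <- utils::head(tab, top_k)
  for (r in seq_len(nrow(tab))) {
    pi <- cmap$col_to_pos[tab$i[r]]
    pj <- cmap$col_to_pos[tab$j[r]]
    if (is.na(pi) || is.na(pj)) next
    if (!wc_compatible(tgt[pi], tgt[pj])) next
    s[pi, pj] <- s[pj, pi] <- tab$score[r]
    prov[pi, pj] <- prov[pj, pi] <- "covariance"
  }
  structure(list(s = s, provenance = prov, n = n, target = cmap$target),
            class = "rna_pairscores")
}

#' Maximum-score nested secondary structure (generalized Nussinov)
#'
#' Dynamic program maximizing the total pair score over all nested
#' structures in which every pair (i, j) encloses at least `min_loop`
#' unpaired nucleotides (j - i - 1 >= min_loop). Pairs with non-positive
#' cell score are never formed: a zero-score compatible pair adds nothing
#' and would only overpair, and incompatible cells carry -1 by
#' construction. Traceback is deterministic with fixed precedence:
#' pair (i, j), then bifurcation at the smallest split point, then leaving
#' i unpaired, then leaving j unpaired.
#'
#' @param psm an `rna_pairscores` (or a plain numeric matrix of cell
#'   scores).
#' @param min_loop minimum hairpin loop length (default 3).
#' @return an `rna_structure` with the optimal pair set and its total
#'   `score`.
#' @export
nussinov <- function(psm, min_loop = 3L) {
  s <- if (inherits(psm, "rna_pairscores")) psm$s else as.matrix(psm)
  n <- nrow(s)
  min_loop <- as.integer(min_loop)
  N <- matrix(0, n, n)
  if (n >= 2L) {
    for (span in seq_len(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- max(N[i + 1L, j], N[i, j - 1L])
        if (j - i - 1L >= min_loop && s[i, j] > 0) {
          inner <- if (j - 1L >= i + 1L) N[i + 1L, j - 1L] else 0
          best <- max(best, s[i, j] + inner)
        }
        if (span >= 2L) {
          ks <- i:(j - 1L)
          best <- max(best, max(N[i, ks] + N[cbind(ks + 1L, rep(j, span))]))
        }
        N[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  if (n >= 2L && N[1L, n] > 0) {
    stack <- list(c(1L, n))
    while (length(stack) > 0L) {
      iv <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- iv[1]; j <- iv[2]
      if (i >= j || N[i, j] <= 0) next
      if (j - i - 1L >= min_loop && s[i, j] > 0 &&
          abs(N[i, j] - (s[i, j] + N[i + 1L, j - 1L])) < 1e-9) {
        pairs <- rbind(pairs, c(i, j))
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
        next
      }
      done <- FALSE
      if (j - i >= 2L) {
        for (k in i:(j - 2L)) {
          if (abs(N[i, j] - (N[i, k] + N[k + 1L, j])) < 1e-9) {
            stack[[length(stack) + 1L]] <- c(k + 1L, j)
            stack[[length(stack) + 1L]] <- c(i, k)
            done <- TRUE
            break
          }
        }
      }
      if (done) next
      if (abs(N[i, j] - N[i + 1L, j]) < 1e-9) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
      } else {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
      }
    }
  }
  st <- rna_structure(pairs, n, score = if (n >= 2L) N[1L, n] else 0)
  if (inherits(psm, "rna_pairscores")) attr(st, "sequence") <- psm$target
  st
}

#' Compare a predicted structure against a reference
#'
#' Both pair sets are restricted to pairs with both ends in `assessable`
#' (by default every position, in practice the positions both resolved in
#' the reference structure's source and aligned for the target), then
#' TP = predicted and in the reference, FP = predicted only,
#' FN = reference only.
#'
#' @param pred predicted `rna_structure`.
#' @param ref reference `rna_structure` (same target indexing).
#' @param assessable integer vector of assessable positions, or `NULL` for
#'   all.
#' @return list of class `rna_eval`: `tp`, `fp`, `fn`, `sensitivity`
#'   (TP/(TP+FN)), `precision` (TP/(TP+FP); reported as 1 with
#'   `no_predictions = TRUE` when nothing was predicted), `excluded`
#'   positions.
#' @export
evaluate_structure <- function(pred, ref, assessable = NULL) {
  n <- max(pred$n, ref$n)
  if (is.null(assessable)) assessable <- seq_len(n)
  keep <- function(p) {
    p[p[, 1] %in% assessable & p[, 2] %in% assessable, , drop = FALSE]
  }
  pk <- keep(pred$pairs)
  rk <- keep(ref$pairs)
  key <- function(p) paste(p[, 1], p[, 2])
  tp <- sum(key(pk) %in% key(rk))
  fp <- nrow(pk) - tp
  fn <- nrow(rk) - tp
  sens <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  no_pred <- (tp + fp) == 0L
  prec <- if (no_pred) 1 else tp / (tp + fp)
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, no_predictions = no_pred,
                 excluded = setdiff(seq_len(n), assessable)),
            class = "rna_eval")
}

#' @export
print.rna_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | sensitivity %.3f  precision %.3f%s\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$precision,
              if (x$no_predictions) " (no predictions)" else ""))
  invisible(x)
}

#' Sensitivity/precision sweep over the retained-score cutoff
#'
#' Re-runs the pair-score construction and Nussinov fold for a grid of
#' `top_k` cutoffs and evaluates each prediction against a reference
#' structure; the number of retained covariance scores is the main free
#' parameter of the folding step (true pairs scale with L, candidate pairs
#' with L^2).
#'
#' @param scores L x L score matrix.
#' @param cmap target column map.
#' @param ref reference `rna_structure` on target coordinates.
#' @param top_k_grid integer vector of cutoffs (default: multiples of the
#'   target length up to 4L).
#' @param min_loop minimum hairpin loop length.
#' @param assessable assessable positions (see [evaluate_structure()]).
#' @return data.frame `top_k`, `n_pred`, `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`.
#' @export
topk_sweep <- function(scores, cmap, ref, top_k_grid = NULL, min_loop = 3L,
                       assessable = NULL) {
  n <- nchar(cmap$target)
  if (is.null(top_k_grid)) {
    top_k_grid <- unique(pmax(1L, round(n * c(0.5, 1, 1.5, 2, 3, 4))))
  }
  rows <- lapply(top_k_grid, function(k) {
    pred <- nussinov(build_pair_scores(scores, cmap, top_k = k),
                     min_loop = min_loop)
    ev <- evaluate_structure(pred, ref, assessable)
    data.frame(top_k = k, n_pred = nrow(pred$pairs), tp = ev$tp, fp = ev$fp,
               fn = ev$fn, sensitivity = ev$sensitivity,
               precision = ev$precision)
  })
  do.call(rbind, rows)
}
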