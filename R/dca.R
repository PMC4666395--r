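#' Fit a mean-field Potts model to an RNA alignment
#'
#' The central estimator of the package. Models the aligned sequences as a
#' pairwise Potts model
#' `P(A_1..A_L) = exp( sum_{i<j} e_ij(A_i,A_j) + sum_i h_i(A_i) ) / Z`
#' over the 5-state alphabet `(-, A, C, G, U)`, inferred by the mean-field
#' route: sequences are reweighted at an identity threshold, marginals are
#' pseudocounted, and couplings are obtained as the negative inverse of the
#' connected-correlation matrix (gap as reference state, zero-sum gauge).
#' Coupling blocks are compressed into the Fapc contact score (Frobenius
#' norm plus average product correction); mutual-information baselines (MI
#' and MIapc) are computed from the same marginals.
#'
#' @param msa an `rna_msa` (see [read_msa()]), or a character vector of
#'   aligned sequences.
#' @param reweight identity threshold for sequence reweighting (default
#'   0.9); `NULL` disables reweighting (all weights 1).
#' @param pseudocount relative pseudocount weight lambda in \[0, 1)
#'   (default 0.5, the customary mean-field value for strongly reweighted
#'   alignments).
#' @param include_gap include the gap state in the Frobenius norm of the
#'   coupling score.
#' @param methods any of `"fapc"`, `"mi"`, `"miapc"`: score matrices to
#'   compute. MI baselines reuse the fit's marginals.
#' @return object of class `rna_dca` with components `msa`, `weights`,
#'   `freq`, `couplings`, `scores` (named list of L x L matrices), and the
#'   matched `call`. Methods: [print.rna_dca()], [summary.rna_dca()],
#'   [coef.rna_dca()], [predict.rna_dca()], [plot.rna_dca()],
#'   [simulate.rna_dca()].
#' @export
#' @examples
#' aln <- rna_msa(c("GGGAAAACCC", "GGCAAAAGCC", "GCGAAAACGC", "CGGAAAACCG"))
#' fit <- dca(aln, reweight = NULL, pseudocount = 0.5)
#' head(score_table(fit))
dca <- function(msa, reweight = 0.9, pseudocount = 0.5, include_gap = TRUE,
                methods = c("fapc", "mi", "miapc")) {
  cl <- match.call()
  if (is.character(msa)) msa <- rna_msa(msa)
  if (!inherits(msa, "rna_msa")) stop_usage("msa must be an rna_msa object")
  methods <- match.arg(methods, c("fapc", "mi", "miapc"), several.ok = TRUE)
  w <- if (is.null(reweight)) {
    structure(list(weights = rep(1, msa$M), Meff = msa$M, threshold = NA_real_),
              class = "rna_weights")
  } else {
    compute_weights(msa, reweight)
  }
  freq <- compute_frequencies(msa, w, pseudocount = pseudocount)
  scores <- list()
  couplings <- NULL
  if ("fapc" %in% methods) {
    couplings <- mean_field_couplings(freq)
    scores$fapc <- frobenius_apc_score(couplings, include_gap = include_gap)
  }
  if ("mi" %in% methods) scores$mi <- mutual_information(freq, apc = FALSE)
  if ("miapc" %in% methods) scores$miapc <- mutual_information(freq, apc = TRUE)
  structure(list(msa = msa, weights = w, freq = freq, couplings = couplings,
                 scores = scores, include_gap = include_gap, call = cl),
            class = "rna_dca")
}

#' @export
print.rna_dca <- function(x, ...) {
  cat("Mean-field direct-coupling fit\n")
  cat(sprintf("  alignment: %d sequences x %d columns\n", x$msa$M, x$msa$L))
  cat(sprintf("  Meff = %.2f (reweighting threshold %s), pseudocount = %g\n",
              x$weights$Meff,
              if (is.na(x$weights$threshold)) "off"
              else sprintf("%g", x$weights$threshold),
              x$freq$lambda))
  cat(sprintf("  scores: %s\n", paste(names(x$scores), collapse = ", ")))
  invisible(x)
}

#' @describeIn dca Top-ranked column pairs per score and fit diagnostics.
#' @param object,x an `rna_dca` fit.
#' @param n_top number of top pairs to display.
#' @param ... unused.
#' @export
summary.rna_dca <- function(object, n_top = 10L, ...) {
  out <- list(fit = object, n_top = n_top,
              top = lapply(object$scores, function(s) {
                utils::head(score_table_matrix(s), n_top)
              }))
  class(out) <- "summary.rna_dca"
  out
}

#' @export
print.summary.rna_dca <- function(x, ...) {
  print(x$fit)
  for (k in names(x$top)) {
    cat(sprintf("\nTop %d pairs by %s:\n", x$n_top, k))
    print(x$top[[k]], row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn dca Extract coupling blocks (`what = "couplings"`), fields
#'   (`"fields"`), or a score matrix (`"scores"`, selected by `method`).
#' @param what which component to return.
#' @param method score kind for `what = "scores"`.
#' @export
coef.rna_dca <- function(object, what = c("scores", "couplings", "fields"),
                         method = c("fapc", "mi", "miapc"), ...) {
  what <- match.arg(what)
  if (what == "couplings") return(object$couplings$e)
  if (what == "fields") return(object$couplings$h)
  method <- match.arg(method)
  sc <- object$scores[[method]]
  if (is.null(sc)) stop_usage("score '", method, "' was not computed")
  sc
}

#' @describeIn dca Predict from the fit: `type = "scores"` returns the
#'   ranked pair table; `type = "structure"` runs the covariance-scored
#'   Nussinov fold for a target row (requires `target`); `type = "contacts"`
#'   filters and ranks tertiary pair candidates (requires `target` and a
#'   secondary structure; a contact map adds true-positive labels).
#' @param target target sequence id (a row of the fitted alignment).
#' @param type what to predict.
#' @param top_k number of covariance scores retained when building the
#'   Nussinov pair-score matrix (default: alignment length).
#' @param min_loop minimum hairpin loop length.
#' @param ss secondary structure (`rna_structure`) for the tertiary-pair
#'   exclusion rule; for `type = "contacts"` defaults to the curated
#'   consensus structure when available.
#' @param contact_map optional `rna_contactmap` for TP labelling.
#' @param threshold contact distance threshold in Angstrom (4 or 8).
#' @export
predict.rna_dca <- function(object, target = NULL,
                            type = c("scores", "structure", "contacts"),
                            method = c("fapc", "mi", "miapc"),
                            top_k = NULL, min_loop = 3L, ss = NULL,
                            contact_map = NULL, threshold = 8, ...) {
  type <- match.arg(type)
  method <- match.arg(method)
  sc <- object$scores[[method]]
  if (is.null(sc)) stop_usage("score '", method, "' was not computed")
  if (type == "scores") return(score_table(object, method = method))
  if (is.null(target)) stop_usage("'target' is required for type = '", type, "'")
  cmap <- build_column_map(object$msa, target)
  if (type == "structure") {
    psm <- build_pair_scores(sc, cmap, top_k = top_k)
    return(nussinov(psm, min_loop = min_loop))
  }
  if (is.null(ss)) {
    ss <- if (!is.null(object$msa$consensus)) {
      curate_consensus(object$msa, cmap)
    } else {
      rna_structure(NULL, nchar(cmap$target))
    }
  }
  filter_and_rank(sc, cmap, ss, cm = contact_map, threshold = threshold)
}

#' @describeIn dca Image of a score matrix (upper triangle) with the
#'   strongest pairs highlighted.
#' @export
plot.rna_dca <- function(x, method = c("fapc", "mi", "miapc"), ...) {
  method <- match.arg(method)
  sc <- x$scores[[method]]
  if (is.null(sc)) stop_usage("score '", method, "' was not computed")
  z <- sc
  z[lower.tri(z, diag = TRUE)] <- NA
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "alignment column i", ylab = "alignment column j",
                  main = paste(attr(sc, "kind"), "score"), ...)
  invisible(x)
}

#' @describeIn dca Draw alignments from the fitted Potts model (couplings +
#'   fields) by Gibbs sampling, one independent chain per sequence.
#' @param nsim number of alignments to draw.
#' @param seed optional RNG seed.
#' @param M sequences per simulated alignment (default: as fitted).
#' @param burn_in Gibbs burn-in sweeps per chain.
#' @export
simulate.rna_dca <- function(object, nsim = 1, seed = NULL,
                             M = object$msa$M, burn_in = 200L, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$couplings)) stop_usage("fit has no couplings")
  L <- object$msa$L
  e <- object$couplings$e
  edges <- list()
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- e[i, j, , ]
      if (sum(blk^2) > 1e-12) {
        edges[[length(edges) + 1L]] <- list(i = i, j = j, e = blk)
      }
    }
  }
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    S <- gibbs_sample_potts(L, M, edges, object$couplings$h,
                            burn_in = burn_in)
    rows <- apply(S, 1L, decode_row)
    out[[s]] <- rna_msa(rows, ids = sprintf("sim%d_%d", s, seq_len(M)))
  }
  if (nsim == 1L) out[[1L]] else out
}

#' Ranked pair table of a score matrix
#'
#' @param fit an `rna_dca` fit (or use [coef.rna_dca()] and
#'   `score_table_matrix` internals via this interface).
#' @param method score kind.
#' @return data.frame `i`, `j` (1-based alignment columns), `score`,
#'   descending by score with deterministic (i, j) tie order.
#' @export
score_table <- function(fit, method = c("fapc", "mi", "miapc")) {
  method <- match.arg(method)
  sc <- fit$scores[[method]]
  if (is.null(sc)) stop_usage("score '", method, "' was not computed")
  score_table_matrix(sc)
}

score_table_matrix <- function(sc) {
  L <- nrow(sc)
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  tab <- data.frame(i = ut[, 1], j = ut[, 2], score = sc[ut])
  tab <- tab[order(-tab$score, tab$i, tab$j), ]
  rownames(tab) <- NULL
  tab
}
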