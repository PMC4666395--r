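#' Map alignment columns to positions of a target sequence
#'
#' @param msa an `rna_msa`.
#' @param target_id identifier of the target row.
#' @return an object of class `rna_colmap`: list with `target` (ungapped
#'   target string), `target_id`, `col_to_pos` (integer vector over columns,
#'   `NA` where the target row is gapped) and `pos_to_col` (inverse).
#' @export
build_column_map <- function(msa, target_id) {
  m <- match(target_id, msa$ids)
  if (is.na(m)) stop_rnadca("unknown sequence id: ", target_id)
  codes <- msa$seq[m, ]
  nongap <- which(codes != 1L)
  if (length(nongap) == 0L) stop_rnadca("target row is all gaps")
  col_to_pos <- rep(NA_integer_, msa$L)
  col_to_pos[nongap] <- seq_along(nongap)
  structure(list(target = paste(rna_states[codes[nongap]], collapse = ""),
                 target_id = target_id,
                 col_to_pos = col_to_pos,
                 pos_to_col = nongap),
            class = "rna_colmap")
}

#' @export
print.rna_colmap <- function(x, ...) {
  cat(sprintf("Column map for '%s': %d target nt over %d alignment columns\n",
              x$target_id, length(x$pos_to_col), length(x$col_to_pos)))
  invisible(x)
}

#' Curate a consensus secondary structure for a specific target
#'
#' Maps each consensus column pair onto the target sequence, keeping only
#' pairs whose target nucleotides form a Watson-Crick or wobble pair
#' (provenance `"consensus-kept"`); pairs with an unmappable end, an
#' incompatible nucleotide pair, or a conflict with an already-kept pair are
#' dropped (`"removed-incompatible"`). With `extend_helices = TRUE`, pairs
#' `(i-1, j+1)` and `(i+1, j-1)` adjacent to kept helices are added
#' iteratively while compatible, non-conflicting, nested and loop-legal
#' (`"helix-extension"`).
#'
#' @param msa an `rna_msa` carrying a consensus structure.
#' @param cmap column map from [build_column_map()] for the same alignment.
#' @param extend_helices add WC/wobble-compatible helix extensions
#'   (off by default).
#' @param min_loop minimum number of unpaired nucleotides between the two
#'   ends of a pair (default 3).
#' @return an `rna_structure` on target coordinates with per-pair
#'   provenance; the table of removed consensus pairs is attached as
#'   attribute `"removed"`.
#' @export
curate_consensus <- function(msa, cmap, extend_helices = FALSE,
                             min_loop = 3L) {
  if (is.null(msa$consensus)) stop_rnadca("alignment has no consensus structure")
  tgt <- strsplit(cmap$target, "", fixed = TRUE)[[1]]
  n <- length(tgt)
  kept <- matrix(integer(0), 0, 2)
  prov <- character(0)
  removed <- data.frame(col_i = integer(0), col_j = integer(0),
                        reason = character(0))
  cp <- msa$consensus
  if (nrow(cp) > 0) {
    for (r in seq_len(nrow(cp))) {
      ci <- cp[r, 1]; cj <- cp[r, 2]
      pi <- cmap$col_to_pos[ci]; pj <- cmap$col_to_pos[cj]
      if (is.na(pi) || is.na(pj)) {
        removed <- rbind(removed, data.frame(col_i = ci, col_j = cj,
                                             reason = "unmappable"))
        next
      }
      if (!wc_compatible(tgt[pi], tgt[pj]) || pj - pi - 1L < min_loop) {
        removed <- rbind(removed, data.frame(col_i = ci, col_j = cj,
                                             reason = "not-compatible"))
        next
      }
      cand <- rbind(kept, c(pi, pj))
      if (anyDuplicated(as.vector(cand)) || !is_nested(as_pair_matrix(cand))) {
        removed <- rbind(removed, data.frame(col_i = ci, col_j = cj,
                                             reason = "conflict"))
        next
      }
      kept <- cand
      prov <- c(prov, "consensus-kept")
    }
  }
  if (extend_helices && nrow(kept) > 0) {
    repeat {
      added <- FALSE
      for (r in seq_len(nrow(kept))) {
        for (d in c(-1L, 1L)) {   # -1: outward (i-1, j+1); +1: inward
          pi <- kept[r, 1] + d; pj <- kept[r, 2] - d
          if (pi < 1L || pj > n || pj - pi - 1L < min_loop) next
          if (pi %in% as.vector(kept) || pj %in% as.vector(kept)) next
          if (!wc_compatible(tgt[pi], tgt[pj])) next
          cand <- rbind(kept, c(pi, pj))
          if (!is_nested(as_pair_matrix(cand))) next
          kept <- cand
          prov <- c(prov, "helix-extension")
          added <- TRUE
        }
      }
      if (!added) break
    }
  }
  ord <- order(kept[, 1])
  st <- rna_structure(kept[ord, , drop = FALSE], n,
                      provenance = prov[ord])
  attr(st, "sequence") <- cmap$target
  attr(st, "removed") <- removed
  st
}
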