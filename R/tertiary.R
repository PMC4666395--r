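#' Heavy-atom contact map of an RNA chain from a PDB file
#'
#' Parses the coordinate section (ATOM records) of a PDB file, keeps the
#' standard nucleotide residues (A, C, G, U; waters, ions and other
#' heteroatoms excluded), drops hydrogens, resolves alternate locations to
#' the highest-occupancy conformer, and computes the minimal pairwise
#' distance between non-hydrogen atoms of every residue pair. Residues are
#' indexed sequentially along the chain; the PDB-number/insertion-code to
#' sequential-index table is returned alongside.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default: first chain containing
#'   nucleotide residues).
#' @return object of class `rna_contactmap`: list with `n`, `dist`
#'   (n x n minimal heavy-atom distances in Angstrom, `NA` diagonal),
#'   `resolved` (residues with at least one heavy atom), `sequence`
#'   (one-letter chain sequence) and `index_table` (sequential index,
#'   PDB residue number, insertion code, residue name).
#' @export
contact_map_from_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_rnadca("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0L) stop_rnadca("no ATOM records in ", path)
  fld <- function(x, a, b) trimws(substr(x, a, b))
  rec <- data.frame(
    name = fld(atoms, 13, 16),
    altloc = fld(atoms, 17, 17),
    resname = fld(atoms, 18, 20),
    chain = fld(atoms, 22, 22),
    resseq = as.integer(fld(atoms, 23, 26)),
    icode = fld(atoms, 27, 27),
    x = as.numeric(fld(atoms, 31, 38)),
    y = as.numeric(fld(atoms, 39, 46)),
    z = as.numeric(fld(atoms, 47, 54)),
    occ = suppressWarnings(as.numeric(fld(atoms, 55, 60))),
    elem = fld(atoms, 77, 78),
    stringsAsFactors = FALSE)
  rec$occ[is.na(rec$occ)] <- 1
  rec <- rec[rec$resname %in% c("A", "C", "G", "U"), , drop = FALSE]
  if (nrow(rec) == 0L) stop_rnadca("no nucleotide residues in ", path)
  if (is.null(chain)) chain <- rec$chain[1]
  rec <- rec[rec$chain == chain, , drop = FALSE]
  if (nrow(rec) == 0L) stop_rnadca("chain '", chain, "' not found or empty")
  # hydrogens: element H/D, or H-leading atom name when element is absent
  is_h <- rec$elem %in% c("H", "D") |
    (!nzchar(rec$elem) & grepl("^[0-9]*H", rec$name))
  rec <- rec[!is_h, , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per (residue, atom name),
  # then restore file order so residues index sequentially along the chain
  rec$ord <- seq_len(nrow(rec))
  rec <- rec[order(-rec$occ), , drop = FALSE]
  rec <- rec[!duplicated(rec[, c("resseq", "icode", "name")]), , drop = FALSE]
  rec <- rec[order(rec$ord), , drop = FALSE]
  reskey <- paste(rec$resseq, rec$icode)
  # chain order follows first appearance in the file
  first <- !duplicated(reskey)
  keys <- reskey[first]
  n <- length(keys)
  index_table <- data.frame(index = seq_len(n),
                            resseq = rec$resseq[first],
                            icode = rec$icode[first],
                            resname = rec$resname[first],
                            stringsAsFactors = FALSE)
  res_of_atom <- match(reskey, keys)
  coords <- as.matrix(rec[, c("x", "y", "z")])
  D2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  D2[D2 < 0] <- 0
  dist <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    ai <- which(res_of_atom == i)
    for (j in seq_len(n)) {
      if (j == i) next
      aj <- which(res_of_atom == j)
      dist[i, j] <- sqrt(min(D2[ai, aj]))
    }
  }
  structure(list(n = n, dist = dist, resolved = seq_len(n),
                 sequence = paste(index_table$resname, collapse = ""),
                 index_table = index_table, chain = chain),
            class = "rna_contactmap")
}

#' @export
print.rna_contactmap <- function(x, ...) {
  cat(sprintf("Contact map: chain %s, %d residues\n", x$chain, x$n))
  invisible(x)
}

#' Reconcile a contact map with an alignment target sequence
#'
#' Locates the one-letter chain sequence as an exact substring of the
#' ungapped target (or vice versa) and re-indexes the contact map onto
#' target positions; target positions outside the match are unresolved.
#'
#' @param cm an `rna_contactmap`.
#' @param target ungapped target sequence string.
#' @return an `rna_contactmap` on target coordinates, with a `mismatch`
#'   report element describing the match offset.
#' @export
align_contact_map <- function(cm, target) {
  nt <- nchar(target)
  hit <- regexpr(cm$sequence, target, fixed = TRUE)[1]
  if (hit > 0) {
    off <- hit - 1L
    map <- seq_len(cm$n) + off       # chain index -> target position
  } else {
    hit2 <- regexpr(target, cm$sequence, fixed = TRUE)[1]
    if (hit2 < 0) {
      stop_rnadca("chain sequence does not match the target ",
                  "(no exact substring in either direction)")
    }
    map <- rep(NA_integer_, cm$n)
    map[seq_len(nt) + hit2 - 1L] <- seq_len(nt)
  }
  dist <- matrix(NA_real_, nt, nt)
  ok <- which(!is.na(map) & map >= 1L & map <= nt)
  dist[map[ok], map[ok]] <- cm$dist[ok, ok]
  diag(dist) <- NA_real_
  structure(list(n = nt, dist = dist, resolved = sort(map[ok]),
                 sequence = target, index_table = cm$index_table,
                 chain = cm$chain,
                 mismatch = list(offset = if (hit > 0) hit - 1L else NA_integer_,
                                 chain_in_target = hit > 0)),
            class = "rna_contactmap")
}

#' Filter and rank candidate tertiary pairs by coevolution score
#'
#' All alignment-column pairs are mapped to target residues; pairs with an
#' unmappable end (gap in the target row, or residue unresolved in the
#' contact map when one is supplied) are excluded with reason
#' `"unmappable"`; then the two trivial-vicinity rules apply: pairs with
#' `|i - j| < 5` are excluded (`"near-diagonal"`), and for each secondary
#' structure base pair (k, l) all 25 pairs (k±0,1,2 , l±0,1,2) are excluded
#' (`"ss-neighborhood"`). Each excluded pair records the first matching
#' rule. Survivors are sorted by score descending (ties by i, then j) and,
#' when a contact map is given, labelled TP iff the minimal heavy-atom
#' distance is at or below `threshold`.
#'
#' @param scores L x L score matrix on alignment columns.
#' @param cmap target column map.
#' @param ss secondary structure (`rna_structure`) on target coordinates
#'   used for the neighborhood exclusion; may be empty.
#' @param cm optional `rna_contactmap` on target coordinates.
#' @param threshold TP distance threshold in Angstrom (4 or 8).
#' @return object of class `rna_ranked`: list with `pairs` (data.frame
#'   `i`, `j`, `col_i`, `col_j`, `nt_i`, `nt_j`, `score`, `dist`, `tp`),
#'   `excluded` (data.frame `i`, `j`, `reason`), `threshold`, `target`.
#' @export
filter_and_rank <- function(scores, cmap, ss, cm = NULL, threshold = 8) {
  L <- length(cmap$col_to_pos)
  if (nrow(scores) != L) stop_usage("score matrix does not match alignment")
  tgt <- strsplit(cmap$target, "", fixed = TRUE)[[1]]
  tab <- score_table_matrix(scores)
  tab <- tab[!is.na(tab$score), , drop = FALSE]
  pi <- cmap$col_to_pos[tab$i]
  pj <- cmap$col_to_pos[tab$j]
  lo <- pmin(pi, pj); hi <- pmax(pi, pj)
  unmap <- is.na(pi) | is.na(pj)
  if (!is.null(cm)) {
    unmap <- unmap |
      (!is.na(pi) & !(pi %in% cm$resolved)) |
      (!is.na(pj) & !(pj %in% cm$resolved))
  }
  near <- !unmap & (hi - lo < 5L)
  ssnb <- rep(FALSE, nrow(tab))
  if (nrow(ss$pairs) > 0) {
    for (r in seq_len(nrow(ss$pairs))) {
      k <- ss$pairs[r, 1]; l <- ss$pairs[r, 2]
      in_nb <- !unmap & !near &
        ((abs(lo - k) <= 2L & abs(hi - l) <= 2L) |
           (abs(lo - l) <= 2L & abs(hi - k) <= 2L))
      ssnb <- ssnb | in_nb
    }
  }
  reason <- rep(NA_character_, nrow(tab))
  reason[ssnb] <- "ss-neighborhood"
  reason[near] <- "near-diagonal"
  reason[unmap] <- "unmappable"
  keep <- is.na(reason)
  pairs <- data.frame(i = lo[keep], j = hi[keep],
                      col_i = tab$i[keep], col_j = tab$j[keep],
                      nt_i = tgt[lo[keep]], nt_j = tgt[hi[keep]],
                      score = tab$score[keep],
                      dist = NA_real_, tp = NA,
                      stringsAsFactors = FALSE)
  if (!is.null(cm)) {
    pairs$dist <- cm$dist[cbind(pairs$i, pairs$j)]
    pairs$tp <- !is.na(pairs$dist) & pairs$dist <= threshold
  }
  pairs <- pairs[order(-pairs$score, pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  excluded <- data.frame(i = lo[!keep], j = hi[!keep],
                         col_i = tab$i[!keep], col_j = tab$j[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(pairs = pairs, excluded = excluded, threshold = threshold,
                 target = cmap$target),
            class = "rna_ranked")
}

#' @export
print.rna_ranked <- function(x, ...) {
  cat(sprintf("Ranked tertiary pair list: %d retained, %d excluded",
              nrow(x$pairs), nrow(x$excluded)))
  if (any(!is.na(x$pairs$tp))) {
    cat(sprintf(" | %d TP at %g A", sum(x$pairs$tp, na.rm = TRUE),
                x$threshold))
  }
  cat("\n")
  invisible(x)
}

#' Cumulative precision (TP-rate) curve of a ranked pair list
#'
#' Precision TP/(TP+FP) among the first n predictions, as a function of n,
#' together with the oracle curve obtained by re-ranking the same pairs by
#' ascending distance (the theoretical best: all contacts precede the first
#' non-contact).
#'
#' @param rpl an `rna_ranked` with TP labels.
#' @return data.frame `rank`, `precision`, `oracle`.
#' @export
tp_rate_curve <- function(rpl) {
  p <- rpl$pairs
  if (nrow(p) == 0L) stop_rnadca("empty ranked pair list")
  if (all(is.na(p$tp))) stop_rnadca("pair list has no TP labels")
  lab <- p$tp
  oracle_lab <- lab[order(p$dist)]
  data.frame(rank = seq_along(lab),
             precision = cumsum(lab) / seq_along(lab),
             oracle = cumsum(oracle_lab) / seq_along(oracle_lab))
}

#' Sliding-window binomial enrichment scan
#'
#' For a ranked pair list with TP labels, slides a window of size
#' `Y = round(window_fraction * length)` (half-up, floored at 1) over the
#' ranking: at offset X the window holds ranks X+1..X+Y with T(X,Y) true
#' positives. The null model redraws the window i.i.d. from the pairs of
#' rank > X, whose TP fraction is r0(X); the P-value is the exact binomial
#' tail `P[Binomial(Y, r0(X)) >= T(X,Y)]`. The scan summary reports the
#' first offset X at which p exceeds `alpha` (enrichment no longer
#' significant) together with the sensitivity and precision of the first X
#' predictions.
#'
#' @param rpl an `rna_ranked` with TP labels.
#' @param window_fraction window size as a fraction of the list (default
#'   0.10).
#' @param alpha significance threshold (default 0.01).
#' @return object of class `rna_enrichment`: list with `scan` (data.frame
#'   `X`, `T`, `r0`, `p`), `Y`, `alpha`, `first_crossing` (NA when p never
#'   exceeds alpha), `sensitivity`, `precision` (NA at X = 0).
#' @export
enrichment_scan <- function(rpl, window_fraction = 0.10, alpha = 0.01) {
  p <- rpl$pairs
  if (nrow(p) == 0L) stop_rnadca("empty ranked pair list")
  if (all(is.na(p$tp))) stop_rnadca("pair list has no TP labels")
  lab <- as.logical(p$tp)
  n <- length(lab)
  Y <- max(1L, as.integer(floor(window_fraction * n + 0.5)))
  if (Y > n) stop_rnadca("window larger than the list")
  tail_tp <- rev(cumsum(rev(lab)))          # TP count among ranks > X-1
  Xs <- 0:(n - Y)
  Tc <- integer(length(Xs))
  r0 <- numeric(length(Xs))
  pv <- numeric(length(Xs))
  cum <- cumsum(lab)
  for (k in seq_along(Xs)) {
    X <- Xs[k]
    Tc[k] <- cum[X + Y] - if (X > 0) cum[X] else 0L
    rem_tp <- if (X < n) tail_tp[X + 1L] else 0L
    r0[k] <- rem_tp / (n - X)
    pv[k] <- binom_tail(Tc[k], Y, r0[k])
  }
  cross <- which(pv > alpha)
  first_crossing <- if (length(cross)) Xs[cross[1]] else NA_integer_
  total_tp <- sum(lab)
  sens <- prec <- NA_real_
  if (!is.na(first_crossing)) {
    X <- first_crossing
    tp_head <- if (X > 0) cum[X] else 0L
    sens <- if (total_tp > 0) tp_head / total_tp else NA_real_
    prec <- if (X > 0) tp_head / X else NA_real_
  }
  structure(list(scan = data.frame(X = Xs, T = Tc, r0 = r0, p = pv),
                 Y = Y, alpha = alpha, first_crossing = first_crossing,
                 sensitivity = sens, precision = prec, n = n,
                 total_tp = total_tp),
            class = "rna_enrichment")
}

# exact upper binomial tail P[Bin(Y, r0) >= T] as an explicit PMF sum
binom_tail <- function(T, Y, r0) {
  if (T <= 0L) return(1)
  if (r0 <= 0) return(0)
  if (r0 >= 1) return(1)
  sum(stats::dbinom(T:Y, Y, r0))
}

#' @export
print.rna_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment scan: window Y = %d over %d pairs (%d TP)\n",
              x$Y, x$n, x$total_tp))
  if (is.na(x$first_crossing)) {
    cat(sprintf("  P-value never exceeds alpha = %g\n", x$alpha))
  } else {
    cat(sprintf("  first P > %g at X = %d | sensitivity %.3f, precision %s\n",
                x$alpha, x$first_crossing, x$sensitivity,
                if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision)))
  }
  invisible(x)
}

#' @describeIn enrichment_scan Plot the P-value profile of a scan.
#' @param x an `rna_enrichment`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rna_enrichment <- function(x, ...) {
  graphics::plot(x$scan$X, pmax(x$scan$p, 1e-300), log = "y", type = "l",
                 xlab = "X (predictions skipped)", ylab = "enrichment P-value",
                 ...)
  graphics::abline(h = x$alpha, lty = 2)
  if (!is.na(x$first_crossing)) {
    graphics::abline(v = x$first_crossing, lty = 3)
  }
  invisible(x)
}

# default representative base atom per nucleotide (configurable stand-in
# for a full atom-pair mapping table): ring nitrogen facing the pairing
# edge -- N1 for purines, N3 for pyrimidines.
default_atom_rule <- c(A = "N1", G = "N1", C = "N3", U = "N3")

#' Export top-ranked predicted contacts as distance restraints
#'
#' Writes one restraint per selected pair: residue indices, one
#' representative atom per residue (per-nucleotide rule, configurable) and
#' a flat-bottom upper distance bound. Two formats: a generic TSV
#' (`i j nt_i nt_j atom_i atom_j score upper`) and Rosetta-style
#' `AtomPair` constraint lines
#' (`AtomPair <atom_i> <i> <atom_j> <j> BOUNDED 0.000 <upper> 1.000`) —
#' soft homogeneous restraints, native distances unknown.
#'
#' @param rpl an `rna_ranked`.
#' @param top_n number of top-ranked pairs to export.
#' @param path output file path.
#' @param format `"tsv"` or `"rosetta"`.
#' @param atom_rule named character vector mapping nucleotide to atom name.
#' @param upper flat-bottom upper bound in Angstrom (default 8).
#' @param header optional comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
export_restraints <- function(rpl, top_n, path, format = c("tsv", "rosetta"),
                              atom_rule = default_atom_rule, upper = 8,
                              header = NULL) {
  format <- match.arg(format)
  if (!is.numeric(top_n) || top_n < 0) stop_usage("top_n must be >= 0")
  if (top_n > nrow(rpl$pairs)) {
    stop_usage("top_n exceeds the ranked list length (", nrow(rpl$pairs), ")")
  }
  sel <- utils::head(rpl$pairs, top_n)
  ai <- unname(atom_rule[sel$nt_i])
  aj <- unname(atom_rule[sel$nt_j])
  out <- if (!is.null(header)) paste0("# ", header) else character(0)
  if (format == "tsv") {
    out <- c(out, "i\tj\tnt_i\tnt_j\tatom_i\tatom_j\tscore\tupper")
    if (nrow(sel) > 0) {
      out <- c(out, sprintf("%d\t%d\t%s\t%s\t%s\t%s\t%.6g\t%.3f",
                            sel$i, sel$j, sel$nt_i, sel$nt_j, ai, aj,
                            sel$score, upper))
    }
  } else {
    if (nrow(sel) > 0) {
      out <- c(out, sprintf("AtomPair %s %d %s %d BOUNDED 0.000 %.3f 1.000",
                            ai, sel$i, aj, sel$j, upper))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a restraint file written by [export_restraints()]
#'
#' @param path restraint file (TSV or Rosetta `AtomPair` lines,
#'   auto-detected).
#' @return data.frame with columns `i`, `j`, `atom_i`, `atom_j`, `upper`
#'   (plus `nt_i`, `nt_j`, `score` for TSV input).
#' @export
read_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(i = integer(0), j = integer(0),
                      atom_i = character(0), atom_j = character(0),
                      upper = numeric(0)))
  }
  if (startsWith(lines[1], "AtomPair")) {
    f <- strsplit(lines, "\\s+")
    data.frame(i = as.integer(vapply(f, `[`, "", 3)),
               j = as.integer(vapply(f, `[`, "", 5)),
               atom_i = vapply(f, `[`, "", 2),
               atom_j = vapply(f, `[`, "", 4),
               upper = as.numeric(vapply(f, `[`, "", 8)),
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) {
      return(data.frame(i = integer(0), j = integer(0),
                        atom_i = character(0), atom_j = character(0),
                        upper = numeric(0)))
    }
    tab
  }
}
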