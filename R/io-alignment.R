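#' Read an RNA multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into an `rna_msa` object. The
#' alphabet is normalized to `(-, A, C, G, U)`: lowercase is uppercased,
#' `T` becomes `U`, and every other symbol (`.`, `N`, IUPAC degenerate codes,
#' ...) becomes a gap. For Stockholm input the `#=GC SS_cons` line is parsed
#' into a nested consensus structure (crossing pairs from extended WUSS are
#' kept separately), and insert columns — columns where the `#=GC RF`
#' annotation, when present, is `.` or lowercase — are dropped, with the
#' retained-column mask recorded.
#'
#' @param path path to the alignment file.
#' @param format `"auto"` (by extension/content), `"fasta"` or `"stockholm"`.
#' @return an object of class `rna_msa`: a list with elements `ids`, `rows`
#'   (normalized aligned strings), `seq` (M x L integer matrix over the state
#'   order of [rna_states]), `M`, `L`, `consensus` (2-column matrix of
#'   1-based column pairs or `NULL`), `crossing` (idem), and `col_mask`
#'   (logical over the original columns, or `NULL` when nothing was dropped).
#' @seealso [write_msa()], [build_column_map()], [curate_consensus()]
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_rnadca("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE)) {
      "stockholm"
    } else if (grepl("\\.(fa|fasta|afa|fna)$", path, ignore.case = TRUE)) {
      "fasta"
    } else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) && grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
    }
  }
  switch(format,
         fasta = read_msa_fasta(path),
         stockholm = read_msa_stockholm(path))
}

read_msa_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_rnadca("cannot parse FASTA: ",
                                                  conditionMessage(e)))
  if (length(set) == 0L) stop_rnadca("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  rows <- unname(normalize_rna(as.character(set)))
  new_msa(ids, rows, consensus = NULL, crossing = NULL, col_mask = NULL)
}

read_msa_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_rnadca("empty alignment file: ", path)
  seqs <- list()
  order_ids <- character(0)
  ss_cons <- ""
  rf <- ""
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss_cons <- paste0(ss_cons, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (grepl("^#=GC\\s+RF\\s", ln)) {
      rf <- paste0(rf, sub("^#=GC\\s+RF\\s+", "", ln))
    } else if (grepl("^#", ln)) {
      next  # other annotations ignored
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) {
        stop_rnadca("malformed Stockholm sequence line: ", ln)
      }
      id <- parts[1]
      if (is.null(seqs[[id]])) {
        seqs[[id]] <- parts[2]
        order_ids <- c(order_ids, id)
      } else {
        seqs[[id]] <- paste0(seqs[[id]], parts[2])
      }
    }
  }
  if (length(seqs) == 0L) stop_rnadca("no sequences in Stockholm file: ", path)
  raw_rows <- unlist(seqs[order_ids], use.names = FALSE)
  L0 <- unique(nchar(raw_rows))
  if (length(L0) != 1L) stop_rnadca("ragged alignment: unequal row lengths")
  keep <- rep(TRUE, L0)
  dropped <- FALSE
  if (nzchar(rf)) {
    if (nchar(rf) != L0) stop_rnadca("RF annotation length mismatch")
    rfc <- strsplit(rf, "", fixed = TRUE)[[1]]
    keep <- !(rfc == "." | grepl("[a-z]", rfc))
    dropped <- !all(keep)
  }
  subset_cols <- function(s) {
    paste(strsplit(s, "", fixed = TRUE)[[1]][keep], collapse = "")
  }
  if (dropped) raw_rows <- vapply(raw_rows, subset_cols, character(1),
                                  USE.NAMES = FALSE)
  rows <- normalize_rna(raw_rows)
  consensus <- NULL
  crossing <- NULL
  if (nzchar(ss_cons)) {
    if (nchar(ss_cons) != L0) stop_rnadca("SS_cons length mismatch")
    if (dropped) ss_cons <- subset_cols(ss_cons)
    ss <- parse_wuss(ss_cons)
    consensus <- ss$nested
    crossing <- ss$crossing
  }
  new_msa(order_ids, rows, consensus = consensus, crossing = crossing,
          col_mask = if (dropped) keep else NULL)
}

new_msa <- function(ids, rows, consensus = NULL, crossing = NULL,
                    col_mask = NULL) {
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop_rnadca("ragged alignment: unequal row lengths")
  if (L < 1L) stop_rnadca("alignment has zero columns")
  structure(list(ids = ids, rows = rows, seq = encode_rows(rows),
                 M = length(rows), L = L, consensus = consensus,
                 crossing = crossing, col_mask = col_mask),
            class = "rna_msa")
}

#' Construct an alignment from in-memory sequences
#'
#' @param rows character vector of aligned sequences (equal length).
#' @param ids sequence identifiers; defaults to `seq1, seq2, ...`.
#' @param consensus optional 2-column matrix of nested column pairs.
#' @return an `rna_msa` object (see [read_msa()]).
#' @export
rna_msa <- function(rows, ids = paste0("seq", seq_along(rows)),
                    consensus = NULL) {
  new_msa(ids, normalize_rna(rows), consensus = consensus)
}

#' @export
print.rna_msa <- function(x, ...) {
  cat(sprintf("RNA alignment: %d sequences x %d columns\n", x$M, x$L))
  if (!is.null(x$consensus)) {
    cat(sprintf("  consensus structure: %d nested pairs", nrow(x$consensus)))
    if (!is.null(x$crossing) && nrow(x$crossing) > 0) {
      cat(sprintf(" (+%d crossing)", nrow(x$crossing)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write an alignment to FASTA or Stockholm
#'
#' @param msa an `rna_msa` object.
#' @param path output path.
#' @param format `"fasta"` or `"stockholm"`. Stockholm output includes a
#'   `#=GC SS_cons` line when the alignment carries a consensus structure.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", msa$ids), msa$rows))
  } else {
    w <- max(nchar(msa$ids), nchar("#=GC SS_cons"))
    out <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", w, msa$ids, msa$rows))
    if (!is.null(msa$consensus)) {
      db <- pairs_to_dotbracket(msa$consensus, msa$L)
      out <- c(out, sprintf("%-*s %s", w, "#=GC SS_cons", db))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse a WUSS/dot-bracket consensus structure string
#'
#' Bracket alphabets `()`, `<>`, `[]`, `{}` are matched with per-type stacks;
#' uppercase/lowercase letter pairs (`Aa`, `Bb`, ...) mark pseudoknots and are
#' routed to the crossing list. Bracket pairs are then accepted into the
#' nested set in bracket-precedence order (`()`, `<>`, `[]`, `{}`); a pair
#' that crosses or overlaps an already-accepted pair goes to the crossing
#' list instead, so the nested set is always pseudoknot-free.
#'
#' @param ss structure string.
#' @return list with `nested` and `crossing`, each a 2-column integer matrix
#'   of 1-based positions (i < j), ordered by opening position.
#' @export
parse_wuss <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  openers <- c("(" = ")", "<" = ">", "[" = "]", "{" = "}")
  stacks <- list()
  by_type <- list()
  letter_pairs <- list()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% names(openers)) {
      stacks[[ch]] <- c(stacks[[ch]], k)
    } else if (ch %in% openers) {
      op <- names(openers)[match(ch, openers)]
      st <- stacks[[op]]
      if (is.null(st) || length(st) == 0L) {
        stop_rnadca("unmatched closing bracket '", ch, "' at position ", k)
      }
      by_type[[op]] <- rbind(by_type[[op]], c(st[length(st)], k))
      stacks[[op]] <- st[-length(st)]
    } else if (grepl("[A-Z]", ch)) {
      stacks[[ch]] <- c(stacks[[ch]], k)
    } else if (grepl("[a-z]", ch)) {
      up <- toupper(ch)
      st <- stacks[[up]]
      if (is.null(st) || length(st) == 0L) {
        stop_rnadca("unmatched pseudoknot letter '", ch, "' at position ", k)
      }
      letter_pairs[[length(letter_pairs) + 1L]] <- c(st[length(st)], k)
      stacks[[up]] <- st[-length(st)]
    }
    # every other character (. , _ - : ~) is unpaired annotation
  }
  left <- vapply(stacks, length, integer(1))
  if (length(left) && any(left > 0L)) {
    stop_rnadca("unmatched opening symbol(s): ",
                paste(names(stacks)[left > 0L], collapse = " "))
  }
  nested <- matrix(integer(0), 0, 2)
  crossing <- matrix(integer(0), 0, 2)
  crosses <- function(p, set) {
    if (nrow(set) == 0L) return(FALSE)
    i <- p[1]; j <- p[2]
    any((set[, 1] < i & i < set[, 2] & set[, 2] < j) |
          (i < set[, 1] & set[, 1] < j & j < set[, 2]) |
          set[, 1] %in% p | set[, 2] %in% p)
  }
  for (tp in c("(", "<", "[", "{")) {
    ps <- by_type[[tp]]
    if (is.null(ps)) next
    ps <- ps[order(ps[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(ps))) {
      p <- ps[r, ]
      if (crosses(p, nested)) crossing <- rbind(crossing, p)
      else nested <- rbind(nested, p)
    }
  }
  for (p in letter_pairs) crossing <- rbind(crossing, p)
  ord <- function(m) {
    m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("i", "j")))
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  list(nested = ord(nested), crossing = ord(crossing))
}
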