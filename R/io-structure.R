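#' Construct a secondary structure object
#'
#' A set of base pairs on a target sequence of length `n`. Pairs must be
#' mutually exclusive (each position in at most one pair); nestedness is
#' checked unless `allow_crossing = TRUE`.
#'
#' @param pairs 2-column matrix of 1-based position pairs (i < j enforced).
#' @param n sequence length.
#' @param provenance optional character vector, one entry per pair (e.g.
#'   `"consensus-kept"`, `"helix-extension"`).
#' @param score optional total score (set by [nussinov()]).
#' @param allow_crossing keep crossing pairs instead of erroring.
#' @return object of class `rna_structure`.
#' @export
rna_structure <- function(pairs, n, provenance = NULL, score = NULL,
                          allow_crossing = FALSE) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) > 0) {
    if (any(pairs < 1L) || any(pairs > n)) {
      stop_rnadca("pair position out of range 1..", n)
    }
    if (anyDuplicated(as.vector(pairs))) {
      stop_rnadca("conflicting pair assignments: a position appears twice")
    }
    if (!allow_crossing && !is_nested(pairs)) {
      stop_rnadca("pairs are not nested")
    }
  }
  structure(list(pairs = pairs, n = as.integer(n),
                 provenance = provenance, score = score),
            class = "rna_structure")
}

as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

is_nested <- function(pairs) {
  if (nrow(pairs) < 2L) return(TRUE)
  for (a in seq_len(nrow(pairs) - 1L)) {
    for (b in (a + 1L):nrow(pairs)) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if ((i < k & k < j & j < l) || (k < i & i < l & l < j)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d pairs on %d nt\n",
              nrow(x$pairs), x$n))
  if (!is.null(x$score)) cat(sprintf("  total score: %.4f\n", x$score))
  if (x$n <= 200 && nrow(x$pairs) > 0 && is_nested(x$pairs)) {
    cat(" ", pairs_to_dotbracket(x$pairs, x$n), "\n")
  }
  invisible(x)
}

#' Convert a nested pair set to dot-bracket notation
#'
#' @param pairs 2-column matrix of 1-based pairs.
#' @param n sequence length.
#' @return a dot-bracket string of length `n`.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) > 0 && !is_nested(pairs)) {
    stop_rnadca("cannot write crossing pairs as plain dot-bracket")
  }
  out <- rep(".", n)
  out[pairs[, 1]] <- "("
  out[pairs[, 2]] <- ")"
  paste(out, collapse = "")
}

#' Read a secondary structure from dot-bracket or CT
#'
#' Dot-bracket files may carry an optional FASTA-like header line and an
#' optional sequence line before the structure line. CT files use the
#' standard six columns (1-based indices; partner 0 means unpaired).
#'
#' @param path input path.
#' @param format `"dotbracket"` or `"ct"` (`"auto"` by extension).
#' @return an `rna_structure`; the target sequence, when present in the
#'   file, is attached as attribute `"sequence"`.
#' @export
read_secondary_structure <- function(path,
                                     format = c("auto", "dotbracket", "ct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_rnadca("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.ct$", path, ignore.case = TRUE)) "ct"
              else "dotbracket"
  }
  if (format == "ct") read_ct(path) else read_dotbracket(path)
}

read_dotbracket <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_rnadca("no structure line in ", path)
  seq_line <- NULL
  if (length(lines) >= 2L && grepl("[ACGUTacgut]", lines[1]) &&
      grepl("^[ACGUTNRYacgutnry.-]+$", lines[1])) {
    seq_line <- normalize_rna(lines[1])
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop_rnadca("no structure line in ", path)
  ss <- parse_wuss(lines[1])
  n <- nchar(lines[1])
  st <- rna_structure(ss$nested, n)
  attr(st, "sequence") <- seq_line
  st
}

read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop_rnadca("empty CT file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) stop_rnadca("CT header must start with the residue count")
  body <- lines[-1]
  if (length(body) < n) stop_rnadca("CT file truncated: expected ", n, " rows")
  idx <- integer(n); partner <- integer(n); base <- character(n)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(f) < 5L) stop_rnadca("malformed CT row: ", body[r])
    idx[r] <- as.integer(f[1])
    base[r] <- f[2]
    partner[r] <- as.integer(f[5])
  }
  if (!identical(idx, seq_len(n))) stop_rnadca("CT rows must be numbered 1..n")
  if (any(partner < 0L | partner > n)) {
    stop_rnadca("CT partner index out of range 1..", n)
  }
  paired <- which(partner > 0L)
  # require symmetry of the partner column
  if (any(partner[partner[paired]] != paired)) {
    stop_rnadca("conflicting pair assignments in CT file")
  }
  sel <- paired[idx[paired] < partner[paired]]
  st <- rna_structure(cbind(sel, partner[sel]), n)
  attr(st, "sequence") <- normalize_rna(paste(base, collapse = ""))
  st
}

#' Write a secondary structure to dot-bracket or CT
#'
#' @param struct an `rna_structure`.
#' @param path output path.
#' @param format `"dotbracket"` or `"ct"`.
#' @param sequence target sequence; defaults to the structure's
#'   `"sequence"` attribute, or all-N placeholder (`A` is written in CT
#'   files lacking a sequence).
#' @param header comment lines (prefixed `#`) for dot-bracket output.
#' @return `path`, invisibly.
#' @export
write_secondary_structure <- function(struct, path,
                                      format = c("dotbracket", "ct"),
                                      sequence = NULL, header = NULL) {
  format <- match.arg(format)
  n <- struct$n
  if (is.null(sequence)) sequence <- attr(struct, "sequence")
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  if (nchar(sequence) != n) stop_rnadca("sequence length != structure length")
  if (format == "dotbracket") {
    out <- c(if (!is.null(header)) paste0("# ", header),
             sequence, pairs_to_dotbracket(struct$pairs, n))
  } else {
    partner <- integer(n)
    partner[struct$pairs[, 1]] <- struct$pairs[, 2]
    partner[struct$pairs[, 2]] <- struct$pairs[, 1]
    bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
    out <- c(sprintf("%d rnadca", n),
             sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                     partner, seq_len(n)))
  }
  writeLines(out, path)
  invisible(path)
}
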