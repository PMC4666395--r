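#' @title RNA alphabet used throughout the package
#' @description State order is fixed as `(-, A, C, G, U)`; the gap is state 1
#'   and serves as the reference state of the mean-field inversion. All encoded
#'   alignments, frequency arrays and coupling arrays index states in this
#'   order.
#' @format Character vector of length 5.
#' @export
rna_states <- c("-", "A", "C", "G", "U")

# 5x5 logical compatibility table over rna_states:
# Watson-Crick (A.U, G.C) plus wobble (G.U), symmetric, gap never pairs.
.wc_table <- local({
  m <- matrix(FALSE, 5L, 5L, dimnames = list(rna_states, rna_states))
  for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
})

#' Watson-Crick / wobble compatibility of two nucleotides
#'
#' A pair is compatible when it is A·U, G·C (Watson-Crick) or G·U (wobble),
#' in either orientation. Gaps are never compatible.
#'
#' @param a,b character vectors of single nucleotides over `(-, A, C, G, U)`,
#'   recycled to common length.
#' @return logical vector.
#' @export
#' @examples
#' wc_compatible(c("A", "G", "A"), c("U", "U", "G"))
wc_compatible <- function(a, b) {
  ia <- match(a, rna_states)
  ib <- match(b, rna_states)
  if (anyNA(ia) || anyNA(ib)) {
    stop_rnadca("nucleotides must be one of -, A, C, G, U")
  }
  .wc_table[cbind(ia, ib)]
}

# Normalize raw sequence characters to the 5-letter alphabet:
# uppercase, T -> U, anything not in {A,C,G,U} (including '.', N, IUPAC
# degenerate codes) becomes the gap character.
normalize_rna <- function(x) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  gsub("[^ACGU]", "-", x)
}

# Encode a character vector of equal-length strings as an integer matrix
# (M x L) over states 1..5 in rna_states order.
encode_rows <- function(rows) {
  M <- length(rows)
  L <- nchar(rows[1])
  chars <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                  nrow = M, ncol = L, byrow = TRUE)
  codes <- match(chars, rna_states)
  stopifnot(!anyNA(codes))
  matrix(codes, nrow = M, ncol = L)
}

decode_row <- function(codes) paste(rna_states[codes], collapse = "")

# internal error helpers: every user-facing error carries class
# "rnadca_error" (data/format problems) or "rnadca_usage" (bad arguments),
# which the CLI maps to exit codes 1 and 2.
stop_rnadca <- function(..., class = "rnadca_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_usage <- function(...) {
  stop_rnadca(..., class = c("rnadca_usage", "rnadca_error"))
}
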