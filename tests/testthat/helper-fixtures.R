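# Fixture builders shared across test files; everything is generated in
# code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small Stockholm family with consensus structure and an RF line
stockholm_fixture <- function() {
  write_lines_tmp(c(
    "# STOCKHOLM 1.0",
    "#=GF ID toy",
    "seq1         GGGAAAACCC",
    "seq2         GGCAAAAGCC",
    "seq3         GC-AAAA-GC",
    "#=GC SS_cons (((....)))",
    "//"), ext = ".sto")
}

# WC-coupled chain-topology alignment (couplings on i <-> i+1 only);
# the stated world: coupling strength 2.0, gap marginal ~5%, burn-in 1000
chain_alignment <- function(n = 6L, M = 2000L, J = 2.0, seed = 1L) {
  set.seed(seed)
  edges <- lapply(seq_len(n - 1L), function(i) {
    list(i = i, j = i + 1L, e = rnadca:::wc_coupling_block(J))
  })
  h <- matrix(0, n, 5)
  h[, 1] <- log(0.05 / ((1 - 0.05) / 4))
  S <- gibbs_sample_potts(n, M, edges, h, burn_in = 1000L)
  rna_msa(apply(S, 1L, function(r) paste(rna_states[r], collapse = "")))
}

# chain-model fits are shared between several acceptance checks; compute
# each replicate once per session
chain_fit_env <- new.env(parent = emptyenv())
get_chain_fits <- function(n_rep = 20L) {
  key <- as.character(n_rep)
  if (is.null(chain_fit_env[[key]])) {
    chain_fit_env[[key]] <- lapply(seq_len(n_rep), function(r) {
      dca(chain_alignment(seed = r))
    })
  }
  chain_fit_env[[key]]
}

# riboswitch-like synthetic family runs (generation + fit), shared across
# test files; the family length is the generator default (n = 70) with M
# scaled from 1000 to 500 to keep the suite inside its runtime budget
ribo_env <- new.env(parent = emptyenv())
get_ribo_runs <- function(n_rep = 20L, n = 70L, M = 500L) {
  key <- paste(n_rep, n, M)
  if (is.null(ribo_env[[key]])) {
    ribo_env[[key]] <- lapply(seq_len(n_rep), function(r) {
      spec <- generator_spec(n = n, M = M)
      sim <- sample_potts_alignment(spec, seed = 100L + r)
      list(sim = sim, fit = dca(sim$msa))
    })
  }
  ribo_env[[key]]
}
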