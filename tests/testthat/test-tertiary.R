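test_that("PDB contact maps report minimal heavy-atom distances", {
  # two single-atom residues 3 A apart
  p <- tempfile(fileext = ".pdb")
  make_pdb_fixture(cbind(1, 2), n = 2, spread = 20, distance = 3, path = p)
  cm <- contact_map_from_pdb(p)
  expect_equal(cm$n, 2L)
  expect_equal(cm$dist[1, 2], 3, tolerance = 1e-9)
  # hand-built 4-residue fixture vs brute-force all-pairs distances
  p2 <- tempfile(fileext = ".pdb")
  make_pdb_fixture(rbind(c(1, 3, 4.0), c(2, 4, 7.5)), n = 4, path = p2)
  cm2 <- contact_map_from_pdb(p2)
  coords <- do.call(rbind, lapply(readLines(p2), function(ln) {
    if (!startsWith(ln, "ATOM")) return(NULL)
    as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)))
  }))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cm2$dist[i, j], sqrt(sum((coords[i, ] - coords[j, ])^2)),
                 tolerance = 1e-9)
  }
  expect_equal(cm2$dist, t(cm2$dist))
  expect_equal(cm2$sequence, "ACGU")
})

atom_line <- function(serial, name, altloc, resname, chain, resseq,
                      x, y, z, occ = 1, elem = "N") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resseq, x, y, z, occ, 0,
          elem)
}

test_that("hydrogens, hetero residues and water are excluded", {
  lines <- c(
    atom_line(1, "N1", " ", "A", "A", 1, 0, 0, 0),
    atom_line(2, "H1", " ", "A", "A", 1, 0.5, 0, 0, elem = "H"),
    atom_line(3, "N3", " ", "C", "A", 2, 9, 0, 0),
    atom_line(4, "H3", " ", "U", "A", 3, 50, 0, 0, elem = "H"),
    atom_line(5, "O", " ", "HOH", "A", 4, 60, 0, 0, elem = "O"),
    atom_line(6, "MG", " ", "MG", "A", 5, 70, 0, 0, elem = "MG"),
    atom_line(7, "O2", " ", "G", "A", 6, 80, 0, 0, elem = "O"),
    "END")
  p <- write_lines_tmp(lines, ext = ".pdb")
  cm <- contact_map_from_pdb(p, chain = "A")
  # residue 3 (hydrogens only), the water and the ion are dropped, so the
  # chain carries residues 1, 2, 6 -> sequential indices 1..3
  expect_equal(cm$n, 3L)
  expect_equal(cm$index_table$resseq, c(1L, 2L, 6L))
  expect_equal(cm$sequence, "ACG")
  expect_equal(cm$dist[1, 2], 9, tolerance = 1e-9)
  expect_error(contact_map_from_pdb(p, chain = "B"), class = "rnadca_error")
})

test_that("altloc keeps the highest-occupancy conformer", {
  lines <- c(
    atom_line(1, "N1", "A", "A", "A", 1, 0, 0, 0, occ = 0.3),
    atom_line(2, "N1", "B", "A", "A", 1, 5, 0, 0, occ = 0.7),
    atom_line(3, "N3", " ", "C", "A", 2, 9, 0, 0),
    "END")
  cm <- contact_map_from_pdb(write_lines_tmp(lines, ext = ".pdb"))
  # residue 1 uses the occupancy-0.7 conformer at x = 5 -> distance 4
  expect_equal(cm$dist[1, 2], 4, tolerance = 1e-9)
})

test_that("contact maps align to the target by exact substring match", {
  p <- tempfile(fileext = ".pdb")
  make_pdb_fixture(cbind(1, 3), n = 4, sequence = "ACGU", path = p,
                   distance = 5)
  cm <- contact_map_from_pdb(p)
  al <- align_contact_map(cm, "GGACGUCC")   # chain sits at offset 2
  expect_equal(al$n, 8L)
  expect_equal(al$resolved, 3:6)
  expect_equal(al$dist[3, 5], 5, tolerance = 1e-9)
  expect_error(align_contact_map(cm, "UUUUUUUU"), class = "rnadca_error")
})

test_that("tertiary pair filtering applies the exclusion rules exactly", {
  n <- 24
  rows <- paste(rep(strsplit("GGGGGAAAAACCCCCGGGGGCCCC", "")[[1]],
                    each = 1), collapse = "")
  msa <- rna_msa(c(rows, rows), ids = c("t", "u"))
  cmap <- build_column_map(msa, "t")
  ss <- rna_structure(rbind(c(10, 20)), n)
  set.seed(3)
  sc <- matrix(0, n, n)
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  sc[ut] <- runif(nrow(ut))
  sc <- sc + t(sc); diag(sc) <- NA
  rpl <- filter_and_rank(sc, cmap, ss)
  # bookkeeping: retained + excluded = all candidate pairs
  expect_equal(nrow(rpl$pairs) + nrow(rpl$excluded), nrow(ut))
  # boundary examples
  expect_true("near-diagonal" %in%
                rpl$excluded$reason[rpl$excluded$i == 1 & rpl$excluded$j == 5])
  expect_true(any(rpl$pairs$i == 1 & rpl$pairs$j == 6))
  # (12,18) within +/-2 of ss pair (10,20); (13,18) retained
  expect_equal(rpl$excluded$reason[rpl$excluded$i == 12 &
                                     rpl$excluded$j == 18],
               "ss-neighborhood")
  expect_true(any(rpl$pairs$i == 13 & rpl$pairs$j == 18))
  # independent brute-force filter agrees pair by pair
  for (r in seq_len(nrow(ut))) {
    i <- ut[r, 1]; j <- ut[r, 2]
    want <- brute_exclusion_reason(i, j, ss$pairs)
    if (is.na(want)) {
      expect_true(any(rpl$pairs$i == i & rpl$pairs$j == j))
    } else {
      expect_equal(rpl$excluded$reason[rpl$excluded$i == i &
                                         rpl$excluded$j == j], want)
    }
  }
  # ranking is score-descending
  expect_true(all(diff(rpl$pairs$score) <= 0))
})

test_that("unmappable and unresolved pairs are excluded with reason", {
  msa <- rna_msa(c("GG-GGGGGGGGGGGG", "GGGGGGGGGGGGGGG"), ids = c("t", "u"))
  cmap <- build_column_map(msa, "t")
  n <- nchar(cmap$target)
  sc <- matrix(1, 15, 15); diag(sc) <- NA
  p <- tempfile(fileext = ".pdb")
  make_pdb_fixture(NULL, n = n, sequence = cmap$target, path = p)
  cm <- contact_map_from_pdb(p)
  cm$resolved <- setdiff(cm$resolved, 2L)   # pretend residue 2 unresolved
  rpl <- filter_and_rank(sc, cmap, rna_structure(NULL, n), cm = cm)
  expect_true(all(rpl$excluded$reason[rpl$excluded$col_i == 3 |
                                        rpl$excluded$col_j == 3] ==
                    "unmappable"))
  expect_true(all(rpl$excluded$reason[!is.na(rpl$excluded$i) &
                                        (rpl$excluded$i == 2 |
                                           rpl$excluded$j == 2)] %in%
                    c("unmappable", "near-diagonal")))
})

test_that("TP labels at 4 A are a subset of labels at 8 A", {
  runs <- get_ribo_runs(1)
  sim <- runs[[1]]$sim
  fit <- runs[[1]]$fit
  cmap <- build_column_map(sim$msa, sim$msa$ids[1])
  n <- nchar(cmap$target)
  contacts <- map_pairs_to_target(rbind(sim$truth$secondary,
                                        sim$truth$tertiary), cmap)
  p <- tempfile(fileext = ".pdb")
  make_pdb_fixture(contacts, n = n, sequence = cmap$target, path = p,
                   distance = 3)
  cm <- contact_map_from_pdb(p)
  ss <- rna_structure(map_pairs_to_target(sim$truth$secondary, cmap), n)
  r4 <- filter_and_rank(fit$scores$fapc, cmap, ss, cm = cm, threshold = 4)
  r8 <- filter_and_rank(fit$scores$fapc, cmap, ss, cm = cm, threshold = 8)
  expect_true(all(!r4$pairs$tp | r8$pairs$tp))
})

test_that("planted tertiary couplings delay the enrichment crossing", {
  # with planted couplings, the coupling-score ranking stays significantly
  # enriched deeper into the list than a randomly permuted ranking
  runs <- get_ribo_runs(20)[1:10]
  wins <- vapply(seq_along(runs), function(k) {
    run <- runs[[k]]
    cmap <- build_column_map(run$sim$msa, run$sim$msa$ids[1])
    n <- nchar(cmap$target)
    ss <- rna_structure(map_pairs_to_target(run$sim$truth$secondary, cmap), n)
    contacts <- map_pairs_to_target(rbind(run$sim$truth$secondary,
                                          run$sim$truth$tertiary), cmap)
    pdb <- tempfile(fileext = ".pdb")
    make_pdb_fixture(contacts, n = n, sequence = cmap$target, path = pdb,
                     distance = 3)
    cm <- contact_map_from_pdb(pdb)
    rpl <- filter_and_rank(run$fit$scores$fapc, cmap, ss, cm = cm)
    set.seed(7000 + k)
    perm <- rpl
    perm$pairs <- rpl$pairs[sample.int(nrow(rpl$pairs)), ]
    fc <- function(x) {
      es <- enrichment_scan(x)
      if (is.na(es$first_crossing)) es$n else es$first_crossing
    }
    fc(rpl) > fc(perm)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("TP-rate curves match the prefix-mean oracle", {
  rpl <- structure(list(pairs = data.frame(
    i = 1:6, j = 11:16, score = 6:1,
    dist = c(3, 9, 2, 10, 7, 1), tp = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)),
    threshold = 8), class = "rna_ranked")
  cv <- tp_rate_curve(rpl)
  expect_equal(cv$precision, cumsum(rpl$pairs$tp) / (1:6))
  expect_equal(cv$precision[1:3], c(1, 1 / 2, 2 / 3))
  expect_true(all(cv$oracle >= cv$precision - 1e-12))
  # all-TP list: constant 1
  rpl2 <- rpl
  rpl2$pairs$tp <- TRUE
  expect_equal(tp_rate_curve(rpl2)$precision, rep(1, 6))
  # random labels vs independent prefix-mean computation
  set.seed(12)
  lab <- runif(40) < 0.3
  rpl3 <- structure(list(pairs = data.frame(
    i = 1:40, j = 51:90, score = 40:1, dist = ifelse(lab, 3, 20), tp = lab)),
    class = "rna_ranked")
  expect_equal(tp_rate_curve(rpl3)$precision,
               vapply(1:40, function(k) mean(lab[1:k]), numeric(1)))
})

test_that("restraint export counts, formats and round-trips", {
  pairs <- data.frame(i = c(2L, 5L), j = c(20L, 30L),
                      col_i = c(2L, 5L), col_j = c(20L, 30L),
                      nt_i = c("A", "G"), nt_j = c("U", "C"),
                      score = c(1.5, 1.2), dist = NA_real_, tp = NA)
  rpl <- structure(list(pairs = pairs, threshold = 8), class = "rna_ranked")
  f <- tempfile()
  export_restraints(rpl, 2, f, format = "rosetta")
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "^AtomPair N1 2 N3 20 BOUNDED 0\\.000 8\\.000")
  back <- read_restraints(f)
  expect_equal(back$i, c(2L, 5L))
  expect_equal(back$atom_i, c("N1", "N1"))
  expect_equal(back$atom_j, c("N3", "N3"))
  # TSV round trip
  f2 <- tempfile()
  export_restraints(rpl, 2, f2, format = "tsv")
  back2 <- read_restraints(f2)
  expect_equal(back2$i, c(2L, 5L))
  expect_equal(back2$upper, c(8, 8))
  # top_n = 0: header-only file
  f3 <- tempfile()
  export_restraints(rpl, 0, f3, format = "tsv")
  expect_equal(nrow(read_restraints(f3)), 0L)
  expect_error(export_restraints(rpl, 5, tempfile()),
               class = "rnadca_usage")
})

test_that("enrichment P-values match closed forms and the enumeration oracle", {
  mk <- function(lab) {
    structure(list(pairs = data.frame(
      i = seq_along(lab), j = seq_along(lab) + 50, score = rev(seq_along(lab)),
      dist = NA_real_, tp = lab)), class = "rna_ranked")
  }
  # window with T = 0 -> p = 1
  es0 <- enrichment_scan(mk(c(rep(FALSE, 18), TRUE, TRUE)),
                         window_fraction = 0.5)
  expect_equal(es0$scan$p[1], 1)   # first window holds no TP... (see below)
  # closed form: Y = 10, r0 = 0.5, T = 10 -> 2^-10
  lab <- c(rep(TRUE, 10), rep(FALSE, 10))
  es <- enrichment_scan(mk(lab), window_fraction = 0.5)
  expect_equal(es$scan$p[1], 2^-10, tolerance = 1e-12)
  # exhaustive enumeration on random short lists
  set.seed(19)
  for (rep in 1:6) {
    m <- sample(10:15, 1)
    lab <- runif(m) < runif(1, 0.2, 0.8)
    es <- enrichment_scan(mk(lab), window_fraction = 0.3)
    for (k in seq_len(nrow(es$scan))) {
      expect_equal(es$scan$p[k],
                   window_tail_oracle(es$scan$T[k], es$Y, es$scan$r0[k]),
                   tolerance = 1e-12)
    }
    expect_true(all(es$scan$p >= 0 & es$scan$p <= 1))
    expect_true(all(es$scan$T <= es$Y))
    expect_true(all(es$scan$r0 >= 0 & es$scan$r0 <= 1))
  }
  # first crossing and its summary statistics
  lab2 <- c(rep(TRUE, 6), rep(FALSE, 30), TRUE, rep(FALSE, 3))
  es2 <- enrichment_scan(mk(lab2), window_fraction = 0.25, alpha = 0.01)
  expect_true(is.finite(es2$first_crossing))
  X <- es2$first_crossing
  expect_equal(es2$sensitivity, sum(lab2[seq_len(X)]) / sum(lab2))
  if (X > 0) expect_equal(es2$precision, sum(lab2[seq_len(X)]) / X)
})
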