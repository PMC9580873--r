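## hand-written two-residue-type PDB snippet: residues 1-3 with CB atoms,
## residue 2 is glycine (no CB), plus a water to be excluded
pdb_atom <- function(serial, name, resname, resno, x, y, z,
                     record = "ATOM", chain = "A", elem = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resno, x, y, z, 1, 0, elem)
}

mini_pdb <- function() {
  write_tmp(c(
    pdb_atom(1, "N",  "ALA", 1, 0.0, 0.0, 0),
    pdb_atom(2, "CA", "ALA", 1, 1.0, 0.0, 0),
    pdb_atom(3, "CB", "ALA", 1, 1.5, 1.0, 0),
    pdb_atom(4, "CA", "GLY", 2, 4.0, 0.0, 0),
    pdb_atom(5, "CA", "TRP", 3, 8.0, 0.0, 0),
    pdb_atom(6, "CB", "TRP", 3, 8.5, 1.0, 0),
    pdb_atom(7, "O",  "HOH", 4, 20.0, 20.0, 20.0, record = "HETATM"),
    "END"), ".pdb")
}

test_that("representative atoms follow the scheme with glycine fallback", {
  m_cb <- read_structure(mini_pdb(), chain = "A", atom_scheme = "cb")
  expect_equal(nrow(m_cb$residues), 3)
  expect_equal(m_cb$sequence, "AGW")
  expect_equal(m_cb$residues$x, c(1.5, 4.0, 8.5))  # CB, CA fallback, CB
  expect_false(any(m_cb$residues$missing))
  m_ca <- read_structure(mini_pdb(), chain = "A", atom_scheme = "ca")
  expect_equal(m_ca$residues$x, c(1.0, 4.0, 8.0))
})

test_that("residues without the representative atom are marked missing", {
  ## drop residue 1's alpha-carbon: the residue stays (N, CB remain) but
  ## has no representative atom under the CA scheme
  lines <- readLines(mini_pdb())
  noca <- write_tmp(lines[!grepl("^ATOM      2", lines)], ".pdb")
  m <- read_structure(noca, chain = "A", atom_scheme = "ca")
  expect_equal(nrow(m$residues), 3)
  expect_true(m$residues$missing[1])
  expect_false(any(m$residues$missing[2:3]))
  expect_true(is.na(m$residues$x[1]))
})

test_that("missing chains and chainless files give informative errors", {
  expect_error(read_structure(mini_pdb(), chain = "B"), "available: A")
})

test_that("synthetic chain PDB round-trips coordinates at PDB precision", {
  path <- tempfile(fileext = ".pdb")
  ch <- generate_chain(40, seed = 5, path = path)
  back <- read_structure(path, chain = "A", atom_scheme = "cb")  # CA fallback
  expect_equal(nrow(back$residues), 40)
  expect_lt(max(abs(as.matrix(back$residues[, c("x", "y", "z")]) -
                      as.matrix(ch$residues[, c("x", "y", "z")]))), 1e-3)
})

test_that("column mapping handles identity, gaps and low identity", {
  model <- read_structure(mini_pdb(), chain = "A")
  aln <- toy_alignment(c("AGW", "AG-"), ids = c("exact", "gapped"))
  m1 <- map_columns(aln, "exact", model)
  expect_equal(m1$identity, 1.0)
  expect_equal(m1$mapping$column, 1:3)
  expect_equal(m1$mapping$str_index, 1:3)

  m2 <- map_columns(aln, "gapped", model, min_identity = 0.5)
  expect_false(3 %in% m2$mapping$column)  # gap column maps to nothing

  helix <- generate_helix(40)
  rowseq <- paste(rep("W", 40), collapse = "")
  aln2 <- coev_alignment(c("w1", "w2"), c(rowseq, rowseq))
  expect_error(map_columns(aln2, "w1", helix), "identity.*floor|below")
})

test_that("manual maps must be injective and monotone", {
  expect_error(column_residue_map(c(1, 2, 2), c(1, 2, 3)), "injective")
  expect_error(column_residue_map(c(1, 2, 3), c(3, 2, 1)), "monotone")
  m <- column_residue_map(c(2, 5, 9), c(1, 2, 3))
  expect_equal(m$mapping$column, c(2, 5, 9))
})

test_that("collinear chain baseline is exact and helix matches closed form", {
  ## collinear toy chain: consecutive atoms 3.8 apart -> mean(s) = 3.8 s, sd 0
  xyz <- cbind(x = 3.8 * (0:9), y = 0, z = 0)
  lin <- coevnet:::toy_structure(xyz)
  bl <- separation_baseline(lin)
  expect_equal(bl$mean, 3.8 * bl$separation, tolerance = 1e-12)
  expect_equal(bl$sd, rep(0, nrow(bl)), tolerance = 1e-12)
  expect_equal(bl$n_pairs, 10 - bl$separation)

  helix <- generate_helix(25)
  bh <- separation_baseline(helix)
  expect_equal(bh$mean, helix_distance(bh$separation), tolerance = 1e-9)
  expect_equal(helix_distance(1), sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2))
})

test_that("baseline equals the brute-force double loop, also with gaps", {
  ch <- generate_chain(60, seed = 11)
  ch$residues$missing[c(10, 30)] <- TRUE
  ch$residues[c(10, 30), c("x", "y", "z")] <- NA
  bl <- separation_baseline(ch)
  or <- oracle_baseline(ch)
  expect_equal(bl$separation, or$separation)
  expect_equal(bl$n_pairs, or$n_pairs)
  expect_equal(bl$mean, or$mean, tolerance = 1e-12)
  expect_equal(bl$sd, or$sd, tolerance = 1e-12)
})

test_that("removing a residue leaves unrelated separations unchanged", {
  ch <- generate_chain(30, seed = 13)
  bl_full <- separation_baseline(ch)
  ch2 <- ch
  ch2$residues$missing[15] <- TRUE
  ch2$residues[15, c("x", "y", "z")] <- NA
  bl_cut <- separation_baseline(ch2)
  ## s = 29 involves only residues 1 and 30
  expect_equal(bl_cut$mean[bl_cut$separation == 29],
               bl_full$mean[bl_full$separation == 29])
  ## pairs lost at separation s: (15 - s >= 1) + (15 + s <= 30)
  lost <- (bl_full$separation <= 14) + (bl_full$separation <= 15)
  expect_equal(bl_cut$n_pairs, bl_full$n_pairs - lost)
})

test_that("evaluate_pairs compares against the separation baseline", {
  ## deterministic geometry: hairpin where residues 2 and 11 face each
  ## other across the fold while other separation-9 pairs sit wider
  xyz <- cbind(x = c(0:5, 5:0), y = c(rep(0, 6), rep(1, 6)), z = 0)
  mod <- coevnet:::toy_structure(xyz)
  bl <- separation_baseline(mod)
  map <- column_residue_map(1:12, 1:12)
  rep <- evaluate_pairs(data.frame(i = 2, j = 11), map, mod, bl)
  expect_equal(rep$pairs$separation, 9)
  expect_equal(rep$pairs$distance, 1)  # fold brings the strands together
  expect_equal(rep$pairs$expected, (1 + 2 * sqrt(5)) / 3)
  expect_true(rep$pairs$closer)
  expect_equal(rep$n_evaluated, 1)
  expect_equal(rep$n_closer, 1)
})

test_that("unmapped and unresolved pairs are excluded from the counts", {
  ch <- generate_chain(20, seed = 21)
  ch$residues$missing[5] <- TRUE
  ch$residues[5, c("x", "y", "z")] <- NA
  bl <- separation_baseline(ch)
  map <- column_residue_map(c(1:4, 6:20), c(1:4, 6:20))  # column 5 unmapped
  pairs <- data.frame(i = c(1, 2, 5, 3), j = c(10, 5, 15, 18))
  rep <- evaluate_pairs(pairs, map, ch, bl)
  expect_equal(rep$n_evaluated, 2)
  expect_equal(rep$n_unmapped, 2)
  expect_equal(rep$pairs$status, c("ok", "unmapped", "unmapped", "ok"))
  expect_equal(rep$n_closer + sum(!rep$pairs$closer[rep$pairs$status == "ok"]),
               rep$n_evaluated)
  ## ties count as not closer: strict inequality
  xyz <- cbind(x = 3.8 * (0:5), y = 0, z = 0)
  lin <- coevnet:::toy_structure(xyz)
  bl_lin <- separation_baseline(lin)
  tie <- evaluate_pairs(data.frame(i = 1, j = 3),
                        column_residue_map(1:6, 1:6), lin, bl_lin)
  expect_false(tie$pairs$closer)
  ## empty pair list: empty report, not an error
  e <- evaluate_pairs(data.frame(i = integer(0), j = integer(0)),
                      column_residue_map(1:6, 1:6), lin, bl_lin)
  expect_equal(e$n_evaluated, 0)
})

test_that("inter-chain minimum distance scans all chain assignments", {
  base <- generate_chain(15, seed = 31)
  shift <- function(m, dx) {
    m$residues$x <- m$residues$x + dx
    m$chain <- "B"
    m
  }
  far <- shift(base, 100)
  res <- interchain_min_distance(list(base, far), pair = c(2, 9))
  d_intra <- sqrt(sum((base$residues[2, c("x", "y", "z")] -
                         base$residues[9, c("x", "y", "z")])^2))
  expect_equal(res$distance, d_intra)
  expect_equal(res$type, "intra")

  ## constructed cross-chain contact: chain B sits so its residue 9 is
  ## 4 A from chain A residue 2 while the intra distance stays large
  near <- base
  near$chain <- "B"
  target <- unlist(base$residues[2, c("x", "y", "z")]) + c(4, 0, 0)
  delta <- target - unlist(base$residues[9, c("x", "y", "z")])
  near$residues$x <- near$residues$x + delta[1]
  near$residues$y <- near$residues$y + delta[2]
  near$residues$z <- near$residues$z + delta[3]
  res2 <- interchain_min_distance(list(base, near), pair = c(2, 9))
  if (d_intra > 4) {
    expect_equal(res2$distance, 4)
    expect_equal(res2$type, "inter")
  }

  ## trimer: minimum equals brute force over all 9 ordered assignments
  rot <- function(m, ang, label) {
    xy <- as.matrix(m$residues[, c("x", "y")])
    m$residues$x <- xy[, 1] * cos(ang) - xy[, 2] * sin(ang) + 30
    m$residues$y <- xy[, 1] * sin(ang) + xy[, 2] * cos(ang)
    m$chain <- label
    m
  }
  trimer <- list(base, rot(base, 2 * pi / 3, "B"), rot(base, 4 * pi / 3, "C"))
  res3 <- interchain_min_distance(trimer, pair = c(3, 12))
  brute <- Inf
  for (x in 1:3) for (y in 1:3) {
    d <- sqrt(sum((unlist(trimer[[x]]$residues[3, c("x", "y", "z")]) -
                     unlist(trimer[[y]]$residues[12, c("x", "y", "z")]))^2))
    brute <- min(brute, d)
  }
  expect_equal(res3$distance, brute)
  expect_equal(nrow(res3$assignments), 9)
})

test_that("distances are symmetric, non-negative, and triangle-consistent", {
  ch <- generate_chain(25, seed = 41)
  xyz <- as.matrix(ch$residues[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  for (k in 1:20) {
    idx <- sample(25, 3)
    expect_lte(d[idx[1], idx[3]],
               d[idx[1], idx[2]] + d[idx[2], idx[3]] + 1e-9)
  }
})
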