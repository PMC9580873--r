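test_that("joint tables tally raw rows and honor gap modes", {
  aln <- toy_alignment(c("AD", "AD", "CE", "CE"))
  tab <- joint_table(aln, 1, 2)
  expect_equal(tab$n, 4)
  expect_equal(unname(tab$counts["A", "D"]), 2)
  expect_equal(unname(tab$counts["C", "E"]), 2)
  expect_equal(sum(tab$counts), tab$n)

  gapped <- toy_alignment(c("AD", "-D", "A-", "CE"))
  expect_equal(joint_table(gapped, 1, 2, "state")$n, 4)
  expect_equal(joint_table(gapped, 1, 2, "exclude")$n, 2)

  expect_error(joint_table(aln, 2, 1), "i < j")
  expect_error(joint_table(aln, 1, 9), "out of range")
})

test_that("joint tables on a 500-row fixture equal a brute-force tally", {
  spec <- synthetic_spec(500, 10, gap_fraction = 0.1,
                         couplings = list(planted_coupling(2, 7, "L", "K", 0.1)),
                         seed = 17)
  aln <- generate_msa(spec)
  for (mode in c("state", "exclude")) {
    tab <- joint_table(aln, 2, 7, mode)
    expect_equal(tab$counts, oracle_joint_tally(aln, 2, 7, mode))
    expect_equal(sum(tab$counts), tab$n)
  }
})

test_that("residuals match their defining cases", {
  coupled <- joint_table(toy_alignment(c("AD", "AD", "CE", "CE")), 1, 2)
  rc <- residuals_table(coupled)
  ad <- rc[rc$a == "A" & rc$b == "D", ]
  expect_equal(ad$f_ab, 0.5)
  expect_equal(ad$residual, 0.25)  # maximal coupling: x - x^2 at x = 1/2

  indep <- joint_table(toy_alignment(c("AD", "AE", "CD", "CE")), 1, 2)
  ri <- residuals_table(indep)
  expect_equal(ri$residual, rep(0, nrow(ri)))
  expect_error(residuals_table(joint_table(toy_alignment(c("--", "--")),
                                           1, 2, "exclude")),
               "empty")
})

test_that("residual algebra holds on random joint tables", {
  for (seed in 1:60) {
    tab <- random_joint_table(seed)
    res <- coevnet:::residual_matrix(tab)
    expect_lte(max(abs(res)), 0.25)
    expect_lt(abs(sum(res)), 1e-9)
    expect_true(all(abs(rowSums(res)) < 1e-9))
    expect_true(all(abs(colSums(res)) < 1e-9))
    ## residual = f_ab - f_a f_b exactly
    f <- tab$counts / tab$n
    expect_equal(res, f - outer(rowSums(f), colSums(f)), tolerance = 1e-12)
  }
})

test_that("residual and p-value are symmetric under table transposition", {
  for (seed in 1:10) {
    tab <- random_joint_table(seed)
    tabT <- structure(list(i = tab$i, j = tab$j, counts = t(tab$counts),
                           n = tab$n, gap_mode = "state"),
                      class = "coev_joint")
    res <- coevnet:::residual_matrix(tab)
    expect_equal(res, t(coevnet:::residual_matrix(tabT)))
    idx <- which(tab$counts > 0, arr.ind = TRUE)[1, ]
    a <- AA_STATES[idx[1]]; b <- AA_STATES[idx[2]]
    expect_equal(as.numeric(pair_significance(tab, a, b)),
                 as.numeric(pair_significance(tabT, b, a)))
  }
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  ## the spot-check; the full n <= 12 sweep lives in the acceptance suite
  aln <- toy_alignment(c("AD", "AD", "CE", "CE"))
  tab <- joint_table(aln, 1, 2)
  expect_equal(as.numeric(pair_significance(tab, "A", "D")), 1 / 3,
               tolerance = 1e-10)  # margins 2/2, observed [[2,0],[0,2]]
  balanced <- toy_alignment(c("AD", "AE", "CD", "CE"))
  expect_equal(as.numeric(pair_significance(joint_table(balanced, 1, 2),
                                            "A", "D")), 1)
  ## degenerate margin: identity absent -> p = 1 with a flag, no error
  p <- pair_significance(tab, "W", "D")
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
})

test_that("chi-squared option agrees with stats::chisq.test", {
  tab <- joint_table(toy_alignment(c("AD", "AD", "AE", "CE", "CD", "CE")),
                     1, 2)
  m <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(as.numeric(pair_significance(tab, "A", "D", method = "chi2")),
               suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value))
})

test_that("pair space size matches the combinatorial closed form", {
  expect_equal(pair_space_size(2, 2), 4)
  expect_equal(pair_space_size(3, 1), 3)
  expect_equal(pair_space_size(300, 21), 19778850)
  expect_error(pair_space_size(1, 21), "L >= 2")
})

test_that("build_network recovers a planted coupling and filters correctly", {
  spec <- synthetic_spec(500, 60, concentration = 3,
                         couplings = list(planted_coupling(5, 40, "A", "W", 0.2)),
                         seed = 1)
  aln <- generate_msa(spec)
  net <- build_network(aln, tr_min = 0.1, p_max = 0.01)
  hit <- net$stats[net$stats$i == 5 & net$stats$j == 40 &
                     net$stats$a == "A" & net$stats$b == "W", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$residual, 0.2, tolerance = 0.05)
  ## every record satisfies all thresholds
  expect_true(all(net$stats$residual >= 0.1))
  expect_true(all(net$stats$p_value <= 0.01))
  ## one record per (i, a, j, b)
  expect_false(anyDuplicated(net$stats[c("i", "j", "a", "b")]) > 0)
  ## the residual bound makes tr_min > 0.25 unsatisfiable
  expect_error(build_network(aln, tr_min = 0.26), "0.25")
  expect_equal(nrow(build_network(aln, tr_min = 0.25, p_max = 1)$stats), 0)
})

test_that("raising tr_min or lowering p_max never adds records", {
  spec <- synthetic_spec(30, 25, concentration = 0.4, seed = 23)
  aln <- generate_msa(spec)
  key <- function(net) do.call(paste, net$stats[c("i", "j", "a", "b")])
  loose <- build_network(aln, tr_min = 0.1, p_max = 0.2)
  for (tr in c(0.12, 0.18)) {
    for (p in c(0.01, 0.1)) {
      tight <- build_network(aln, tr_min = tr, p_max = p)
      expect_true(all(key(tight) %in% key(loose)))
    }
  }
})

test_that("signed filtering admits negative residuals, BH only shrinks", {
  ## avoidance pattern: A at 1 never co-occurs with E at 2, so (A, E) has
  ## the maximal negative residual -0.25
  aln <- toy_alignment(rep(c("AD", "CE"), each = 6))
  pos <- build_network(aln, tr_min = 0.2, p_max = 1, min_count = 0)
  sgn <- build_network(aln, tr_min = 0.2, p_max = 1, signed = TRUE,
                       min_count = 0)
  expect_true(all(pos$stats$residual >= 0.2))
  expect_gt(nrow(sgn$stats), nrow(pos$stats))
  neg <- sgn$stats[sgn$stats$residual < 0, ]
  expect_true(all(c("A", "C") %in% neg$a))
  expect_true(any(neg$residual == -0.25))

  spec <- synthetic_spec(40, 20, concentration = 0.4, seed = 31)
  rand <- generate_msa(spec)
  bh <- build_network(rand, tr_min = 0.08, p_max = 0.05, p_adjust = "BH")
  raw <- build_network(rand, tr_min = 0.08, p_max = 0.05)
  expect_lte(nrow(bh$stats), nrow(raw$stats))
})

test_that("edge tables round-trip through TSV", {
  spec <- synthetic_spec(80, 15, concentration = 0.4, seed = 41)
  aln <- generate_msa(spec)
  net <- build_network(aln, tr_min = 0.05, p_max = 0.5)
  expect_gt(nrow(net$stats), 0)
  path <- tempfile(fileext = ".tsv")
  write_edges(net, path)
  back <- read_edges(path)
  expect_equal(back$i, net$stats$i)
  expect_equal(back$residual, net$stats$residual, tolerance = 1e-9)
  expect_equal(back$p_value, net$stats$p_value, tolerance = 1e-9)
  ## 1-based contract is stated in the header
  expect_true(any(grepl("1-based", readLines(path)[1:2])))
})

test_that("threshold presets expose the documented ladder", {
  expect_equal(threshold_preset("adk_p1"), list(tr_min = 0.15, p_max = 0.1))
  expect_equal(threshold_preset("x8"), list(tr_min = 0.1, p_max = 0.001))
  ladder <- sapply(c("adk_p005", "adk_p01", "adk_p05", "adk_p1"),
                   function(nm) threshold_preset(nm)$p_max)
  expect_true(all(diff(ladder) > 0))
})
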