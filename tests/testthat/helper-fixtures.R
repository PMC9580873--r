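## Shared fixtures and independent oracles for the test suite.
## Oracles here are deliberately naive (loops, exhaustive enumeration) and
## never call the package code paths they check.

toy_alignment <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  coev_alignment(ids, rows)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## brute-force joint tally: single pass over raw rows with substr
oracle_joint_tally <- function(aln, i, j, gap_mode = "state") {
  counts <- matrix(0L, 21, 21, dimnames = list(AA_STATES, AA_STATES))
  for (r in seq_len(aln$n)) {
    a <- substr(aln$rows[r], i, i)
    b <- substr(aln$rows[r], j, j)
    if (a == "X" || b == "X") next
    if (gap_mode == "exclude" && (a == "-" || b == "-")) next
    counts[a, b] <- counts[a, b] + 1L
  }
  counts
}

## exhaustive two-sided Fisher p for a 2x2 with cell x11 and margins r1, c1
oracle_fisher_p <- function(x11, r1, c1, n) {
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1.0)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  pk <- stats::dhyper(k, c1, n - c1, r1)
  pobs <- stats::dhyper(x11, c1, n - c1, r1)
  sum(pk[pk <= pobs * (1 + 1e-7)])
}

## random joint table: multinomial counts over a sparse random cell set
random_joint_table <- function(seed) {
  set.seed(seed)
  n <- sample(5:300, 1)
  k <- sample(2:12, 1)
  cells <- sample(441, k)
  prob <- as.vector(stats::rmultinom(1, n, rep(1 / k, k)))
  counts <- matrix(0L, 21, 21, dimnames = list(AA_STATES, AA_STATES))
  counts[cells] <- prob
  structure(list(i = 1L, j = 2L, counts = counts, n = n,
                 gap_mode = "state"),
            class = "coev_joint")
}

## brute-force per-separation distance statistics via a double loop
oracle_baseline <- function(model) {
  xyz <- as.matrix(model$residues[, c("x", "y", "z")])
  n <- nrow(xyz)
  acc <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (anyNA(xyz[a, ]) || anyNA(xyz[b, ])) next
      s <- b - a
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      acc[[as.character(s)]] <- c(acc[[as.character(s)]], d)
    }
  }
  seps <- sort(as.integer(names(acc)))
  data.frame(separation = seps,
             n_pairs = vapply(as.character(seps), function(k) length(acc[[k]]), 1L),
             mean = vapply(as.character(seps), function(k) mean(acc[[k]]), 1),
             sd = vapply(as.character(seps), function(k)
               if (length(acc[[k]]) > 1) stats::sd(acc[[k]]) else 0, 1),
             row.names = NULL)
}

## brute-force cloud detection: BFS over the eps-neighborhood graph
oracle_clouds <- function(stats_df, eps, min_edges, metric = "chebyshev") {
  k <- nrow(stats_df)
  comp <- rep(NA_integer_, k)
  cid <- 0L
  for (start in seq_len(k)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in seq_len(k)) {
        if (!is.na(comp[w])) next
        dd <- if (metric == "chebyshev")
          max(abs(stats_df$i[v] - stats_df$i[w]), abs(stats_df$j[v] - stats_df$j[w]))
        else sqrt((stats_df$i[v] - stats_df$i[w])^2 + (stats_df$j[v] - stats_df$j[w])^2)
        if (dd <= eps) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= min_edges])
  lapply(keep, function(cc) sort(which(comp == cc)))
}

## minimal synthetic network wrapper for layout/cloud tests
make_network <- function(stats_df, L, tr_min = 0.1, p_max = 0.1,
                         profiles = NULL) {
  if (is.null(profiles)) {
    freq <- matrix(0, 21, L, dimnames = list(AA_STATES, NULL))
    freq["A", ] <- 1
    for (r in seq_len(nrow(stats_df))) {
      freq[stats_df$a[r], stats_df$i[r]] <- 0.5
      freq[stats_df$b[r], stats_df$j[r]] <- 0.5
      freq["A", stats_df$i[r]] <- 0.5
      freq["A", stats_df$j[r]] <- 0.5
    }
    profiles <- list(frequencies = freq, n_counted = rep(10L, L),
                     gap_mode = "state")
  }
  structure(list(stats = stats_df, profiles = profiles,
                 thresholds = list(tr_min = tr_min, p_max = p_max,
                                   min_count = 2L),
                 provenance = list(alignment = "fixture", gap_mode = "state",
                                   method = "fisher", signed = FALSE,
                                   p_adjust = "none", n_sequences = 10L),
                 L = L),
            class = "coev_network")
}

edge_stats_df <- function(i, j, a = "A", b = "A", residual = 0.15,
                          p_value = 0.01, n = 10L) {
  k <- length(i)
  data.frame(i = i, j = j, a = rep_len(a, k), b = rep_len(b, k),
             n = rep_len(n, k), f_ab = rep_len(residual + 0.25, k),
             f_a = rep_len(0.5, k), f_b = rep_len(0.5, k),
             residual = rep_len(residual, k),
             p_value = rep_len(p_value, k),
             stringsAsFactors = FALSE)
}
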