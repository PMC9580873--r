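#' Joint residue counts for a pair of alignment columns
#'
#' Tabulates, over the sequences of the family, how often each pair of
#' residue identities `(a at i, b at j)` co-occurs. In `gap_mode =
#' "exclude"` rows gapped at either column are dropped; in `"state"` the
#' gap is an ordinary 21st state. Rows with `X` at either column are
#' always dropped, so marginals derived from the table are complete-case.
#'
#' @param aln a `coev_alignment`.
#' @param i,j column indices, `i < j` (1-based).
#' @param gap_mode `"state"` or `"exclude"`.
#' @return A list of class `coev_joint`: `i`, `j`, `counts` (21 x 21
#'   integer matrix over [AA_STATES]), `n` (sequences counted), `gap_mode`.
#' @export
joint_table <- function(aln, i, j, gap_mode = c("state", "exclude")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(aln, "coev_alignment"))
  if (i >= j) stop("need i < j (got i = ", i, ", j = ", j, ")", call. = FALSE)
  if (i < 1L || j > aln$L) {
    stop("column indices out of range 1..", aln$L, call. = FALSE)
  }
  ci <- match(substr(aln$rows, i, i), AA_STATES)
  cj <- match(substr(aln$rows, j, j), AA_STATES)
  joint_table_codes(ci, cj, i, j, gap_mode)
}

## core tally on pre-encoded column codes (NA = excluded ambiguity)
joint_table_codes <- function(ci, cj, i, j, gap_mode) {
  keep <- !is.na(ci) & !is.na(cj)
  if (gap_mode == "exclude") keep <- keep & ci != GAP_CODE & cj != GAP_CODE
  ci <- ci[keep]; cj <- cj[keep]
  counts <- matrix(tabulate(ci + 21L * (cj - 1L), nbins = 441L),
                   nrow = 21L, ncol = 21L,
                   dimnames = list(AA_STATES, AA_STATES))
  structure(list(i = as.integer(i), j = as.integer(j), counts = counts,
                 n = length(ci), gap_mode = gap_mode),
            class = "coev_joint")
}

## residual matrix: observed joint fraction minus product of marginals,
## both taken from the same complete-case table
residual_matrix <- function(table) {
  if (table$n == 0L) stop("empty joint table (n = 0)", call. = FALSE)
  f_ab <- table$counts / table$n
  f_a <- rowSums(f_ab)
  f_b <- colSums(f_ab)
  f_ab - outer(f_a, f_b)
}

#' Identity-pair residuals of a joint table
#'
#' For every identity pair `(a, b)` with nonzero observed or expected
#' fraction, returns the residual `f_ab - f_a * f_b`: the unexpected
#' fraction of the family sharing residue `a` at position `i` and `b` at
#' position `j`, relative to independence of the two positions. The
#' residual is bounded in `[-0.25, 0.25]` and sums to zero over the table.
#' Significance is not computed here; see [pair_significance()].
#'
#' @param table a `coev_joint` from [joint_table()].
#' @return A data frame with columns `i`, `j`, `a`, `b`, `n`, `f_ab`,
#'   `f_a`, `f_b`, `residual`, `p_value` (all `NA` here).
#' @export
residuals_table <- function(table) {
  stopifnot(inherits(table, "coev_joint"))
  res <- residual_matrix(table)
  f_ab <- table$counts / table$n
  f_a <- rowSums(f_ab)
  f_b <- colSums(f_ab)
  expected <- outer(f_a, f_b)
  keep <- which(f_ab > 0 | expected > 0, arr.ind = TRUE)
  keep <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
  data.frame(
    i = table$i, j = table$j,
    a = AA_STATES[keep[, 1L]], b = AA_STATES[keep[, 2L]],
    n = table$n,
    f_ab = f_ab[keep], f_a = f_a[keep[, 1L]], f_b = f_b[keep[, 2L]],
    residual = res[keep],
    p_value = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Significance of one identity pair
#'
#' Collapses the 21 x 21 joint table to the 2 x 2 table (has `a` at `i` vs.
#' not) x (has `b` at `j` vs. not) and returns a two-sided p-value: Fisher's
#' exact test (default) or chi-squared without continuity correction.
#' Degenerate margins (identity absent or universal at its column) admit
#' only one table, so the p-value is 1 and the result carries attribute
#' `degenerate = TRUE` rather than raising an error.
#'
#' @param table a `coev_joint`.
#' @param a,b residue identities (one-letter, `"-"` allowed in gap-as-state
#'   tables).
#' @param method `"fisher"` or `"chi2"`.
#' @return A p-value in `[0, 1]`, possibly with attribute `degenerate`.
#' @export
pair_significance <- function(table, a, b, method = c("fisher", "chi2")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "coev_joint"))
  ia <- match(a, AA_STATES)
  ib <- match(b, AA_STATES)
  if (is.na(ia) || is.na(ib)) {
    stop("identities must be one of: ", paste(AA_STATES, collapse = " "),
         call. = FALSE)
  }
  x11 <- table$counts[ia, ib]
  r1 <- sum(table$counts[ia, ])
  c1 <- sum(table$counts[, ib])
  n <- table$n
  p2x2(x11, r1, c1, n, method)
}

## two-sided p for the 2x2 with cell x11, margins r1 (row), c1 (col), total n
p2x2 <- function(x11, r1, c1, n, method) {
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) {
    return(structure(1.0, degenerate = TRUE))
  }
  m <- matrix(c(x11, r1 - x11, c1 - x11, n - r1 - c1 + x11), nrow = 2L)
  if (method == "fisher") {
    stats::fisher.test(m)$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }
}

#' Size of the identity-pair search space
#'
#' The number of (unordered position pair, identity pair) combinations a
#' family of `L` positions over an alphabet of `A` identities offers:
#' `choose(L, 2) * A^2`. For a typical 300-residue protein over the 20
#' amino acids plus gap this is 19,778,850 — the "almost 20 million"
#' potentially important interdependencies a co-evolution analysis has to
#' sift.
#'
#' @param L number of positions (`>= 2`).
#' @param A alphabet size (default 21: 20 amino acids + gap).
#' @return The count, as a double.
#' @export
pair_space_size <- function(L, A = 21) {
  if (L < 2) stop("need L >= 2 positions", call. = FALSE)
  if (A < 1) stop("need alphabet size A >= 1", call. = FALSE)
  choose(L, 2) * A^2
}

#' Threshold presets
#'
#' Named residual/significance threshold pairs covering the filter ladders
#' used for the families this method was developed on: `adk_p005`..`adk_p1`
#' hold the residual threshold at 0.15 while relaxing significance through
#' 0.005, 0.01, 0.05, 0.1 (the ladder on which visually salient clouds of
#' weak co-evolution emerge); `gelsolin` (0.12, 0.05), `x8` (0.1, 0.001)
#' and `pii` (0.11, 0.005) are the per-family settings used for structural
#' validation.
#'
#' @param name preset name.
#' @return A list with `tr_min` and `p_max`.
#' @export
threshold_preset <- function(name = c("adk_p005", "adk_p01", "adk_p05", "adk_p1",
                                      "gelsolin", "x8", "pii")) {
  name <- match.arg(name)
  presets <- list(
    adk_p005 = list(tr_min = 0.15, p_max = 0.005),
    adk_p01 = list(tr_min = 0.15, p_max = 0.01),
    adk_p05 = list(tr_min = 0.15, p_max = 0.05),
    adk_p1 = list(tr_min = 0.15, p_max = 0.1),
    gelsolin = list(tr_min = 0.12, p_max = 0.05),
    x8 = list(tr_min = 0.1, p_max = 0.001),
    pii = list(tr_min = 0.11, p_max = 0.005)
  )
  presets[[name]]
}

#' Build a threshold-filtered co-evolution network
#'
#' Scans every column pair `i < j` of the alignment, computes identity-pair
#' residuals, and retains records passing all three filters: residual at
#' least `tr_min` (by default positive-only, co-occurrence above
#' expectation; `signed = TRUE` admits `|residual| >= tr_min`), observed
#' count at least `min_count`, and two-sided significance at most `p_max`.
#' Significance is only computed for cells passing the residual and count
#' prefilters, which keeps full-length families tractable.
#'
#' @param aln a `coev_alignment`.
#' @param tr_min residual threshold in `[0, 0.25]`.
#' @param p_max significance threshold in `(0, 1]`.
#' @param min_count minimum observed co-occurrence count (default 2).
#' @param gap_mode `"state"` or `"exclude"`.
#' @param method significance test, `"fisher"` (default) or `"chi2"`.
#' @param signed admit negative residuals by absolute value.
#' @param p_adjust `"none"` (default; the method deliberately explores raw
#'   p-values up to 0.1) or `"BH"` for Benjamini-Hochberg over the
#'   prefiltered candidate set.
#' @param name alignment identifier recorded in provenance.
#' @return An object of class `coev_network`: `stats` (data frame of
#'   retained records ordered by `i`, `j`, `a`, `b`), `profiles` (per-column
#'   frequency matrix), `thresholds`, `provenance`, `L`.
#' @export
build_network <- function(aln, tr_min = 0.1, p_max = 0.1, min_count = 2L,
                          gap_mode = c("state", "exclude"),
                          method = c("fisher", "chi2"),
                          signed = FALSE, p_adjust = c("none", "BH"),
                          name = "alignment") {
  gap_mode <- match.arg(gap_mode)
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(aln, "coev_alignment"))
  if (aln$L < 2L) stop("alignment has fewer than 2 columns", call. = FALSE)
  if (tr_min < 0 || tr_min > 0.25) {
    stop("tr_min must lie in [0, 0.25]", call. = FALSE)
  }
  if (p_max <= 0 || p_max > 1) stop("p_max must lie in (0, 1]", call. = FALSE)

  m <- encode_alignment(aln)
  prof <- profile_matrix(aln, gap_mode)
  out <- vector("list", 256L); n_out <- 0L
  for (i in seq_len(aln$L - 1L)) {
    ci_all <- m[, i]
    for (j in seq.int(i + 1L, aln$L)) {
      tab <- joint_table_codes(ci_all, m[, j], i, j, gap_mode)
      if (tab$n == 0L) next
      res <- residual_matrix(tab)
      pass <- if (signed) abs(res) >= tr_min else res >= tr_min
      pass <- pass & tab$counts >= min_count
      if (!any(pass)) next
      idx <- which(pass, arr.ind = TRUE)
      f_ab <- tab$counts / tab$n
      f_a <- rowSums(f_ab); f_b <- colSums(f_ab)
      rows <- data.frame(
        i = i, j = j,
        a = AA_STATES[idx[, 1L]], b = AA_STATES[idx[, 2L]],
        n = tab$n,
        f_ab = f_ab[idx], f_a = f_a[idx[, 1L]], f_b = f_b[idx[, 2L]],
        residual = res[idx],
        p_value = vapply(seq_len(nrow(idx)), function(k) {
          as.numeric(p2x2(tab$counts[idx[k, 1L], idx[k, 2L]],
                          sum(tab$counts[idx[k, 1L], ]),
                          sum(tab$counts[, idx[k, 2L]]),
                          tab$n, method))
        }, numeric(1)),
        stringsAsFactors = FALSE
      )
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- rows
    }
  }
  stats <- if (n_out > 0L) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(i = integer(0), j = integer(0), a = character(0),
               b = character(0), n = integer(0), f_ab = numeric(0),
               f_a = numeric(0), f_b = numeric(0), residual = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  if (p_adjust == "BH" && nrow(stats) > 0L) {
    stats$p_value <- stats::p.adjust(stats$p_value, method = "BH")
  }
  stats <- stats[stats$p_value <= p_max, , drop = FALSE]
  stats <- stats[order(stats$i, stats$j, stats$a, stats$b), , drop = FALSE]
  rownames(stats) <- NULL
  structure(
    list(stats = stats, profiles = prof,
         thresholds = list(tr_min = tr_min, p_max = p_max,
                           min_count = as.integer(min_count)),
         provenance = list(alignment = name, gap_mode = gap_mode,
                           method = method, signed = signed,
                           p_adjust = p_adjust, n_sequences = aln$n),
         L = aln$L),
    class = "coev_network"
  )
}

#' @export
print.coev_network <- function(x, ...) {
  cat("Co-evolution network:", nrow(x$stats), "identity-pair records over",
      x$L, "columns\n")
  cat(sprintf("  thresholds: residual >= %g, p <= %g, count >= %d (%s, %s)\n",
              x$thresholds$tr_min, x$thresholds$p_max, x$thresholds$min_count,
              x$provenance$method, x$provenance$gap_mode))
  if (nrow(x$stats) > 0L) print(utils::head(x$stats, 10L))
  invisible(x)
}

#' Write / read network records as a tab-separated edge table
#'
#' Columns: `i` (1-based), `res_i`, `j` (1-based), `res_j`, `n`, `f_ab`,
#' `f_a`, `f_b`, `residual`, `p_value`. A header comment records the
#' thresholds and states that coordinates are 1-based.
#'
#' @param net a `coev_network`.
#' @param path output path.
#' @return `path` invisibly, or a data frame for `read_edges`.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "coev_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# coevnet edge table; coordinates i, j are 1-based alignment columns",
    sprintf("# thresholds: tr_min=%g p_max=%g min_count=%d gap_mode=%s method=%s",
            net$thresholds$tr_min, net$thresholds$p_max,
            net$thresholds$min_count, net$provenance$gap_mode,
            net$provenance$method),
    paste(c("i", "res_i", "j", "res_j", "n", "f_ab", "f_a", "f_b",
            "residual", "p_value"), collapse = "\t")
  ), con)
  s <- net$stats
  if (nrow(s) > 0L) {
    writeLines(sprintf("%d\t%s\t%d\t%s\t%d\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                       s$i, s$a, s$j, s$b, s$n, s$f_ab, s$f_a, s$f_b,
                       s$residual, s$p_value), con)
  }
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df)[names(df) == "res_i"] <- "a"
  names(df)[names(df) == "res_j"] <- "b"
  df[, c("i", "j", "a", "b", "n", "f_ab", "f_a", "f_b", "residual", "p_value")]
}
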