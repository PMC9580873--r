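#' Read one chain of a PDB structure as a residue model
#'
#' Loads a PDB file through bio3d, keeps the first model's `ATOM` records
#' for the requested chain (waters and heteroatoms excluded, alternate
#' locations resolved to blank/`A`/highest occupancy), and reduces each
#' residue to a single representative atom: the beta-carbon with
#' alpha-carbon fallback (`"cb"`, default — glycine has no beta-carbon) or
#' the alpha-carbon (`"ca"`). Residues lacking the representative atom are
#' retained but marked missing so sequential separations stay correct.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; required when the file has several
#'   chains.
#' @param atom_scheme `"cb"` (beta-carbon, alpha-carbon fallback) or
#'   `"ca"`.
#' @return An object of class `coev_structure`: `chain`, `atom_scheme`,
#'   `residues` (data frame `resno`, `insert`, `resid`, `aa`, `x`, `y`,
#'   `z`, `missing`, ordered by residue number and insertion code; the row
#'   number is the structure sequence index), `sequence` (one-letter).
#' @export
read_structure <- function(path, chain = NULL,
                           atom_scheme = c("cb", "ca")) {
  atom_scheme <- match.arg(atom_scheme)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" &
                   !(atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  chains <- sort(unique(atoms$chain))
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop("file has chains ", paste(chains, collapse = ", "),
           "; pick one with chain=", call. = FALSE)
    }
    chain <- chains[1L]
  }
  if (!chain %in% chains) {
    stop("chain '", chain, "' not present; available: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  ## alternate locations: blank or 'A' preferred, then highest occupancy
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  alt_pref <- ifelse(alt %in% c("", "A"), 0L, 1L)
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  atoms <- atoms[order(atoms$resno, atoms$insert, atoms$elety, alt_pref, -occ),
                 , drop = FALSE]
  atoms <- atoms[!duplicated(atoms[c("resno", "insert", "elety")]), , drop = FALSE]

  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$resno, ins, sep = "|")
  ord_key <- unique(key[order(atoms$resno, ins)])
  rep_atom <- function(k) {
    sel <- atoms[key == k, , drop = FALSE]
    pick <- if (atom_scheme == "cb") {
      w <- which(sel$elety == "CB")
      if (length(w) == 0L) which(sel$elety == "CA") else w
    } else which(sel$elety == "CA")
    if (length(pick) == 0L) NULL else sel[pick[1L], , drop = FALSE]
  }
  res_list <- lapply(ord_key, function(k) {
    sel <- atoms[key == k, , drop = FALSE]
    rep <- rep_atom(k)
    data.frame(resno = sel$resno[1L],
               insert = if (is.na(sel$insert[1L])) "" else sel$insert[1L],
               resid = sel$resid[1L],
               aa = suppressWarnings(bio3d::aa321(sel$resid[1L])),
               x = if (is.null(rep)) NA_real_ else rep$x,
               y = if (is.null(rep)) NA_real_ else rep$y,
               z = if (is.null(rep)) NA_real_ else rep$z,
               missing = is.null(rep),
               stringsAsFactors = FALSE)
  })
  residues <- do.call(rbind, res_list)
  residues$aa[is.na(residues$aa)] <- "X"
  rownames(residues) <- NULL
  structure(list(chain = chain, atom_scheme = atom_scheme,
                 residues = residues,
                 sequence = paste(residues$aa, collapse = "")),
            class = "coev_structure")
}

#' @export
print.coev_structure <- function(x, ...) {
  cat("Structure chain", x$chain, ":", nrow(x$residues), "residues (",
      sum(x$residues$missing), "without", toupper(x$atom_scheme),
      "coordinates )\n")
  invisible(x)
}

#' Construct a column-to-residue map directly
#'
#' The manual-override counterpart of [map_columns()], for cases where the
#' automatic alignment is unavailable or unwanted (e.g. synthetic
#' pipelines where alignment columns are structure positions by
#' construction).
#'
#' @param columns alignment columns (1-based).
#' @param str_index structure sequence indices (row numbers of the model's
#'   residue table), same length as `columns`.
#' @param matched logical vector (recycled) flagging identity-matched
#'   positions.
#' @param row_id,identity provenance metadata.
#' @return An object of class `coev_colmap`.
#' @export
column_residue_map <- function(columns, str_index, matched = TRUE,
                               row_id = "manual", identity = NA_real_) {
  if (length(columns) != length(str_index)) {
    stop("columns and str_index must have the same length", call. = FALSE)
  }
  if (anyDuplicated(columns) || anyDuplicated(str_index)) {
    stop("column-to-residue mapping must be injective", call. = FALSE)
  }
  ord <- order(columns)
  columns <- columns[ord]; str_index <- str_index[ord]
  if (is.unsorted(str_index, strictly = TRUE)) {
    stop("mapped structure indices must be monotone in column order",
         call. = FALSE)
  }
  structure(list(row_id = row_id, identity = identity,
                 n_aligned = length(columns),
                 mapping = data.frame(column = as.integer(columns),
                                      str_index = as.integer(str_index),
                                      matched = rep_len(matched,
                                                        length(columns)))),
            class = "coev_colmap")
}

#' Map alignment columns onto structure residues
#'
#' Globally aligns the ungapped sequence of one family member against the
#' structure's one-letter sequence (Needleman-Wunsch, BLOSUM62) and maps
#' alignment columns to structure sequence indices through the matched
#' positions. Mismatched (substituted) positions are mapped but flagged.
#' An identity fraction below `min_identity` aborts with advice to build
#' the map manually via [column_residue_map()].
#'
#' @param aln a `coev_alignment`.
#' @param row_id identifier of the alignment row to map through.
#' @param model a `coev_structure`.
#' @param min_identity identity floor over aligned positions (default 0.9).
#' @return A `coev_colmap`: `row_id`, `identity`, `n_aligned`, `mapping`
#'   (data frame `column`, `str_index`, `matched`).
#' @export
map_columns <- function(aln, row_id, model, min_identity = 0.9) {
  stopifnot(inherits(aln, "coev_alignment"), inherits(model, "coev_structure"))
  ridx <- match(row_id, aln$ids)
  if (is.na(ridx)) stop("row '", row_id, "' not in alignment", call. = FALSE)
  chars <- strsplit(aln$rows[ridx], "")[[1]]
  cols <- which(chars != "-")
  if (length(cols) == 0L) stop("row '", row_id, "' is all gaps", call. = FALSE)
  rowseq <- paste(chars[cols], collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rowseq), Biostrings::AAString(model$sequence),
    type = "global", substitutionMatrix = get("BLOSUM62"),
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pi_ <- cumsum(pa != "-")
  si <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  identity <- if (any(both)) mean(pa[both] == sa[both]) else 0
  if (identity == 0 && min_identity <= 0) {
    stop("row and structure sequences share no aligned positions",
         call. = FALSE)
  }
  if (identity < min_identity) {
    stop(sprintf(paste0("row-to-structure identity %.3f is below the %.2f floor; ",
                        "check the row/chain or build the map manually with ",
                        "column_residue_map()"), identity, min_identity),
         call. = FALSE)
  }
  mapping <- data.frame(column = cols[pi_[both]],
                        str_index = si[both],
                        matched = pa[both] == sa[both])
  structure(list(row_id = row_id, identity = identity,
                 n_aligned = sum(both), mapping = mapping),
            class = "coev_colmap")
}

coords_matrix <- function(model) {
  as.matrix(model$residues[, c("x", "y", "z")])
}

#' Expected inter-residue distance per sequential separation
#'
#' For every sequential separation `s >= 1` present in the chain, computes
#' summary statistics of the representative-atom distance over all residue
#' pairs `(k, k+s)` with both coordinates present. The per-separation mean
#' is the expected distance a selected pair is compared against: residues
#' far apart in sequence are usually far apart in space, so "close" is
#' only meaningful relative to pairs of the same separation.
#'
#' @param model a `coev_structure` with at least 2 placed residues.
#' @return An object of class `coev_baseline`: a data frame with columns
#'   `separation`, `n_pairs`, `mean`, `sd`, `p5`, `p50`, `p95`, plus
#'   attributes `atom_scheme`, `chain`, `n_res`.
#' @export
separation_baseline <- function(model) {
  stopifnot(inherits(model, "coev_structure"))
  xyz <- coords_matrix(model)
  n <- nrow(xyz)
  if (sum(stats::complete.cases(xyz)) < 2L) {
    stop("fewer than 2 residues with coordinates", call. = FALSE)
  }
  rows <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    a <- xyz[seq_len(n - s), , drop = FALSE]
    b <- xyz[seq_len(n - s) + s, , drop = FALSE]
    d <- sqrt(rowSums((a - b)^2))
    d <- d[!is.na(d)]
    if (length(d) == 0L) next
    q <- stats::quantile(d, c(0.05, 0.5, 0.95), names = FALSE)
    rows[[s]] <- data.frame(separation = s, n_pairs = length(d),
                            mean = mean(d),
                            sd = if (length(d) > 1L) stats::sd(d) else 0,
                            p5 = q[1L], p50 = q[2L], p95 = q[3L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("coev_baseline", "data.frame"),
            atom_scheme = model$atom_scheme, chain = model$chain,
            n_res = n)
}

#' Evaluate selected residue pairs against the distance baseline
#'
#' Maps each selected alignment-column pair onto structure residues,
#' measures its representative-atom distance, and compares it to the
#' expected distance for its sequential separation (separation is measured
#' in structure sequence indices after mapping, not alignment-column
#' offset, so alignment gaps do not distort it). A pair is
#' closer-than-expected when its distance is strictly below the baseline
#' value; ties count as not closer. Pairs whose columns are unmapped or
#' whose residues lack coordinates are reported but excluded from the
#' evaluated count — a structure usually resolves fewer residues than the
#' family alignment covers.
#'
#' @param pairs a data frame (or 2-column matrix) of 1-based alignment
#'   column pairs `i < j`.
#' @param map a `coev_colmap` for the structure's family member.
#' @param model the `coev_structure` the baseline was computed from.
#' @param baseline a `coev_baseline` from [separation_baseline()] on the
#'   same model and atom scheme.
#' @param expected which baseline statistic defines the expected distance:
#'   `"mean"` (default) or `"median"`.
#' @return An object of class `coev_pair_report`: `pairs` (per-pair data
#'   frame with `i`, `j`, `str_i`, `str_j`, `separation`, `distance`,
#'   `expected`, `closer`, `status`) and aggregates `n_evaluated`,
#'   `n_closer`, `n_unmapped`.
#' @export
evaluate_pairs <- function(pairs, map, model, baseline,
                           expected = c("mean", "median")) {
  expected <- match.arg(expected)
  stopifnot(inherits(map, "coev_colmap"), inherits(model, "coev_structure"),
            inherits(baseline, "coev_baseline"))
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) {
    if (nrow(pairs) == 0L) {
      pairs <- data.frame(i = integer(0), j = integer(0))
    } else stop("pairs needs two columns (i, j)", call. = FALSE)
  }
  names(pairs)[1:2] <- c("i", "j")
  exp_col <- if (expected == "mean") "mean" else "p50"
  xyz <- coords_matrix(model)
  lookup <- function(col) map$mapping$str_index[match(col, map$mapping$column)]
  si <- lookup(pairs$i); sj <- lookup(pairs$j)
  np <- nrow(pairs)
  out <- data.frame(i = pairs$i, j = pairs$j, str_i = si, str_j = sj,
                    separation = rep(NA_integer_, np),
                    distance = rep(NA_real_, np),
                    expected = rep(NA_real_, np), closer = rep(NA, np),
                    status = rep("ok", np), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    if (is.na(si[k]) || is.na(sj[k])) { out$status[k] <- "unmapped"; next }
    if (model$residues$missing[si[k]] || model$residues$missing[sj[k]]) {
      out$status[k] <- "missing"; next
    }
    s <- abs(sj[k] - si[k])
    d <- sqrt(sum((xyz[si[k], ] - xyz[sj[k], ])^2))
    e <- baseline[[exp_col]][match(s, baseline$separation)]
    out$separation[k] <- s
    out$distance[k] <- d
    out$expected[k] <- e
    out$closer[k] <- !is.na(e) && d < e
  }
  ok <- out$status == "ok"
  structure(list(pairs = out,
                 n_evaluated = sum(ok),
                 n_closer = sum(out$closer[ok]),
                 n_unmapped = sum(!ok),
                 expected_stat = expected),
            class = "coev_pair_report")
}

#' @export
print.coev_pair_report <- function(x, ...) {
  cat("Pair distance report:", x$n_closer, "of", x$n_evaluated,
      "evaluated pairs closer than the expected distance for their",
      "separation;", x$n_unmapped, "pairs unmapped or unresolved\n")
  invisible(x)
}

#' Minimum inter-residue distance across the chains of an assembly
#'
#' For oligomeric proteins, co-evolution statistics cannot tell whether a
#' coupling acts within one subunit or between neighboring subunits: the
#' family alignment sees only the monomer sequence. Given the assembly's
#' chains, this computes the representative-atom distance of a residue
#' pair under every ordered chain assignment (residue 1 in chain X,
#' residue 2 in chain Y; X = Y included for the intra-chain reference) and
#' returns the minimum with the assignment that achieves it.
#'
#' @param models list of `coev_structure` chains (at least 2) with the
#'   same residue indexing (identical subunits).
#' @param pair integer pair of structure sequence indices.
#' @return A list: `distance` (Å, `NA` if nowhere computable), `chain_i`,
#'   `chain_j`, `type` (`"intra"`/`"inter"`), `assignments` (data frame of
#'   all chain assignments with distances; unresolved ones `NA`),
#'   `n_missing` (assignments skipped for missing coordinates).
#' @export
interchain_min_distance <- function(models, pair) {
  if (length(models) < 2L) stop("need at least 2 chains", call. = FALSE)
  if (length(pair) != 2L) stop("pair must be two residue indices", call. = FALSE)
  labels <- vapply(models, function(m) m$chain, character(1))
  if (anyDuplicated(labels)) labels <- paste0(labels, ".", seq_along(models))
  grid <- expand.grid(ci = seq_along(models), cj = seq_along(models))
  d <- vapply(seq_len(nrow(grid)), function(k) {
    m1 <- models[[grid$ci[k]]]; m2 <- models[[grid$cj[k]]]
    r1 <- pair[1L]; r2 <- pair[2L]
    if (r1 > nrow(m1$residues) || r2 > nrow(m2$residues)) return(NA_real_)
    if (m1$residues$missing[r1] || m2$residues$missing[r2]) return(NA_real_)
    sqrt(sum((unlist(m1$residues[r1, c("x", "y", "z")]) -
                unlist(m2$residues[r2, c("x", "y", "z")]))^2))
  }, numeric(1))
  assignments <- data.frame(chain_i = labels[grid$ci],
                            chain_j = labels[grid$cj],
                            distance = d, stringsAsFactors = FALSE)
  if (all(is.na(d))) {
    return(list(distance = NA_real_, chain_i = NA_character_,
                chain_j = NA_character_, type = NA_character_,
                assignments = assignments, n_missing = sum(is.na(d))))
  }
  best <- which.min(d)
  list(distance = d[best],
       chain_i = assignments$chain_i[best],
       chain_j = assignments$chain_j[best],
       type = if (grid$ci[best] == grid$cj[best]) "intra" else "inter",
       assignments = assignments,
       n_missing = sum(is.na(d)))
}

#' Plot selected pairs over the per-separation distance distribution
#'
#' Draws the expected-distance curve with its 5-95 percentile band and
#' overlays the evaluated pairs, filled when closer than expected.
#'
#' @param baseline a `coev_baseline`.
#' @param report optional `coev_pair_report` to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot_pair_distances <- function(baseline, report = NULL, ...) {
  graphics::plot(baseline$separation, baseline$mean, type = "n",
                 xlab = "sequential separation |i - j| (residues)",
                 ylab = "inter-residue distance (Å)",
                 ylim = c(0, max(baseline$p95)), ...)
  graphics::polygon(c(baseline$separation, rev(baseline$separation)),
                    c(baseline$p5, rev(baseline$p95)),
                    col = "grey90", border = NA)
  graphics::lines(baseline$separation, baseline$mean, lwd = 2)
  if (!is.null(report)) {
    p <- report$pairs[report$pairs$status == "ok", , drop = FALSE]
    graphics::points(p$separation, p$distance,
                     pch = ifelse(p$closer, 19, 1), col = "#cc3311")
  }
  invisible(baseline)
}
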