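#' Amino-acid alphabet used throughout the package
#'
#' `AA20` is the canonical 20-letter amino-acid alphabet in alphabetical
#' one-letter order; `AA_STATES` appends the gap character `"-"` as a 21st
#' state. All frequency profiles and joint tables are indexed by
#' `AA_STATES`. Ambiguity and non-canonical codes (`B`, `Z`, `J`, `U`, `O`,
#' anything else) are normalized to `"X"` on input and carry no identity
#' information: rows holding `X` at a position are excluded from that
#' column's counts.
#'
#' @format Character vectors of length 20 and 21.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA20
#' @export
AA_STATES <- c(AA20, "-")

GAP_CODE <- 21L

## normalize a character vector of aligned rows to the package alphabet:
## uppercase, '.' -> '-', non-canonical letters -> 'X'
normalize_rows <- function(rows, strict = FALSE) {
  rows <- toupper(chartr(".", "-", rows))
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "X-]"), "", rows)
  if (any(nchar(bad) > 0)) {
    offending <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    if (strict) {
      stop("alignment contains characters outside the 20+gap alphabet: ",
           paste(offending, collapse = " "), call. = FALSE)
    }
    for (ch in offending) rows <- gsub(ch, "X", rows, fixed = TRUE)
  }
  rows
}

#' Construct a multiple sequence alignment object
#'
#' An alignment is an ordered set of equal-length rows over the 20
#' amino acids, the gap character `-`, and `X` for normalized ambiguity
#' codes. This is the container every statistic in the package is computed
#' from.
#'
#' @param ids character vector of sequence identifiers.
#' @param rows character vector of aligned rows, same length as `ids`.
#' @param strict if `TRUE`, characters outside the alphabet raise an error
#'   instead of being normalized to `X`.
#' @return An object of class `coev_alignment` with elements `ids`, `rows`,
#'   `n` (sequences) and `L` (columns).
#' @export
coev_alignment <- function(ids, rows, strict = FALSE) {
  if (length(ids) != length(rows)) {
    stop("ids and rows must have the same length", call. = FALSE)
  }
  if (length(rows) < 2L) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    ref <- widths[1L]
    bad <- ids[widths != ref][1L]
    stop("ragged alignment: sequence '", bad, "' has length ",
         widths[widths != ref][1L], ", expected ", ref, call. = FALSE)
  }
  if (widths[1L] < 2L) {
    stop("an alignment needs at least 2 columns", call. = FALSE)
  }
  rows <- normalize_rows(rows, strict = strict)
  structure(
    list(ids = as.character(ids), rows = rows,
         n = length(rows), L = widths[1L]),
    class = "coev_alignment"
  )
}

#' @export
print.coev_alignment <- function(x, ...) {
  cat("Multiple sequence alignment:", x$n, "sequences x", x$L, "columns\n")
  show <- utils::head(seq_len(x$n), 6L)
  w <- min(x$L, 60L)
  for (k in show) {
    cat(sprintf("  %-20s %s%s\n", substr(x$ids[k], 1, 20),
                substr(x$rows[k], 1, w), if (x$L > w) "..." else ""))
  }
  if (x$n > 6L) cat("  ...", x$n - 6L, "more\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm (Pfam seed dialect). Rows are
#' normalized: letters uppercased, `.` mapped to `-`, non-canonical letters
#' mapped to `X`. Record order is preserved.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"`, `"stockholm"`, or `"auto"` (sniff the first
#'   non-blank line).
#' @param drop_insert_columns Stockholm only: if `TRUE` and a `#=GC RF`
#'   reference annotation is present, columns marked as insert states
#'   (`.` or lowercase in RF) are dropped. By default insert columns are
#'   retained as ordinary columns.
#' @param strict passed to [coev_alignment()].
#' @return A `coev_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm"),
                           drop_insert_columns = FALSE, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    format <- if (grepl("^# STOCKHOLM", first[1L])) "stockholm"
              else if (startsWith(first[1L], ">")) "fasta"
              else stop("cannot identify alignment format of ", path, call. = FALSE)
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(set))
    rows <- unname(as.character(set))
  } else {
    parsed <- parse_stockholm(path, drop_insert_columns = drop_insert_columns)
    ids <- parsed$ids
    rows <- parsed$rows
  }
  coev_alignment(ids, rows, strict = strict)
}

## Tolerant Stockholm reader for the Pfam seed dialect: '#' lines are
## markup, sequence lines may be split over several blocks, '//' ends the
## entry. Handles interleaved #=GR/#=GC markup that stricter readers reject.
parse_stockholm <- function(path, drop_insert_columns = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  if (!grepl("^# STOCKHOLM", lines[1L])) {
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
         call. = FALSE)
  }
  rf <- character(0)
  seqs <- list()
  order <- character(0)
  for (ln in lines[-1L]) {
    if (startsWith(ln, "//")) break
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+RF\\s", ln)) {
        rf <- c(rf, sub("^#=GC\\s+RF\\s+", "", ln))
      }
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop("malformed Stockholm sequence line: '", ln, "'", call. = FALSE)
    }
    id <- parts[1L]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[2L]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[2L])
    }
  }
  if (length(seqs) == 0L) stop("no sequences in Stockholm file: ", path,
                               call. = FALSE)
  rows <- unlist(seqs[order], use.names = FALSE)
  if (drop_insert_columns && length(rf) > 0L) {
    rf <- paste(rf, collapse = "")
    keep <- which(strsplit(rf, "")[[1]] %in% c(LETTERS, "x"))
    rows <- vapply(strsplit(rows, ""), function(ch)
      paste(ch[keep], collapse = ""), character(1))
  }
  list(ids = order, rows = rows)
}

#' Write an alignment as normalized aligned FASTA
#'
#' @param aln a `coev_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "coev_alignment"))
  set <- Biostrings::BStringSet(stats::setNames(aln$rows, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## integer encoding of the alignment: n x L matrix with codes 1..21
## (AA_STATES order) and NA for 'X' (excluded from all counts)
encode_alignment <- function(aln) {
  m <- matrix(match(unlist(strsplit(aln$rows, ""), use.names = FALSE),
                    AA_STATES),
              nrow = aln$n, ncol = aln$L, byrow = TRUE)
  m
}

#' Per-column residue frequency profile
#'
#' Computes the residue distribution of one alignment column — one column
#' of the family's position-specific scoring matrix. In `gap_mode =
#' "state"` the gap is counted as a 21st state; in `"exclude"` rows gapped
#' at the column are dropped. Rows with `X` at the column are excluded from
#' the counts in both modes.
#'
#' @param aln a `coev_alignment`.
#' @param k column index (1-based).
#' @param gap_mode `"state"` or `"exclude"`.
#' @return A list of class `coev_profile`: `column`, `frequencies` (named
#'   over [AA_STATES], summing to 1 over the counted states), `n_counted`.
#' @export
column_profile <- function(aln, k, gap_mode = c("state", "exclude")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(aln, "coev_alignment"))
  if (length(k) != 1L || k < 1L || k > aln$L) {
    stop("column index k = ", k, " out of range 1..", aln$L, call. = FALSE)
  }
  codes <- match(substr(aln$rows, k, k), AA_STATES)
  codes <- codes[!is.na(codes)]
  if (gap_mode == "exclude") codes <- codes[codes != GAP_CODE]
  counts <- tabulate(codes, nbins = 21L)
  n <- length(codes)
  freq <- if (n > 0L) counts / n else rep(0, 21L)
  names(freq) <- AA_STATES
  structure(list(column = as.integer(k), frequencies = freq,
                 n_counted = n, gap_mode = gap_mode),
            class = "coev_profile")
}

## 21 x L matrix of per-column frequencies (rows AA_STATES), plus counts
profile_matrix <- function(aln, gap_mode = c("state", "exclude")) {
  gap_mode <- match.arg(gap_mode)
  m <- encode_alignment(aln)
  freq <- matrix(0, nrow = 21L, ncol = aln$L,
                 dimnames = list(AA_STATES, NULL))
  n_counted <- integer(aln$L)
  for (k in seq_len(aln$L)) {
    codes <- m[, k]
    codes <- codes[!is.na(codes)]
    if (gap_mode == "exclude") codes <- codes[codes != GAP_CODE]
    n_counted[k] <- length(codes)
    if (length(codes) > 0L) {
      freq[, k] <- tabulate(codes, nbins = 21L) / length(codes)
    }
  }
  list(frequencies = freq, n_counted = n_counted, gap_mode = gap_mode)
}
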