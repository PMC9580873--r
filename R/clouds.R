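#' Construct, load and save "interesting cloud" pair selections
#'
#' A cloud selection is a named list of user-chosen alignment-column pairs
#' — the residue pairs a user recorded as belonging to a visually coherent
#' group of weak co-evolution edges. Selections round-trip through a
#' simple TSV (`i`, `j` and optionally `res_i`, `res_j`, `cloud_name`;
#' 1-based coordinates).
#'
#' @param members data frame with columns `i`, `j` (1-based, `i < j`) and
#'   optionally `res_i`, `res_j`.
#' @param name selection name.
#' @param provenance list recording `source` (`"manual"` or `"detected"`)
#'   and any thresholds/seed used.
#' @return An object of class `coev_selection`.
#' @export
cloud_selection <- function(members, name = "cloud",
                            provenance = list(source = "manual")) {
  members <- as.data.frame(members)
  if (!all(c("i", "j") %in% names(members))) {
    stop("members need columns i and j", call. = FALSE)
  }
  if (!"res_i" %in% names(members)) members$res_i <- NA_character_
  if (!"res_j" %in% names(members)) members$res_j <- NA_character_
  swap <- members$i > members$j
  if (any(swap)) {
    tmp <- members$i[swap]; members$i[swap] <- members$j[swap]
    members$j[swap] <- tmp
    tmp <- members$res_i[swap]; members$res_i[swap] <- members$res_j[swap]
    members$res_j[swap] <- tmp
  }
  if (any(members$i == members$j)) {
    stop("self-pairs (i == j) are not allowed", call. = FALSE)
  }
  key <- paste(members$i, members$j, members$res_i, members$res_j)
  if (anyDuplicated(key)) {
    warning("duplicate selection members collapsed", call. = FALSE)
    members <- members[!duplicated(key), , drop = FALSE]
  }
  members <- members[order(members$i, members$j), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(name = name,
                 members = members[, c("i", "j", "res_i", "res_j")],
                 provenance = provenance),
            class = "coev_selection")
}

#' @rdname cloud_selection
#' @param path TSV path.
#' @export
load_selection <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0L) stop("no rows in selection file: ", path,
                               call. = FALSE)
  header <- strsplit(lines[body[1L]], "\t")[[1]]
  if (!all(c("i", "j") %in% header)) {
    stop("selection file must have header columns i and j: ", path,
         call. = FALSE)
  }
  rows <- lapply(body[-1L], function(ln) {
    parts <- strsplit(lines[ln], "\t")[[1]]
    if (length(parts) != length(header)) {
      stop("malformed selection row at line ", ln, " of ", path,
           " (", length(parts), " fields, expected ", length(header), ")",
           call. = FALSE)
    }
    stats::setNames(as.list(parts), header)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  ij <- suppressWarnings(cbind(as.integer(df$i), as.integer(df$j)))
  bad <- which(is.na(ij[, 1L]) | is.na(ij[, 2L]))
  if (length(bad) > 0L) {
    stop("non-integer coordinates at line ", body[-1L][bad[1L]], " of ",
         path, call. = FALSE)
  }
  df$i <- ij[, 1L]; df$j <- ij[, 2L]
  name <- if ("cloud_name" %in% names(df) && length(unique(df$cloud_name)) == 1L)
    df$cloud_name[1L] else "cloud"
  cloud_selection(df, name = name,
                  provenance = list(source = "manual", path = path))
}

#' @rdname cloud_selection
#' @param sel a `coev_selection`.
#' @export
save_selection <- function(sel, path) {
  stopifnot(inherits(sel, "coev_selection"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# coevnet cloud selection; coordinates are 1-based alignment columns",
               paste(c("i", "j", "res_i", "res_j", "cloud_name"),
                     collapse = "\t")), con)
  m <- sel$members
  writeLines(sprintf("%d\t%d\t%s\t%s\t%s", m$i, m$j,
                     ifelse(is.na(m$res_i), "", m$res_i),
                     ifelse(is.na(m$res_j), "", m$res_j),
                     sel$name), con)
  invisible(path)
}

#' Propose candidate clouds by edge-density clustering (exploratory)
#'
#' The criteria by which users select clouds are not formalized; this
#' detector is an advisory stand-in, never a substitute for manual
#' selection, and its output provenance is marked `detected`. Network
#' records are points in the `(i, j)` column-index plane; records within
#' Chebyshev distance `eps` of each other are neighbors, and connected
#' groups holding at least `min_edges` records are reported as candidate
#' clouds, ordered by total residual.
#'
#' @param net a `coev_network`.
#' @param eps neighborhood radius in column-index units (`>= 1`).
#' @param min_edges minimum records per cloud (`>= 2`).
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return A list of `coev_selection` objects (possibly empty).
#' @export
detect_clouds <- function(net, eps = 3, min_edges = 4,
                          metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(net, "coev_network"))
  if (eps < 1) stop("eps must be >= 1", call. = FALSE)
  if (min_edges < 2) stop("min_edges must be >= 2", call. = FALSE)
  s <- net$stats
  if (nrow(s) == 0L) return(list())
  di <- abs(outer(s$i, s$i, "-"))
  dj <- abs(outer(s$j, s$j, "-"))
  dmat <- if (metric == "chebyshev") pmax(di, dj) else sqrt(di^2 + dj^2)
  g <- igraph::graph_from_adjacency_matrix(dmat <= eps, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_edges)
  if (length(keep) == 0L) return(list())
  clouds <- lapply(keep, function(cid) {
    idx <- which(comp$membership == cid)
    members <- data.frame(i = s$i[idx], j = s$j[idx],
                          res_i = s$a[idx], res_j = s$b[idx],
                          stringsAsFactors = FALSE)
    list(members = members, total_residual = sum(s$residual[idx]))
  })
  ord <- order(vapply(clouds, `[[`, numeric(1), "total_residual"),
               decreasing = TRUE)
  out <- lapply(seq_along(ord), function(k) {
    cl <- clouds[[ord[k]]]
    cloud_selection(cl$members, name = sprintf("cloud_%02d", k),
                    provenance = list(source = "detected", eps = eps,
                                      min_edges = min_edges, metric = metric,
                                      total_residual = cl$total_residual))
  })
  out
}
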