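#' Rendering configuration for the cylindrical layout
#'
#' @param radius cylinder radius in layout length units.
#' @param axial_spacing distance between consecutive residue slots along
#'   the cylinder axis.
#' @param angle_offset angle (radians) of the first column; the N-terminal
#'   marker is drawn here.
#' @param direction `"counterclockwise"` (default; the N-terminal arrow
#'   points in the direction of increasing sequence coordinates) or
#'   `"clockwise"`.
#' @param residue_order axial stacking order of residue sub-nodes; default
#'   alphabetical one-letter order with the gap state last.
#' @param size_scale multiplier on node sizes.
#' @return A list of class `coev_render_config`.
#' @export
render_config <- function(radius = 10, axial_spacing = 1, angle_offset = 0,
                          direction = c("counterclockwise", "clockwise"),
                          residue_order = AA_STATES, size_scale = 1) {
  direction <- match.arg(direction)
  if (!setequal(residue_order, AA_STATES)) {
    stop("residue_order must be a permutation of the 21 states", call. = FALSE)
  }
  structure(list(radius = radius, axial_spacing = axial_spacing,
                 angle_offset = angle_offset, direction = direction,
                 residue_order = residue_order, size_scale = size_scale),
            class = "coev_render_config")
}

node_key <- function(column, residue) {
  if (length(column) == 0L) return(character(0))
  paste0(column, ":", residue)
}

#' Cylindrical radial node-link layout of a co-evolution network
#'
#' Places the family's per-column residue profiles sequentially around the
#' periphery of a cylinder: each column occupies one angular position
#' (consecutive layout ranks are `2*pi/L` apart), and within a column each
#' residue with nonzero frequency becomes a sub-node at a fixed axial slot.
#' Sub-node radius is proportional to the square root of the residue's
#' population fraction, so drawn area encodes frequency. Every network
#' record becomes one edge between its two identity sub-nodes, weighted by
#' its residual.
#'
#' @param net a `coev_network` with at least one column profile.
#' @param config a [render_config()].
#' @param ranks optional integer vector mapping alignment column to layout
#'   rank (`0`-based angular slot); defaults to sequence order. Used by
#'   [randomize_columns()].
#' @return A list of class `coev_scene`: `geometry`, `nodes` (data frame
#'   `key`, `column`, `residue`, `rank`, `angle`, `axial`, `size`,
#'   `frequency`), `edges` (data frame `from`, `to`, `weight`,
#'   `significance`), `n_marker`.
#' @export
cylindrical_layout <- function(net, config = render_config(), ranks = NULL) {
  stopifnot(inherits(net, "coev_network"))
  L <- net$L
  freq <- net$profiles$frequencies
  if (is.null(freq) || ncol(freq) < 1L) {
    stop("network has no column profiles to lay out", call. = FALSE)
  }
  if (is.null(ranks)) ranks <- seq_len(L) - 1L
  if (!identical(sort(as.integer(ranks)), seq_len(L) - 1L)) {
    stop("ranks must be a permutation of 0..L-1", call. = FALSE)
  }
  dir_sign <- if (config$direction == "counterclockwise") 1 else -1
  slot <- match(AA_STATES, config$residue_order) - 1L

  nz <- which(freq > 0, arr.ind = TRUE)  # (state, column)
  col <- nz[, 2L]
  state <- nz[, 1L]
  nodes <- data.frame(
    key = node_key(col, AA_STATES[state]),
    column = col,
    residue = AA_STATES[state],
    rank = ranks[col],
    angle = (config$angle_offset + dir_sign * 2 * pi * ranks[col] / L) %% (2 * pi),
    axial = slot[state] * config$axial_spacing,
    size = config$size_scale * sqrt(freq[nz]),
    frequency = freq[nz],
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$column, match(nodes$residue, config$residue_order)), ]
  rownames(nodes) <- NULL

  s <- net$stats
  edges <- data.frame(
    from = node_key(s$i, s$a),
    to = node_key(s$j, s$b),
    weight = s$residual,
    significance = s$p_value,
    stringsAsFactors = FALSE
  )
  missing_ep <- !(edges$from %in% nodes$key) | !(edges$to %in% nodes$key)
  if (any(missing_ep)) {
    stop("edge endpoints missing from node set: ",
         paste(utils::head(edges$from[missing_ep]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      geometry = list(radius = config$radius,
                      axial_span = (length(AA_STATES) - 1L) * config$axial_spacing,
                      angle_offset = config$angle_offset,
                      direction = config$direction,
                      L = L, tr_min = net$thresholds$tr_min),
      nodes = nodes, edges = edges,
      n_marker = list(angle = config$angle_offset,
                      direction = config$direction)
    ),
    class = "coev_scene"
  )
}

#' @export
print.coev_scene <- function(x, ...) {
  cat("Layout scene:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges on",
      x$geometry$L, "columns (", x$geometry$direction, ")\n")
  invisible(x)
}

## run expr with a private, seeded RNG stream; global stream untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Column-order randomization control
#'
#' Draws a uniformly random bijection of layout ranks from a seeded
#' generator and lays the network out with columns placed at the permuted
#' ranks. This is the visual-salience control: it maintains exactly the
#' same set (number and size) of nodes and the same multiset of edge
#' weights as the unrandomized scene — the statistics are not recomputed —
#' and only the angular placements change. If salient structure survives
#' randomization, it was an artifact of the display rather than of the
#' family.
#'
#' @param net a `coev_network`.
#' @param seed integer seed (mandatory: the control must be reproducible).
#' @param config a [render_config()].
#' @return A list with `permutation` (integer vector: `permutation[rank+1]`
#'   is the alignment column placed at that rank, with attribute `seed`)
#'   and `scene` (the permuted `coev_scene`).
#' @export
randomize_columns <- function(net, seed, config = render_config()) {
  stopifnot(inherits(net, "coev_network"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the randomization control", call. = FALSE)
  }
  L <- net$L
  perm <- with_seed(seed, sample.int(L))  # perm[rank+1] = column at that rank
  ranks <- integer(L)
  ranks[perm] <- seq_len(L) - 1L          # column -> rank
  scene <- cylindrical_layout(net, config, ranks = ranks)
  list(permutation = structure(as.integer(perm), seed = as.integer(seed)),
       scene = scene)
}
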