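#' Build a first-nearest-neighbor graph from channel positions
#'
#' Channel `j` is a neighbor of channel `i` when the distance between them is
#' at most `scale` times the distance from `i` to its single nearest channel;
#' the relation is symmetrized by union. The rule is deterministic and
#' montage-agnostic, and every channel gets at least one neighbor (its
#' nearest channel always qualifies).
#'
#' @param positions channels x 3 numeric matrix (any consistent coordinates).
#' @param scale tolerance multiplier on each channel's nearest distance
#'   (default 1.25, which on a regular grid admits the lattice neighbors and
#'   excludes the diagonals).
#' @return a list of integer vectors, one per channel, of neighbor indices.
#' @examples
#' sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
#' build_neighbor_graph(sq)  # edges only along the square's sides
#' @export
build_neighbor_graph <- function(positions, scale = 1.25) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 channels", call. = FALSE)
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  if (any(d < 1e-12))
    stop("duplicate channel positions", call. = FALSE)
  nearest <- apply(d, 1, min)
  g <- lapply(seq_len(n), function(i)
    unname(which(d[i, ] <= scale * nearest[i])))
  # symmetrize by union
  for (i in seq_len(n)) for (j in g[[i]])
    if (!(i %in% g[[j]])) g[[j]] <- sort(c(g[[j]], i))
  g
}

#' Nearest-neighbor surface Laplacian reference
#'
#' Re-references each channel to its neighborhood: output channel i equals
#' its own value minus the mean of its neighbors' values. A spatial
#' high-pass that suppresses the common reference and far-field activity.
#'
#' @param recording a `session_recording`.
#' @param neighbor_graph list of neighbor index vectors as produced by
#'   [build_neighbor_graph()]; computed from the recording's positions when
#'   omitted.
#' @return a `session_recording` with re-referenced data (annotations kept).
#' @export
laplacian_reference <- function(recording, neighbor_graph = NULL) {
  if (is.null(neighbor_graph)) {
    if (is.null(recording$channel_positions))
      stop("no neighbor_graph given and recording has no channel positions",
           call. = FALSE)
    neighbor_graph <- build_neighbor_graph(recording$channel_positions)
  }
  n <- nrow(recording$data)
  if (length(neighbor_graph) != n)
    stop("neighbor_graph length must equal the channel count", call. = FALSE)
  isolated <- which(vapply(neighbor_graph, length, integer(1)) == 0L)
  if (length(isolated))
    stop(sprintf("isolated channels with no neighbors: %s",
                 paste(recording$channel_labels[isolated], collapse = ", ")),
         call. = FALSE)
  # W = I - N where N averages each channel's neighbors
  out <- recording$data
  for (i in seq_len(n)) {
    nb <- neighbor_graph[[i]]
    out[i, ] <- recording$data[i, ] -
      colMeans(recording$data[nb, , drop = FALSE])
  }
  rec <- recording
  rec$data <- out
  rec
}
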