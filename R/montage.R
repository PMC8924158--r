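# Sensor montages: quasi-uniform electrode layouts on an upper hemisphere.
#
# Stands in for a high-density infant net. Positions are a Fibonacci
# lattice on the upper hemisphere of a spherical head model (radius in
# cm); the golden-angle spiral gives near-uniform spacing for any channel
# count, and a seed-derived global azimuth rotation decorrelates montages
# generated with different seeds while keeping each montage deterministic.

#' Build a hemispheric electrode montage
#'
#' @param n_channels Number of electrodes (>= 4); default 128.
#' @param head_radius Head radius in cm; default 6.
#' @param seed Integer; rotates the lattice azimuthally (deterministic
#'   given arguments).
#' @return A `montage`: `channels` (ids), `positions` (n x 3 matrix, cm),
#'   `head_radius`, `reference` (id of the vertex-most electrode).
#' @examples
#' m <- make_montage(128, 6)
#' range(sqrt(rowSums(m$positions^2)))
#' @export
make_montage <- function(n_channels = 128L, head_radius = 6, seed = 0L) {
  if (!is_count(n_channels) || n_channels < 4L) {
    stopf("n_channels must be an integer >= 4")
  }
  if (!is.numeric(head_radius) || head_radius <= 0) {
    stopf("head_radius must be positive")
  }
  i <- seq_len(n_channels) - 1L
  z <- (i + 0.5) / n_channels          # height fraction above the equator
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + (derive_seed(seed, 1L) %% 360L) * pi / 180
  rxy <- sqrt(1 - z^2)
  pos <- head_radius * cbind(x = rxy * cos(phi), y = rxy * sin(phi), z = z)
  ids <- sprintf("E%03d", seq_len(n_channels))
  rownames(pos) <- ids
  structure(list(channels = ids,
                 positions = pos,
                 head_radius = head_radius,
                 reference = ids[which.max(pos[, "z"])]),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels on a %.1f cm hemisphere (ref %s)\n",
              length(x$channels), x$head_radius, x$reference))
  invisible(x)
}

#' Pairwise electrode distances
#'
#' @param montage A `montage`.
#' @return Symmetric matrix of Euclidean distances in cm.
#' @export
montage_distances <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  as.matrix(stats::dist(montage$positions))
}

#' Channel adjacency by Euclidean distance
#'
#' Two electrodes are neighbors when their Euclidean distance does not
#' exceed `max_dist` cm. Isolated channels are reported, not fatal.
#'
#' @param montage A `montage`.
#' @param max_dist Neighbor threshold in cm (default 3).
#' @return An `adjacency_graph`: logical `matrix` (no self-edges),
#'   `mean_degree`, `isolated` (channel ids without neighbors).
#' @export
build_adjacency <- function(montage, max_dist = 3) {
  d <- montage_distances(montage)
  adj <- d <= max_dist
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  structure(list(matrix = adj,
                 mean_degree = mean(deg),
                 isolated = montage$channels[deg == 0],
                 max_dist = max_dist),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d channels, mean degree %.1f (<= %.1f cm)%s\n",
              nrow(x$matrix), x$mean_degree, x$max_dist,
              if (length(x$isolated))
                sprintf(", %d isolated", length(x$isolated)) else ""))
  invisible(x)
}

#' Write / read a montage TSV sidecar
#'
#' Columns `channel`, `x_cm`, `y_cm`, `z_cm`; the head radius is recovered
#' from the positions on read.
#'
#' @param montage A `montage`.
#' @param path TSV path.
#' @return `path` / a `montage`.
#' @export
write_montage_tsv <- function(montage, path) {
  write_tsv(data.frame(channel = montage$channels,
                       x_cm = montage$positions[, 1],
                       y_cm = montage$positions[, 2],
                       z_cm = montage$positions[, 3]), path)
}

#' @rdname write_montage_tsv
#' @export
read_montage_tsv <- function(path) {
  df <- read_tsv(path)
  pos <- as.matrix(df[, c("x_cm", "y_cm", "z_cm")])
  rownames(pos) <- df$channel
  colnames(pos) <- c("x", "y", "z")
  structure(list(channels = df$channel,
                 positions = pos,
                 head_radius = stats::median(sqrt(rowSums(pos^2))),
                 reference = df$channel[which.max(pos[, "z"])]),
            class = "montage")
}
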