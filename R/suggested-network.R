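# The 25-node suggestion graph shown (as stars) to players in nudging
# sessions. Players are split into five groups of five and indexed (g, i) in
# Z5 x Z5; each node is linked to its two within-group ring neighbours and to
# one node in each of the four other groups via affine index rules. The
# result is 6-regular, perfectly bi-directional, has diameter two and is
# vertex-transitive (all nodes topologically identical).

#' Build the suggested communication network
#'
#' Constructs the 25-node suggestion graph. With 0-based residues
#' \eqn{g, i \in Z_5} and player id \eqn{5g + i + 1}, node \eqn{(g, i)} is
#' linked to \eqn{(g, i \pm 1)}, \eqn{(g+1, 2i+1)}, \eqn{(g+2, 3i+3)},
#' \eqn{(g+3, 2i+4)} and \eqn{(g+4, 3i+2)}, all indices mod 5. The inter-group
#' rules come in reciprocal pairs, so the relation is symmetric without
#' symmetrisation.
#'
#' @return An object of class `suggested_network`: `n_groups`, `group_size`,
#'   `labels` (data frame `player`, `g`, `i`), and the 25 x 25 0/1 `adjacency`
#'   matrix.
#' @export
#'
#' @examples
#' net <- build_suggested_network()
#' rowSums(net$adjacency)  # all 6
build_suggested_network <- function() {
  g <- rep(0:4, each = 5)
  i <- rep(0:4, times = 5)
  id <- function(g, i) 5L * (g %% 5L) + (i %% 5L) + 1L
  n <- 25L
  adj <- matrix(0L, n, n)
  for (k in seq_len(n)) {
    gk <- g[k]; ik <- i[k]
    nb <- c(id(gk, ik + 1), id(gk, ik - 1),
            id(gk + 1, 2 * ik + 1), id(gk + 2, 3 * ik + 3),
            id(gk + 3, 2 * ik + 4), id(gk + 4, 3 * ik + 2))
    adj[k, nb] <- 1L
  }
  if (!identical(adj, t(adj)))
    stop("internal error: suggestion graph not symmetric", call. = FALSE)
  structure(
    list(n_groups = 5L, group_size = 5L,
         labels = data.frame(player = seq_len(n), g = g, i = i),
         adjacency = adj),
    class = "suggested_network"
  )
}

#' @export
print.suggested_network <- function(x, ...) {
  cat(sprintf("<suggested_network> %d nodes, %d edges, %d-regular\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              unique(rowSums(x$adjacency))[1]))
  invisible(x)
}

as_adjacency <- function(net) {
  if (inherits(net, "suggested_network")) net$adjacency else as.matrix(net)
}

#' Structural diagnostics of an undirected network
#'
#' Verifies the three properties claimed for the suggestion graph: perfect
#' bi-directionality (symmetric adjacency), 6-regularity, and diameter two.
#' Works on any adjacency matrix; shortest paths are computed with igraph.
#'
#' @param net A `suggested_network` or a square 0/1 adjacency matrix.
#'
#' @return A list: `degrees`, `is_symmetric`, `diameter`, `eccentricities`,
#'   `bidirectional_pair_count` (mutual links, i.e. undirected edges for a
#'   symmetric matrix), and `homogeneous` (all nodes share degree and
#'   eccentricity).
#' @export
graph_diagnostics <- function(net) {
  adj <- as_adjacency(net)
  is_sym <- isTRUE(all.equal(adj, t(adj), check.attributes = FALSE))
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  d <- igraph::distances(gr, mode = "out")
  ecc <- apply(d, 1, max)
  list(
    degrees = rowSums(adj > 0),
    is_symmetric = is_sym,
    diameter = max(d),
    eccentricities = ecc,
    bidirectional_pair_count = sum(adj * t(adj) > 0) / 2,
    homogeneous = length(unique(rowSums(adj > 0))) == 1L &&
      length(unique(ecc)) == 1L
  )
}

#' Directed inquiry pattern under full compliance
#'
#' The directed network of inquiries that results if every player sends an
#' inquiry along each suggested link in every round: every undirected
#' suggestion edge used in both directions.
#'
#' @param net A `suggested_network`.
#' @return A 25 x 25 0/1 directed adjacency matrix (here equal to the
#'   symmetric suggestion matrix).
#' @export
suggested_inquiry_pattern <- function(net) {
  as_adjacency(net)
}

#' Export a network as a two-column edge list
#'
#' Writes one row per undirected edge (`from < to`), tab-separated, no header.
#'
#' @param net A `suggested_network` or adjacency matrix.
#' @param path Output file path.
#' @export
write_edgelist <- function(net, path) {
  adj <- as_adjacency(net)
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  utils::write.table(data.frame(from = idx[, 1], to = idx[, 2]),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column edge list into an adjacency matrix
#'
#' @param path Edge-list file written by [write_edgelist()].
#' @param n_players Number of nodes.
#' @return A symmetric 0/1 adjacency matrix.
#' @export
read_edgelist <- function(path, n_players = 25) {
  el <- utils::read.table(path, col.names = c("from", "to"))
  adj <- matrix(0L, n_players, n_players)
  adj[cbind(el$from, el$to)] <- 1L
  adj[cbind(el$to, el$from)] <- 1L
  adj
}
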