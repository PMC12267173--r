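#' Network graph
#'
#' A neuron connectivity graph: `n` nodes (1-based indices, matching the
#' neuron numbering used in the synchrony tables), an edge list with a
#' per-edge `directed` flag, and the index of the externally stimulated
#' node.  Directed edges model chemical synapses (presynaptic `src` to
#' postsynaptic `dst`); undirected edges model gap junctions and couple both
#' endpoints.
#'
#' Self-loops and duplicate edges are rejected.
#'
#' @param n node count, >= 2.
#' @param edges data frame with integer columns `src`, `dst` and logical
#'   column `directed`.
#' @param stimulated_node index of the node receiving the external stimulus
#'   (default 1).
#' @return An object of class `network_graph`.
#' @export
network_graph <- function(n, edges, stimulated_node = 1) {
  n <- as.integer(n)
  stopifnot(length(n) == 1, n >= 2)
  edges <- as.data.frame(edges)
  stopifnot(all(c("src", "dst", "directed") %in% names(edges)))
  edges$src <- as.integer(edges$src)
  edges$dst <- as.integer(edges$dst)
  edges$directed <- as.logical(edges$directed)
  if (any(is.na(edges$src)) || any(is.na(edges$dst)) || any(is.na(edges$directed)))
    stop("edge list contains missing values", call. = FALSE)
  if (any(edges$src < 1 | edges$src > n | edges$dst < 1 | edges$dst > n))
    stop("edge endpoints must lie in 1..n", call. = FALSE)
  if (any(edges$src == edges$dst))
    stop("self-loops are not allowed", call. = FALSE)
  key <- ifelse(edges$directed,
                paste0("d", edges$src, ">", edges$dst),
                paste0("u", pmin(edges$src, edges$dst), "-", pmax(edges$src, edges$dst)))
  if (anyDuplicated(key))
    stop("duplicate edges are not allowed", call. = FALSE)
  stimulated_node <- as.integer(stimulated_node)
  stopifnot(length(stimulated_node) == 1, stimulated_node >= 1, stimulated_node <= n)
  rownames(edges) <- NULL
  structure(list(n = n, edges = edges[c("src", "dst", "directed")],
                 stimulated_node = stimulated_node),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat("<network_graph>", x$n, "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$directed), "directed ), stimulated node", x$stimulated_node, "\n")
  invisible(x)
}

#' Ring network
#'
#' The ring backbone used by every topology in the package: node `i` linked
#' to node `i + 1` and node `n` closing the loop back to node 1.  Directed
#' rings (chemical synapses) pass the stimulus around in one direction;
#' undirected rings (gap junctions) conduct both ways, so the node farthest
#' from the stimulated node 1 is `n/2 + 1`.
#'
#' @param n node count, >= 2.
#' @param directed logical; directed edges (chemical) or undirected (electrical).
#' @param stimulated_node stimulated node index.
#' @return A [network_graph()].
#' @examples
#' build_ring(100, directed = TRUE)
#' @export
build_ring <- function(n, directed = TRUE, stimulated_node = 1) {
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n < 2)
    stop("configuration error: a ring needs n >= 2", call. = FALSE)
  if (directed) {
    edges <- data.frame(src = 1:n, dst = c(2:n, 1L), directed = TRUE)
  } else if (n == 2) {
    edges <- data.frame(src = 1L, dst = 2L, directed = FALSE)
  } else {
    edges <- data.frame(src = 1:n, dst = c(2:n, 1L), directed = FALSE)
  }
  network_graph(n, edges, stimulated_node)
}

#' Hub-augmented Newman-Watts small-world network
#'
#' Ring backbone plus `k` shortcut edges from a hub node (the stimulated
#' node) to nodes it is not already adjacent to.  By default the targets are
#' deterministically evenly spaced at ring distance 4: `hub + 4, hub + 8,
#' ...` (for `n = 100`, `hub = 1`, `k = 24` this is 5, 9, ..., 97), which is
#' reproducible and avoids the hub's ring neighbours.  An explicit `targets`
#' vector overrides the default.
#'
#' Shortcuts are directed hub-to-target when `directed` (the hub distributes
#' the stimulus), or undirected for electrical coupling;
#' `bidirectional_shortcuts` adds the reverse chemical arcs as well.
#'
#' @param n node count.
#' @param hub hub node index (also the stimulated node).
#' @param k number of shortcuts; needs `k <= n - 3`.
#' @param directed logical; edge directedness as in [build_ring()].
#' @param targets optional explicit shortcut targets (length `k`).
#' @param bidirectional_shortcuts logical; also add target-to-hub arcs
#'   (directed graphs only).
#' @return A [network_graph()].
#' @examples
#' g <- build_nw_hub(100)
#' nrow(g$edges)  # 124
#' @export
build_nw_hub <- function(n, hub = 1, k = 24, directed = TRUE, targets = NULL,
                         bidirectional_shortcuts = FALSE) {
  n <- as.integer(n); hub <- as.integer(hub); k <- as.integer(k)
  if (k < 0 || k > n - 3)
    stop("configuration error: need 0 <= k <= n - 3 shortcuts", call. = FALSE)
  ring <- build_ring(n, directed = directed, stimulated_node = hub)
  if (k == 0 && is.null(targets)) return(ring)
  ring_neighbours <- c(hub %% n + 1L, (hub - 2L) %% n + 1L)
  if (is.null(targets)) {
    targets <- ((hub - 1L + 4L * seq_len(k)) %% n) + 1L
  }
  targets <- as.integer(targets)
  if (length(targets) != k || anyDuplicated(targets))
    stop("configuration error: need k distinct shortcut targets", call. = FALSE)
  if (any(targets == hub) || any(targets %in% ring_neighbours))
    stop("configuration error: shortcut targets must not be the hub or its ring neighbours",
         call. = FALSE)
  sc <- data.frame(src = hub, dst = targets, directed = directed)
  if (directed && bidirectional_shortcuts)
    sc <- rbind(sc, data.frame(src = targets, dst = hub, directed = TRUE))
  network_graph(n, rbind(ring$edges, sc), stimulated_node = hub)
}

#' Probabilistic Newman-Watts small-world network
#'
#' Ring backbone plus each non-ring node pair added independently as a
#' shortcut with probability `p`.  `p = 0` recovers the plain ring; `p = 1`
#' gives the complete (globally coupled) graph.  For directed graphs the
#' shortcut runs from the lower to the higher node index.
#'
#' @param n node count.
#' @param p shortcut probability in `[0, 1]`.
#' @param directed logical; edge directedness.
#' @param seed RNG seed for reproducible wiring (the caller's RNG state is
#'   left untouched).
#' @param stimulated_node stimulated node index.
#' @return A [network_graph()].
#' @export
build_nw_random <- function(n, p, directed = FALSE, seed = NULL,
                            stimulated_node = 1) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("configuration error: `p` must lie in [0, 1]", call. = FALSE)
  ring <- build_ring(n, directed = directed, stimulated_node = stimulated_node)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  adjacent <- (pairs[, 2] - pairs[, 1] == 1) | (pairs[, 1] == 1 & pairs[, 2] == n)
  pairs <- pairs[!adjacent, , drop = FALSE]
  take <- with_seed(seed, runif(nrow(pairs)) < p)
  if (!any(take)) return(ring)
  sc <- data.frame(src = pairs[take, 1], dst = pairs[take, 2], directed = directed)
  network_graph(n, rbind(ring$edges, sc), stimulated_node = stimulated_node)
}

#' Write / read a graph as an edge-list CSV
#'
#' Plain-text round-trip of a [network_graph()]: columns `source`, `target`,
#' `directed`, with the node count and stimulated node kept in commented
#' header lines.
#'
#' @param graph a [network_graph()].
#' @param path file path.
#' @return `write_graph_csv()` returns `path` invisibly; `read_graph_csv()`
#'   returns the reconstructed [network_graph()].
#' @export
write_graph_csv <- function(graph, path) {
  stopifnot(inherits(graph, "network_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n: %d", graph$n),
               sprintf("# stimulated_node: %d", graph$stimulated_node),
               "source,target,directed"), con)
  e <- graph$edges
  writeLines(sprintf("%d,%d,%s", e$src, e$dst, ifelse(e$directed, "TRUE", "FALSE")), con)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
read_graph_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  n <- as.integer(sub("# n: *", "", hdr[1]))
  stim <- as.integer(sub("# stimulated_node: *", "", hdr[2]))
  e <- read.csv(path, comment.char = "#")
  network_graph(n, data.frame(src = e$source, dst = e$target,
                              directed = e$directed),
                stimulated_node = stim)
}

# Expand the edge list into directed arcs as seen by the integrator:
# undirected edges contribute both directions.
graph_arcs <- function(graph) {
  e <- graph$edges
  und <- e[!e$directed, , drop = FALSE]
  rbind(cbind(e$src, e$dst),
        if (nrow(und)) cbind(und$dst, und$src))
}
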