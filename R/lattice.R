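#' Build a square-lattice interaction network
#'
#' Players sit on a `rows` x `cols` grid and interact with their von
#' Neumann (4-)neighbourhood.  By default the lattice has a border — there
#' is no wraparound, so corner players have 2 neighbours and edge players
#' 3, and being on an edge can slow wealth growth or decay because of the
#' smaller number of turns per round.  The toroidal variant
#' (`borderless = TRUE`) gives every player exactly 4 neighbours and is
#' used to measure the size of that edge effect.
#'
#' @param rows,cols Grid dimensions (>= 1; toroidal needs >= 3 to avoid
#'   duplicate edges).
#' @param borderless Wrap the lattice into a torus.
#'
#' @return An object of class `farmers_lattice`: node ids are row-major
#'   integers `1..rows*cols`; `adj` holds a sorted integer neighbour vector
#'   per node; `alive` is a logical flag per node; `coords` the 0-based
#'   (row, col) of each node.
#'
#' @examples
#' net <- build_lattice(20, 20)
#' nrow(lattice_edges(net))   # 760 edges
#' border_fraction(net)       # 0.19
#' @seealso [remove_node_reconnect()], [lattice_edges()]
#' @export
build_lattice <- function(rows, cols, borderless = FALSE) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L) {
    stop("rows and cols must be positive integers")
  }
  if (borderless && (rows < 3L || cols < 3L)) {
    stop("toroidal lattice needs rows, cols >= 3")
  }
  n <- rows * cols
  id <- function(r, c) r * cols + c + 1L  # 0-based coords, row-major ids
  adj <- vector("list", n)
  for (r in seq_len(rows) - 1L) {
    for (c in seq_len(cols) - 1L) {
      nb <- integer()
      if (borderless) {
        nb <- c(id((r - 1L) %% rows, c), id((r + 1L) %% rows, c),
                id(r, (c - 1L) %% cols), id(r, (c + 1L) %% cols))
      } else {
        if (r > 0L)        nb <- c(nb, id(r - 1L, c))
        if (r < rows - 1L) nb <- c(nb, id(r + 1L, c))
        if (c > 0L)        nb <- c(nb, id(r, c - 1L))
        if (c < cols - 1L) nb <- c(nb, id(r, c + 1L))
      }
      adj[[id(r, c)]] <- sort(unique(nb))
    }
  }
  coords <- cbind(row = rep(seq_len(rows) - 1L, each = cols),
                  col = rep(seq_len(cols) - 1L, times = rows))
  structure(list(rows = rows, cols = cols, n = n, adj = adj,
                 alive = rep(TRUE, n), coords = coords,
                 borderless = isTRUE(borderless),
                 initial_degree = lengths(adj)),
            class = "farmers_lattice")
}

#' Remove a dead player and reconnect its neighbours
#'
#' Marks `node` dead, deletes all its edges, and connects its still-alive
#' former neighbours to each other so that survivors keep playing.  Two
#' policies are provided:
#'
#' * `"pair"` — the neighbours, in ascending id order, are joined in
#'   nested pairs (first with last, second with second-last, ...).  On the
#'   intact lattice this joins *opposite* neighbours (up with down, left
#'   with right), and it preserves degree: each survivor loses the edge to
#'   the dead player and gains one replacement, so interior players keep
#'   about 4 interactions per round however many deaths accumulate.  An
#'   odd neighbour out gains no edge (as if moved to a border).
#' * `"clique"` — every pair of still-alive former neighbours is
#'   connected.  Degrees then grow with each adjacent death, which under
#'   heavy die-off inflates per-round interaction counts (and with them
#'   total consumption) far beyond the nominal 4 turns per round.
#'
#' Pairs already connected are skipped; dead nodes never gain edges.
#'
#' @param network A `farmers_lattice`.
#' @param node Id of an alive node.
#' @param policy `"clique"` or `"pair"`.  Simulations use the policy in
#'   [game_config()] (default `"pair"`).
#' @return The updated network.
#' @examples
#' net <- build_lattice(3, 3)
#' # centre death: 6 new edges under clique, 2 (opposite pairs) under pair
#' nrow(lattice_edges(remove_node_reconnect(net, 5L, "clique")))
#' nrow(lattice_edges(remove_node_reconnect(net, 5L, "pair")))
#' @export
remove_node_reconnect <- function(network, node,
                                  policy = c("clique", "pair")) {
  stopifnot(inherits(network, "farmers_lattice"))
  policy <- match.arg(policy)
  node <- as.integer(node)
  if (node < 1L || node > network$n) stop("no such node: ", node)
  if (!network$alive[node]) stop("node already dead: ", node)
  kill_nodes(network, node, policy)
}

# Simultaneous removal of one or more dying nodes: mark all dead first,
# then reconnect each one's still-alive former neighbours.  Both
# participants of an interaction can die at once; neither then counts as a
# reconnection target of the other.
kill_nodes <- function(network, nodes, policy = "clique") {
  nodes <- as.integer(nodes)
  former <- lapply(nodes, function(nd) network$adj[[nd]])
  network$alive[nodes] <- FALSE
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    for (nb in former[[k]]) {
      network$adj[[nb]] <- setdiff(network$adj[[nb]], nd)
    }
    network$adj[[nd]] <- integer()
  }
  connect <- function(a, b) {
    if (!(b %in% network$adj[[a]])) {
      network$adj[[a]] <<- sort(c(network$adj[[a]], b))
      network$adj[[b]] <<- sort(c(network$adj[[b]], a))
    }
  }
  for (k in seq_along(nodes)) {
    live <- former[[k]][network$alive[former[[k]]]]
    m <- length(live)
    if (m < 2L) next
    if (identical(policy, "clique")) {
      pairs <- utils::combn(live, 2L)
      for (j in seq_len(ncol(pairs))) connect(pairs[1L, j], pairs[2L, j])
    } else {
      for (j in seq_len(m %/% 2L)) connect(live[[j]], live[[m + 1L - j]])
    }
  }
  network
}

#' Fraction of players on the lattice border
#'
#' Fraction of initial nodes whose initial degree is below 4 (corners and
#' edges).  On the default 20 x 20 lattice this is 76/400 = 0.19, about a
#' 20% edge population; a toroidal lattice returns 0.
#'
#' @param network A `farmers_lattice`.
#' @return A fraction in \[0, 1\].
#' @examples
#' border_fraction(build_lattice(100, 100))  # 0.0396
#' @export
border_fraction <- function(network) {
  stopifnot(inherits(network, "farmers_lattice"))
  mean(network$initial_degree < 4L)
}

#' Edge list of a lattice network
#'
#' @param network A `farmers_lattice`.
#' @param alive_only Keep only edges between two alive nodes.
#' @return A data frame with columns `node_a < node_b`, sorted
#'   lexicographically — the canonical play order of a round.
#' @export
lattice_edges <- function(network, alive_only = FALSE) {
  stopifnot(inherits(network, "farmers_lattice"))
  a <- integer(); b <- integer()
  for (i in seq_len(network$n)) {
    nb <- network$adj[[i]]
    nb <- nb[nb > i]
    if (length(nb)) {
      a <- c(a, rep.int(i, length(nb)))
      b <- c(b, nb)
    }
  }
  df <- data.frame(node_a = a, node_b = b)
  if (alive_only) {
    df <- df[network$alive[df$node_a] & network$alive[df$node_b], ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a lattice to CSV files for inspection
#'
#' @param network A `farmers_lattice`.
#' @param edge_file,node_file Output paths; `NULL` skips that file.
#' @return Invisibly, a list with the two data frames.
#' @export
write_lattice <- function(network, edge_file = NULL, node_file = NULL) {
  edges <- lattice_edges(network)
  nodes <- data.frame(id = seq_len(network$n),
                      row = network$coords[, "row"],
                      col = network$coords[, "col"],
                      alive = network$alive)
  if (!is.null(edge_file)) utils::write.csv(edges, edge_file, row.names = FALSE)
  if (!is.null(node_file)) utils::write.csv(nodes, node_file, row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}

#' @export
print.farmers_lattice <- function(x, ...) {
  cat(sprintf("%dx%d%s lattice: %d nodes (%d alive), %d edges\n",
              x$rows, x$cols, if (x$borderless) " toroidal" else "",
              x$n, sum(x$alive), nrow(lattice_edges(x, alive_only = TRUE))))
  invisible(x)
}
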