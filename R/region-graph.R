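#' Region adjacency graphs
#'
#' A \code{region_graph} stores the first-order neighbourhood structure of a
#' set of regions: for each region \eqn{j} the set \eqn{N(j)} of regions that
#' share a boundary with it.  The graph drives both the intrinsic Markov
#' random field prior of the spatial model and the weight matrix used for
#' Moran's I.  Adjacency is symmetric with no self-loops; regions without any
#' neighbour are flagged as islands and take no part in the MRF prior.
#'
#' @param region_ids character or integer vector of unique region identifiers.
#' @param neighbors list, one element per region, each an integer vector of
#'   neighbour positions (indices into \code{region_ids}).
#' @return An object of class \code{region_graph} with elements
#'   \code{region_ids}, \code{neighbors} (list of integer index vectors),
#'   \code{n_neighbors} and \code{islands} (logical).
#' @export
region_graph <- function(region_ids, neighbors) {
  region_ids <- as.character(region_ids)
  J <- length(region_ids)
  if (anyDuplicated(region_ids)) stop("region ids must be unique")
  if (length(neighbors) != J) stop("need one neighbour set per region")
  neighbors <- lapply(neighbors, function(x) sort(unique(as.integer(x))))
  for (j in seq_len(J)) {
    nb <- neighbors[[j]]
    if (any(nb < 1L | nb > J)) stop("neighbour index out of range for region ", region_ids[j])
    if (j %in% nb) stop("self-loop at region ", region_ids[j])
    for (j2 in nb) {
      if (!(j %in% neighbors[[j2]]))
        stop("adjacency not symmetric between ", region_ids[j], " and ", region_ids[j2])
    }
  }
  structure(
    list(region_ids = region_ids,
         neighbors = neighbors,
         n_neighbors = vapply(neighbors, length, integer(1)),
         islands = vapply(neighbors, length, integer(1)) == 0L),
    class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("Region adjacency graph:", length(x$region_ids), "regions,",
      sum(x$n_neighbors) / 2, "edges")
  if (any(x$islands)) cat(",", sum(x$islands), "island(s)")
  cat("\n")
  invisible(x)
}

#' Build a rook-adjacency lattice of regions
#'
#' Generates a rectangular grid of \code{rows * cols} synthetic regions in
#' which two regions are neighbours when their cells share an edge.  The
#' lattice stands in for a first-level administrative map when simulating
#' survey data.
#'
#' @param rows,cols positive integers; \code{rows * cols >= 2}.
#' @return A \code{\link{region_graph}}.  Region ids are \code{"r<row>c<col>"}
#'   in row-major order; the grid position of each region is attached as
#'   attribute \code{coords} (matrix of row/col indices) for centroid layout.
#' @examples
#' g <- build_region_lattice(3, 4)
#' g$n_neighbors
#' @export
build_region_lattice <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 1L || length(cols) != 1L || is.na(rows) || is.na(cols) ||
      rows < 1L || cols < 1L)
    stop("rows and cols must be positive integers")
  if (rows * cols < 2L) stop("lattice needs at least two regions")
  idx <- function(r, c) (r - 1L) * cols + c
  J <- rows * cols
  nbs <- vector("list", J)
  coords <- matrix(0L, J, 2L, dimnames = list(NULL, c("row", "col")))
  ids <- character(J)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      j <- idx(r, c)
      ids[j] <- sprintf("r%dc%d", r, c)
      coords[j, ] <- c(r, c)
      nb <- integer(0)
      if (r > 1L)    nb <- c(nb, idx(r - 1L, c))
      if (r < rows)  nb <- c(nb, idx(r + 1L, c))
      if (c > 1L)    nb <- c(nb, idx(r, c - 1L))
      if (c < cols)  nb <- c(nb, idx(r, c + 1L))
      nbs[[j]] <- nb
    }
  }
  g <- region_graph(ids, nbs)
  attr(g, "coords") <- coords
  g
}

#' Connected components of a region graph
#' @keywords internal
graph_components <- function(graph) {
  J <- length(graph$region_ids)
  comp <- integer(J)
  cur <- 0L
  for (start in seq_len(J)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[j] != 0L) next
      comp[j] <- cur
      stack <- c(stack, graph$neighbors[[j]][comp[graph$neighbors[[j]]] == 0L])
    }
  }
  comp
}

#' Draw from an intrinsic Gaussian Markov random field
#'
#' Samples one realisation of region effects under the intrinsic GMRF whose
#' conditionals are \eqn{s_j | s_{-j} ~ N(mean(s_{N(j)}), tau2 / N_j)}.  The
#' joint precision \eqn{(D - A)/tau2} is rank-deficient (null space = constant
#' vector on a connected graph); the draw is taken in the orthogonal
#' complement of the null space, so it sums to zero exactly.
#'
#' @param graph a \code{\link{region_graph}}; must be connected.
#' @param tau2 conditional variance parameter (> 0).
#' @return numeric vector of length \code{J}, summing to zero.
#' @export
sample_intrinsic_gmrf <- function(graph, tau2) {
  stopifnot(inherits(graph, "region_graph"))
  if (!is.numeric(tau2) || length(tau2) != 1L || tau2 <= 0)
    stop("tau2 must be a positive scalar")
  comp <- graph_components(graph)
  if (max(comp) > 1L) {
    tab <- table(comp)
    stop("graph is disconnected: ", max(comp), " components with sizes ",
         paste(tab, collapse = ", "))
  }
  Q <- structure_matrix(graph) / tau2
  eg <- eigen(Q, symmetric = TRUE)
  J <- length(graph$region_ids)
  # last eigenvalue ~ 0 (constant null space); sample the rest
  lam <- eg$values[seq_len(J - 1L)]
  V <- eg$vectors[, seq_len(J - 1L), drop = FALSE]
  s <- drop(V %*% (stats::rnorm(J - 1L) / sqrt(lam)))
  s - mean(s)   # null-space complement is already centred; re-centre for exactness
}

#' Structure (graph Laplacian) matrix D - A of a region graph
#' @keywords internal
structure_matrix <- function(graph) {
  J <- length(graph$region_ids)
  Q <- matrix(0, J, J)
  for (j in seq_len(J)) {
    Q[j, j] <- graph$n_neighbors[j]
    Q[j, graph$neighbors[[j]]] <- -1
  }
  Q
}

#' Binary first-order adjacency weight matrix of a region graph
#'
#' @param graph a \code{\link{region_graph}}.
#' @return J x J 0/1 matrix with zero diagonal, suitable for
#'   \code{\link{morans_i}}.
#' @export
region_weights <- function(graph) {
  J <- length(graph$region_ids)
  W <- matrix(0, J, J, dimnames = list(graph$region_ids, graph$region_ids))
  for (j in seq_len(J)) W[j, graph$neighbors[[j]]] <- 1
  W
}

#' Read / write a region graph in plain-text layout
#'
#' The file holds the number of regions on the first line, then one line per
#' region: \code{id n_neighbors neighbor_id...} (the layout used by common
#' structured-additive-regression software for boundary graphs).
#'
#' @param graph a \code{\link{region_graph}}.
#' @param path file path.
#' @return \code{read_region_graph} returns a \code{\link{region_graph}};
#'   \code{write_region_graph} returns \code{path} invisibly.
#' @export
write_region_graph <- function(graph, path) {
  stopifnot(inherits(graph, "region_graph"))
  lines <- c(as.character(length(graph$region_ids)),
             vapply(seq_along(graph$region_ids), function(j) {
               paste(c(graph$region_ids[j], graph$n_neighbors[j],
                       graph$region_ids[graph$neighbors[[j]]]), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_region_graph
#' @export
read_region_graph <- function(path) {
  lines <- readLines(path)
  J <- as.integer(lines[1L])
  if (is.na(J) || length(lines) < J + 1L) stop("malformed graph file: ", path)
  ids <- character(J)
  raw <- vector("list", J)
  for (j in seq_len(J)) {
    tok <- strsplit(trimws(lines[j + 1L]), "[[:space:]]+")[[1]]
    ids[j] <- tok[1L]
    nn <- as.integer(tok[2L])
    raw[[j]] <- if (nn > 0L) tok[2L + seq_len(nn)] else character(0)
  }
  nbs <- lapply(raw, function(x) match(x, ids))
  if (any(vapply(nbs, anyNA, logical(1)))) stop("graph file references unknown region id")
  region_graph(ids, nbs)
}
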