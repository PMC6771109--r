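#' Area adjacency graphs
#'
#' An `area_graph` stores the binary first-order spatial weights matrix
#' \eqn{W} shared by the incidence and survival models, together with area
#' identifiers and (optionally) planar centroids.  Adjacency is symmetric
#' with a zero diagonal; the diagonal of neighbour counts \eqn{D} enters the
#' Leroux conditional variance \eqn{\sigma^2 / (\rho \sum_j w_{ij} + 1 - \rho)}.
#'
#' @param area_ids character vector of unique area identifiers.
#' @param W symmetric binary adjacency matrix (base or `Matrix` sparse),
#'   zero diagonal, dimensions matching `area_ids`.
#' @param centroids optional numeric matrix (n x 2) of planar coordinates.
#'
#' @return An object of class `area_graph` with elements `area_ids`, `W`
#'   (a sparse `dgCMatrix`), `centroids`, and `neighbour_counts`.
#' @export
area_graph <- function(area_ids, W, centroids = NULL) {
  area_ids <- as.character(area_ids)
  n <- length(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area ids")
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(W) != n || ncol(W) != n) stop("W dimensions do not match area_ids")
  if (any(W@x != 0 & W@x != 1)) stop("W must be binary")
  if (!Matrix::isSymmetric(W)) stop("W must be symmetric")
  if (any(Matrix::diag(W) != 0)) stop("W must have a zero diagonal")
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != n || ncol(centroids) != 2)
      stop("centroids must be an n x 2 matrix")
    rownames(centroids) <- area_ids
  }
  dimnames(W) <- list(area_ids, area_ids)
  structure(
    list(area_ids = area_ids, W = W, centroids = centroids,
         neighbour_counts = setNames(as.numeric(Matrix::rowSums(W)), area_ids)),
    class = "area_graph"
  )
}

#' @export
print.area_graph <- function(x, ...) {
  n <- length(x$area_ids)
  m <- sum(x$neighbour_counts) / 2
  cat(sprintf("area_graph: %d areas, %d edges, %d isolated\n",
              n, as.integer(m), sum(x$neighbour_counts == 0)))
  invisible(x)
}

#' @export
length.area_graph <- function(x) length(x$area_ids)

#' Number of undirected edges in an area graph
#' @param graph an [area_graph].
#' @return integer edge count.
#' @export
n_edges <- function(graph) as.integer(sum(graph$neighbour_counts) / 2)

#' Build a binary first-order adjacency graph
#'
#' Areas are adjacent if they share a common boundary of positive length
#' (polygon mode) or are listed as an edge (edge-list mode).  Point (corner)
#' contact does not create adjacency.  An area wholly enclosed within
#' another shares its entire ring with the host's interior ring and is
#' therefore adjacent to the host only.
#'
#' @param edges data frame with columns `id_a`, `id_b` (one row per
#'   undirected edge), or `NULL` when `polygons` is given.
#' @param area_ids character vector of all area ids (required in edge-list
#'   mode so isolated areas are representable; defaults to ids appearing in
#'   `edges`).
#' @param polygons named list of polygons, one per area.  Each polygon is a
#'   list of rings (outer ring first, holes after); each ring a closed
#'   two-column coordinate matrix.  A bare matrix is taken as a single ring.
#' @param centroids optional n x 2 matrix of centroids; computed from ring
#'   vertices in polygon mode when omitted.
#' @param tol distance tolerance for coincident vertices in polygon mode.
#' @return an [area_graph].
#' @export
build_adjacency <- function(edges = NULL, area_ids = NULL, polygons = NULL,
                            centroids = NULL, tol = 1e-9) {
  if (!is.null(polygons)) {
    return(build_adjacency_polygons(polygons, centroids = centroids, tol = tol))
  }
  if (is.null(edges)) stop("supply either edges or polygons")
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("edge list needs two columns")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  if (any(a == b)) stop("self-edges are not allowed")
  if (is.null(area_ids)) area_ids <- sort(unique(c(a, b)))
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area ids")
  if (!all(c(a, b) %in% area_ids)) stop("edge references unknown area id")
  n <- length(area_ids)
  i <- match(a, area_ids); j <- match(b, area_ids)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  W@x[] <- 1
  area_graph(area_ids, W, centroids)
}

# Positive-length overlap of two collinear segments; returns the overlap
# length (0 when segments are not collinear or touch only at a point).
.segment_overlap <- function(p1, p2, q1, q2, tol = 1e-9) {
  d1 <- p2 - p1
  len1 <- sqrt(sum(d1^2))
  if (len1 < tol) return(0)
  u <- d1 / len1
  # both endpoints of q must lie on the infinite line through p1-p2
  for (q in list(q1, q2)) {
    v <- q - p1
    cross <- u[1] * v[2] - u[2] * v[1]
    if (abs(cross) > tol) return(0)
  }
  t1 <- 0; t2 <- len1
  s1 <- sum((q1 - p1) * u); s2 <- sum((q2 - p1) * u)
  lo <- max(min(t1, t2), min(s1, s2))
  hi <- min(max(t1, t2), max(s1, s2))
  max(0, hi - lo)
}

.poly_rings <- function(poly) {
  if (is.matrix(poly)) list(poly) else poly
}

.poly_segments <- function(poly) {
  segs <- list()
  for (ring in .poly_rings(poly)) {
    ring <- as.matrix(ring)
    k <- nrow(ring)
    if (k < 2) next
    # drop duplicated closing vertex handling: iterate consecutive pairs
    for (s in seq_len(k - 1)) {
      segs[[length(segs) + 1L]] <- ring[c(s, s + 1L), , drop = FALSE]
    }
  }
  segs
}

.poly_bbox <- function(poly) {
  xs <- do.call(rbind, .poly_rings(poly))
  c(min(xs[, 1]), min(xs[, 2]), max(xs[, 1]), max(xs[, 2]))
}

.shared_boundary_length <- function(pa, pb, tol = 1e-9) {
  total <- 0
  for (sa in pa) {
    for (sb in pb) {
      total <- total + .segment_overlap(sa[1, ], sa[2, ], sb[1, ], sb[2, ], tol)
    }
  }
  total
}

build_adjacency_polygons <- function(polygons, centroids = NULL, tol = 1e-9) {
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids)) stop("polygons must be uniquely named")
  n <- length(polygons)
  segs <- lapply(polygons, .poly_segments)
  bbox <- t(vapply(polygons, .poly_bbox, numeric(4)))
  ii <- integer(0); jj <- integer(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # bounding-box prefilter
      if (bbox[a, 1] > bbox[b, 3] + tol || bbox[b, 1] > bbox[a, 3] + tol ||
          bbox[a, 2] > bbox[b, 4] + tol || bbox[b, 2] > bbox[a, 4] + tol) next
      if (.shared_boundary_length(segs[[a]], segs[[b]], tol) > tol) {
        ii <- c(ii, a); jj <- c(jj, b)
      }
    }
  }
  if (is.null(centroids)) {
    centroids <- t(vapply(polygons, function(p) {
      ring <- .poly_rings(p)[[1]]
      colMeans(ring[-nrow(ring), , drop = FALSE])
    }, numeric(2)))
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
  area_graph(ids, W, centroids)
}

#' Assign neighbours to island areas
#'
#' Every area with zero neighbours gains at least one symmetric link: the
#' manually specified target when given (the bridge/ferry convention used on
#' real geographies), otherwise the nearest non-island area by centroid
#' distance, with ties broken by lowest area id.  Non-island adjacency is
#' untouched and the operation is idempotent.
#'
#' @param graph an [area_graph].
#' @param manual_links optional named character vector or list mapping
#'   island area id to the id of its assigned neighbour.
#' @return an [area_graph] with no zero-neighbour areas.
#' @export
repair_islands <- function(graph, manual_links = NULL) {
  deg <- graph$neighbour_counts
  islands <- which(deg == 0)
  if (length(islands) == 0) return(graph)
  if (length(islands) == length(graph$area_ids))
    stop("graph consists only of islands; cannot repair")
  W <- graph$W
  mainland <- which(deg > 0)
  for (isl in islands) {
    id <- graph$area_ids[isl]
    if (!is.null(manual_links) && id %in% names(manual_links)) {
      target <- match(as.character(manual_links[[id]]), graph$area_ids)
      if (is.na(target)) stop("manual link for '", id, "' names unknown area")
    } else {
      if (is.null(graph$centroids))
        stop("centroids required to repair islands without manual links")
      d2 <- rowSums((graph$centroids[mainland, , drop = FALSE] -
                       matrix(graph$centroids[isl, ], length(mainland), 2,
                              byrow = TRUE))^2)
      # ties broken deterministically by lowest area id
      best <- mainland[order(d2, graph$area_ids[mainland])][1]
      target <- best
    }
    W[isl, target] <- 1
    W[target, isl] <- 1
  }
  area_graph(graph$area_ids, W, graph$centroids)
}

#' Apply the small-area exclusion filters
#'
#' Removes every record carrying an exclusion flag (no population, no
#' physical location, fewer than five average residents, very remote
#' island) and returns the retained areas.
#'
#' @param fixture a data frame with columns `id` and `flag` (empty string or
#'   `NA` for retained records), e.g. from [generate_exclusion_fixture()].
#' @return list with `retained_ids`, `n_retained`, `n_excluded`, and the
#'   per-flag exclusion table.
#' @export
apply_exclusions <- function(fixture) {
  flag <- as.character(fixture$flag)
  flag[is.na(flag)] <- ""
  keep <- flag == ""
  tab <- table(flag[!keep])
  list(retained_ids = as.character(fixture$id[keep]),
       n_retained = sum(keep),
       n_excluded = sum(!keep),
       excluded_by_flag = tab)
}

#' Read / write adjacency edge lists
#'
#' Sparse triplet CSV with columns `id_a`, `id_b`, one row per undirected
#' edge (each edge listed once).
#'
#' @param graph an [area_graph].
#' @param path file path.
#' @return `write_edges` returns `path` invisibly; `read_edges` a data frame.
#' @export
write_edges <- function(graph, path) {
  tri <- Matrix::which(Matrix::triu(graph$W) != 0, arr.ind = TRUE)
  df <- data.frame(id_a = graph$area_ids[tri[, 1]],
                   id_b = graph$area_ids[tri[, 2]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) read.csv(path, colClasses = "character")
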