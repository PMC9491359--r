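#' 2D Delaunay triangulation (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation of a point set. Points are
#' inserted one at a time; triangles whose circumcircle contains the new
#' point are removed and the resulting cavity is re-triangulated. Cocircular
#' point groups (e.g., the four corners of a square) are resolved
#' arbitrarily but deterministically. Intended for sensor-layout projections
#' (a few hundred points); complexity is O(n^2).
#'
#' @param px,py point coordinates.
#' @return integer matrix with one triangle per row (vertex indices), or an
#'   error if the points are collinear / degenerate.
#' @export
delaunay_triangulation <- function(px, py) {
  n <- length(px)
  if (n < 3) stop("triangulation needs at least 3 points")
  if (anyDuplicated(cbind(px, py)))
    stop("triangulation error: duplicated points")
  # super-triangle enclosing all points with a wide margin
  cx <- mean(range(px)); cy <- mean(range(py))
  # wide margin so circumcircles of hull slivers classify correctly
  r <- max(diff(range(px)), diff(range(py)), 1e-9) * 1e5
  X <- c(px, cx - 2 * r, cx + 2 * r, cx)
  Y <- c(py, cy - r, cy - r, cy + 2 * r)

  circum <- function(i, j, k) {
    ax <- X[i]; ay <- Y[i]; bx <- X[j]; by <- Y[j]; ccx <- X[k]; ccy <- Y[k]
    d <- 2 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by))
    if (abs(d) < 1e-14 * max(abs(c(ax, ay, bx, by, ccx, ccy)), 1)^2)
      return(c(NA_real_, NA_real_, Inf))  # (near-)collinear triangle
    ux <- ((ax^2 + ay^2) * (by - ccy) + (bx^2 + by^2) * (ccy - ay) +
             (ccx^2 + ccy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (ccx - bx) + (bx^2 + by^2) * (ax - ccx) +
             (ccx^2 + ccy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- matrix(circum(n + 1L, n + 2L, n + 3L), 1, 3)
  for (p in seq_len(n)) {
    d2 <- (X[p] - cc[, 1])^2 + (Y[p] - cc[, 2])^2
    bad <- which(d2 < cc[, 3] * (1 - 1e-12))
    if (length(bad) == 0L) {
      # numerically on a circumcircle boundary: take the nearest
      bad <- which.min(d2 - cc[, 3])
    }
    # cavity boundary: edges of bad triangles that appear exactly once
    edges <- rbind(tri[bad, c(1, 2), drop = FALSE],
                   tri[bad, c(2, 3), drop = FALSE],
                   tri[bad, c(3, 1), drop = FALSE])
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), ,
                      drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      newt <- c(boundary[e, 1], boundary[e, 2], p)
      tri <- rbind(tri, newt)
      cc <- rbind(cc, circum(newt[1], newt[2], newt[3]))
    }
  }
  keep <- apply(tri, 1, function(v) all(v <= n))
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0L)
    stop("triangulation error: points are collinear or degenerate")
  dimnames(tri) <- NULL
  tri
}

#' Sensor adjacency from Delaunay triangulation of the 2D projection
#'
#' Triangulates the layout's 2D projection and defines two sensors as
#' neighbors when they share a triangle edge — the standard triangulation
#' neighborhood definition for sensor-space cluster statistics. The graph
#' is symmetric and irreflexive by construction.
#'
#' @param layout a `sensor_layout`.
#' @param method currently only `"delaunay"`.
#' @return a list of class `fpvs_adjacency` with `matrix` (logical
#'   n x n), `neighbors` (list of integer vectors), `sensor` ids, `method`.
#' @examples
#' adj <- build_adjacency(make_layout(32))
#' isSymmetric(adj$matrix * 1)
#' @export
build_adjacency <- function(layout, method = "delaunay") {
  method <- match.arg(method, "delaunay")
  n <- nrow(layout)
  tri <- delaunay_triangulation(layout$px, layout$py)
  A <- matrix(FALSE, n, n)
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    A[tri[, e, drop = FALSE]] <- TRUE
    A[tri[, rev(e), drop = FALSE]] <- TRUE
  }
  diag(A) <- FALSE
  structure(list(matrix = A,
                 neighbors = lapply(seq_len(n), function(i) which(A[i, ])),
                 sensor = layout$sensor,
                 method = method),
            class = "fpvs_adjacency")
}

#' Connected components of a sensor subset under an adjacency graph
#'
#' Breadth-first search over the induced subgraph on `members`.
#'
#' @param adjacency an `fpvs_adjacency` (or a logical adjacency matrix).
#' @param members integer sensor indices.
#' @return list of integer vectors, one per connected component.
#' @export
graph_components <- function(adjacency, members) {
  A <- if (inherits(adjacency, "fpvs_adjacency")) adjacency$matrix
  else adjacency
  members <- sort(unique(as.integer(members)))
  unseen <- rep(TRUE, length(members))
  comps <- list()
  while (any(unseen)) {
    queue <- members[which(unseen)[1]]
    unseen[match(queue, members)] <- FALSE
    comp <- queue
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- members[unseen][A[v, members[unseen]]]
      if (length(nb)) {
        unseen[match(nb, members)] <- FALSE
        comp <- c(comp, nb)
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Is the adjacency graph connected?
#'
#' @param adjacency an `fpvs_adjacency`.
#' @return logical.
#' @export
is_connected <- function(adjacency) {
  n <- nrow(adjacency$matrix)
  length(graph_components(adjacency, seq_len(n))) == 1L
}

#' @export
print.fpvs_adjacency <- function(x, ...) {
  deg <- rowSums(x$matrix)
  cat("<fpvs_adjacency> ", length(x$sensor), " sensors, ",
      sum(x$matrix) / 2, " edges (", x$method, "); degree ",
      min(deg), "-", max(deg), "\n", sep = "")
  invisible(x)
}
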