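## Synthetic source spaces: subdivided icospheres carrying a contiguous
## parcellation, embedded in a voxel grid with a diagonal RAS affine.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  midpoint <- new.env(parent = emptyenv())
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b), sep = "_")
    idx <- midpoint[[key]]
    if (!is.null(idx)) return(idx)
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    v <<- rbind(v, m)
    idx <- nrow(v)
    midpoint[[key]] <- idx
    idx
  }
  nf <- matrix(0L, 4L * nrow(f), 3L)
  r <- 0L
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    nf[r + 1L, ] <- c(a, ab, ca)
    nf[r + 2L, ] <- c(b, bc, ab)
    nf[r + 3L, ] <- c(c, ca, bc)
    nf[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = v, triangles = nf)
}

mesh_adjacency <- function(triangles, n_vertices) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  A <- sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                    x = 1, dims = c(n_vertices, n_vertices))
  A@x[] <- 1
  Matrix::drop0(A)
}

## Multi-source BFS graph distances (in hops) from `sources` on an
## adjacency-list graph; returns per-vertex distance to nearest source.
graph_bfs_dist <- function(nbr, sources) {
  n <- length(nbr)
  d <- rep(Inf, n)
  d[sources] <- 0
  frontier <- sources
  while (length(frontier)) {
    nxt <- unique(unlist(nbr[frontier]))
    nxt <- nxt[d[nxt] > d[frontier[1]] + 0]
    nxt <- nxt[is.infinite(d[nxt])]
    if (!length(nxt)) break
    d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  d
}

## BFS labelling: grow all seeds simultaneously -> contiguous parcels.
grow_parcels <- function(nbr, seeds) {
  n <- length(nbr)
  lab <- integer(n)
  lab[seeds] <- seq_along(seeds)
  frontier <- seeds
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in nbr[[v]]) {
        if (lab[u] == 0L) {
          lab[u] <- lab[v]
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  lab
}

#' Build a toy cortical source space
#'
#' Constructs a closed triangulated surface (subdivided icosahedron, the
#' smallest subdivision level with at least `n_vertices` vertices), a
#' contiguous parcellation of its vertices obtained by seeded
#' farthest-point sampling followed by simultaneous region growing, and a
#' voxel grid with a diagonal voxel-to-mm (RAS) affine in which every
#' near-surface voxel is labelled with the parcel of its nearest vertex.
#'
#' @param n_vertices requested number of vertices (>= 42); the actual count
#'   is the next icosphere size (42, 162, 642, 2562, ...).
#' @param n_parcels number of parcels (<= number of vertices).
#' @param grid_shape integer vector of length 3, voxel grid dimensions.
#' @param seed integer seed controlling parcel seeding.
#' @param radius_mm sphere radius in mm (default 70, roughly brain-sized).
#' @return an object of class `toy_source_space` with fields `vertices`
#'   (V x 3 mm), `triangles` (1-based index triples), `adjacency` (sparse
#'   binary V x V), `parcel_of_vertex`, `grid_shape`, `affine` (4 x 4
#'   voxel->mm, 0-based voxel indices), `parcel_of_voxel` (3-D array,
#'   0 = background), `vertex_of_voxel` (nearest vertex per labelled voxel)
#'   and `n_parcels`.
#' @export
make_source_space <- function(n_vertices, n_parcels, grid_shape = c(20, 20, 20),
                              seed = 1, radius_mm = 70) {
  if (n_vertices < 42) stop_invalid("n_vertices must be >= 42")
  if (n_parcels > n_vertices) stop_invalid("n_parcels cannot exceed n_vertices")
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop_invalid("grid_shape must be 3 integers >= 4")
  mesh <- icosahedron()
  while (nrow(mesh$vertices) < n_vertices) mesh <- subdivide_mesh(mesh)
  storage.mode(mesh$triangles) <- "integer"
  V <- nrow(mesh$vertices)
  vertices <- mesh$vertices * radius_mm
  A <- mesh_adjacency(mesh$triangles, V)
  nbr <- apply(A != 0, 1, which, simplify = FALSE)

  ## farthest-point parcel seeds, then simultaneous BFS growth
  set.seed(sub_seed(seed, 1))
  seeds <- sample.int(V, 1)
  while (length(seeds) < n_parcels) {
    d <- graph_bfs_dist(nbr, seeds)
    cand <- which(d == max(d))
    seeds <- c(seeds, cand[sample.int(length(cand), 1)])
  }
  parcel_of_vertex <- grow_parcels(nbr, seeds)

  ## voxel grid: diagonal affine covering the sphere with a margin
  margin <- 6
  ext <- radius_mm + margin
  spacing <- 2 * ext / grid_shape
  affine <- diag(4)
  affine[cbind(1:3, 1:3)] <- spacing
  affine[1:3, 4] <- -ext + spacing / 2

  ## label voxels whose center lies near the surface with the parcel of
  ## their nearest vertex; always label the voxel containing each vertex
  centers <- voxel_centers(grid_shape, affine)
  shell <- max(spacing) * 1.25
  rad <- sqrt(rowSums(centers^2))
  near <- which(abs(rad - radius_mm) <= shell)
  parcel_of_voxel <- array(0L, dim = grid_shape)
  vertex_of_voxel <- array(0L, dim = grid_shape)
  if (length(near)) {
    nv <- nearest_vertex(centers[near, , drop = FALSE], vertices)
    ok <- sqrt(rowSums((centers[near, , drop = FALSE] -
                          vertices[nv, , drop = FALSE])^2)) <= shell
    parcel_of_voxel[near[ok]] <- parcel_of_vertex[nv[ok]]
    vertex_of_voxel[near[ok]] <- nv[ok]
  }
  vox_idx <- mm_to_voxel(vertices, affine, grid_shape)
  lin <- vox_idx[, 1] + 1L + grid_shape[1] * (vox_idx[, 2] +
           grid_shape[2] * vox_idx[, 3])
  nv2 <- nearest_vertex(centers[lin, , drop = FALSE], vertices)
  parcel_of_voxel[lin] <- parcel_of_vertex[nv2]
  vertex_of_voxel[lin] <- nv2

  structure(list(
    vertices = vertices, triangles = mesh$triangles,
    adjacency = A, parcel_of_vertex = parcel_of_vertex,
    grid_shape = as.integer(grid_shape), affine = affine,
    parcel_of_voxel = parcel_of_voxel, vertex_of_voxel = vertex_of_voxel,
    n_parcels = as.integer(n_parcels), radius_mm = radius_mm,
    neighbors = nbr, seed = as.integer(seed)
  ), class = "toy_source_space")
}

#' @export
print.toy_source_space <- function(x, ...) {
  cat(sprintf("toy_source_space: %d vertices, %d triangles, %d parcels, grid %s\n",
              nrow(x$vertices), nrow(x$triangles), x$n_parcels,
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

## mm centers of all voxels, rows in linear (column-major) voxel order
voxel_centers <- function(grid_shape, affine) {
  idx <- as.matrix(expand.grid(i = 0:(grid_shape[1] - 1),
                               j = 0:(grid_shape[2] - 1),
                               k = 0:(grid_shape[3] - 1)))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

## nearest vertex index per row of `pts`, chunked to bound memory
nearest_vertex <- function(pts, vertices) {
  n <- nrow(pts)
  out <- integer(n)
  v2 <- rowSums(vertices^2)
  chunk <- max(1L, as.integer(2e6 / nrow(vertices)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d <- outer(rowSums(pts[s:e, , drop = FALSE]^2), v2, `+`) -
      2 * pts[s:e, , drop = FALSE] %*% t(vertices)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

## mm -> 0-based voxel index (rounded, clamped to the grid)
mm_to_voxel <- function(pts, affine, grid_shape) {
  inv <- solve(affine)
  v <- sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], `+`)
  v <- round(v)
  for (d in 1:3) v[, d] <- pmin(pmax(v[, d], 0), grid_shape[d] - 1)
  storage.mode(v) <- "integer"
  v
}

#' Generate a synthetic leadfield
#'
#' Seeded Gaussian channel mixing post-multiplied by a graph-smoothing
#' kernel of the mesh adjacency, so that columns of graph-adjacent
#' vertices are spatially coherent (correlated) while the matrix keeps
#' full row rank.
#'
#' @param space a `toy_source_space`.
#' @param n_channels number of channels (>= 8).
#' @param seed integer seed.
#' @param smooth_steps random-walk smoothing steps (default 3).
#' @return C x V numeric matrix of class `leadfield`.
#' @export
make_leadfield <- function(space, n_channels, seed = 1, smooth_steps = 3) {
  if (n_channels < 8) stop_invalid("n_channels must be >= 8")
  V <- nrow(space$vertices)
  set.seed(sub_seed(seed, 2))
  G <- matrix(rnorm(n_channels * V), n_channels, V)
  P <- as.matrix(space$adjacency) + diag(V)
  P <- P / rowSums(P)
  K <- diag(V)
  for (i in seq_len(smooth_steps)) K <- K %*% P
  L <- G %*% K
  structure(L, class = c("leadfield", "matrix", "array"))
}
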