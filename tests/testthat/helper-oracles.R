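# Independent oracles and small frame constructors used across tests.

# periodic minimum-image distance between two points (explicit, scalar)
mi_dist <- function(p, q, box) {
  d <- abs(p - q)
  d <- pmin(d, box - d)
  sqrt(sum(d^2))
}

# Brute-force DBSCAN oracle: full O(N^2) neighbor enumeration, core
# detection, cluster = igraph connected component of the core graph,
# border points attached to the cluster of their NEAREST core point.
oracle_dbscan <- function(xy, box, eps, min_neighbors,
                          include_self = FALSE) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- mi_dist(xy[i, ], xy[j, ], box)
  nb <- d <= eps
  diag(nb) <- include_self
  core <- rowSums(nb) >= min_neighbors
  labels <- rep(-1L, n)
  ci <- which(core)
  if (length(ci)) {
    sub <- nb[ci, ci, drop = FALSE]
    diag(sub) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(g)$membership - 1L
    labels[ci] <- comp
    for (i in which(!core)) {
      near <- ci[nb[i, ci]]
      if (length(near))
        labels[i] <- labels[near[which.min(d[i, near])]]
    }
  }
  labels
}

# canonical relabeling by order of first appearance, for comparing
# partitions up to cluster renumbering
canon_labels <- function(labels) {
  out <- labels
  seen <- integer(0)
  for (i in seq_along(labels)) {
    if (labels[i] < 0L) next
    if (!labels[i] %in% seen) seen <- c(seen, labels[i])
    out[i] <- match(labels[i], seen) - 1L
  }
  as.integer(out)
}

# Brute-force contact oracle: explicit pair enumeration with scalar
# minimum-image distances (slow path, independent of the package's
# vectorized matrix route).
oracle_contacts <- function(xa, xb, box, cutoff) {
  count <- 0L
  for (i in seq_len(nrow(xa)))
    for (j in seq_len(nrow(xb)))
      if (mi_dist(xa[i, ], xb[j, ], box) <= cutoff)
        count <- count + 1L
  count / (nrow(xa) * nrow(xb))
}

# bare frame of free-standing atoms (one molecule per atom)
bare_frame <- function(coords, species, box,
                       atomName = rep("CB", nrow(coords)),
                       element = rep("C", nrow(coords)),
                       resName = species,
                       moleculeId = seq_len(nrow(coords))) {
  MonolayerFrame(coords = coords, atomName = atomName,
                 element = element, resName = resName,
                 species = species, moleculeId = moleculeId, box = box)
}

# frame of n single-chain "phospholipids": each molecule carries a P
# head at z = 2 plus chain-1 first/last markers with the given unit
# direction; water markers locate the midplane at z = 0
chain_frame <- function(directions, box = c(50, 50, 12),
                        chain_len = 1.9) {
  n <- nrow(directions)
  ng <- ceiling(sqrt(n))
  gx <- ((seq_len(n) - 1L) %% ng + 0.5) * box[1] / ng
  gy <- ((seq_len(n) - 1L) %/% ng + 0.5) * box[2] / ng
  p <- cbind(gx, gy, 8)
  c1 <- cbind(gx, gy, 8.2)
  c16 <- c1 + chain_len * directions
  coords <- rbind(p, c1, c16, cbind(box[1] / 2, box[2] / 2, 6))
  MonolayerFrame(
    coords = coords,
    atomName = c(rep("P", n), rep("C22", n), rep("C216", n), "OW"),
    element = c(rep("P", n), rep("C", 2 * n), "O"),
    resName = c(rep("DPPC", 3 * n), "SOL"),
    species = c(rep("DPPC", 3 * n), "WATER"),
    moleculeId = c(rep(seq_len(n), 3), n + 1L),
    box = box)
}

# random marker point set with no structure (for oracle comparisons)
random_points <- function(n, box_l, seed) {
  set.seed(seed)
  cbind(runif(n, 0, box_l), runif(n, 0, box_l))
}

# clustered + noise point set probing the DBSCAN decision boundary
clustered_points <- function(seed, box_l = 12) {
  set.seed(seed)
  n_blobs <- sample(1:3, 1)
  pts <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
    c0 <- runif(2, 1, box_l - 1)
    m <- sample(20:80, 1)
    cbind(c0[1] + rnorm(m, 0, 0.35), c0[2] + rnorm(m, 0, 0.35))
  }))
  gas <- cbind(runif(60, 0, box_l), runif(60, 0, box_l))
  out <- rbind(pts, gas) %% box_l
  out
}

# core-point mask under the periodic eps/min-neighbors rule
core_points <- function(xy, box, eps, min_neighbors) {
  n <- nrow(xy)
  deg <- integer(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && mi_dist(xy[i, ], xy[j, ], box) <= eps)
        deg[i] <- deg[i] + 1L
  deg >= min_neighbors
}

# every labelled border point must lie within eps of a core point
# carrying the same cluster label
borders_valid <- function(labels, xy, box, eps, core) {
  for (i in which(!core & labels >= 0L)) {
    ok <- FALSE
    for (j in which(core))
      if (labels[j] == labels[i] &&
          mi_dist(xy[i, ], xy[j, ], box) <= eps) { ok <- TRUE; break }
    if (!ok) return(FALSE)
  }
  TRUE
}
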