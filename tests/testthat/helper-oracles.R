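# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: components come from igraph on a thresholded
# distance graph, SASA from a randomised (non-deterministic point layout)
# Shrake-Rupley at higher quadrature density, densities from direct counting.

# Connected components of the eps-threshold graph on a distance matrix.
oracle_components <- function(D, eps) {
  n <- nrow(D)
  g <- igraph::graph_from_adjacency_matrix(D <= eps, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# Two labelings describe the same partition?
same_partition <- function(a, b) {
  na <- is.na(a); nb <- is.na(b)
  if (!identical(na, nb)) return(FALSE)
  a <- a[!na]; b <- b[!nb]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(paste(a, b))) == length(unique(b))
}

# Randomised Shrake-Rupley at arbitrary density; independent point layout.
oracle_sasa <- function(frame, target, radii = default_sasa_radii(),
                        probe = 1.4, n_points = 5120, seed = 99) {
  set.seed(seed)
  cls <- frame$beads$size_class
  r <- unname(radii[cls])
  total <- 0
  for (i in target) {
    Ri <- r[i] + probe
    u <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    u <- u / sqrt(rowSums(u^2))
    surf <- sweep(u * Ri, 2, frame$coords[i, ], "+")
    occ <- setdiff(seq_len(nrow(frame$coords)), i)
    acc <- rep(TRUE, n_points)
    for (j in occ) {
      dj <- sqrt(rowSums(sweep(surf, 2, frame$coords[j, ])^2))
      acc <- acc & dj >= r[j] + probe
      if (!any(acc)) break
    }
    total <- total + 4 * pi * Ri^2 * mean(acc)
  }
  total
}

# Single-bead "molecules" frame: entities for clustering oracles.
point_entity_frame <- function(xyz, box = rep(500, 3)) {
  n <- nrow(xyz)
  cg_frame(xyz,
           tibble::tibble(molecule = "P1", mol_id = seq_len(n), bead = "BB",
                          type = "P2", size_class = "regular", charge = 0,
                          mass = 72, heavy_atoms = 4L, role = "backbone",
                          monomer = "M1", monomer_index = 1L),
           box)
}

# Random well-separated blob instances: every blob is mutually within eps
# (fully connected) and has >= min_samples members; no borderline chains.
random_blob_instance <- function(seed, eps = 8, min_blob = 5, max_blob = 12,
                                 n_blobs = NULL) {
  set.seed(seed)
  if (is.null(n_blobs)) n_blobs <- sample(2:6, 1)
  centers <- matrix(stats::runif(3 * n_blobs, 60, 440), n_blobs, 3)
  # push centers apart until pairwise > 5 * eps
  repeat {
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    if (min(d) > 5 * eps) break
    centers <- matrix(stats::runif(3 * n_blobs, 60, 440), n_blobs, 3)
  }
  pts <- list()
  for (b in seq_len(n_blobs)) {
    m <- sample(min_blob:max_blob, 1)
    # all points within a ball of radius eps/2 - margin: mutual dist < eps
    u <- matrix(stats::rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2)) * stats::runif(m, 0, eps / 2 - 0.5)
    pts[[b]] <- sweep(u, 2, centers[b, ], "+")
  }
  do.call(rbind, pts)
}
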