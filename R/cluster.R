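#' Clustering parameters for aggregation analysis
#'
#' DBSCAN over molecular entities with the metric defined as the minimum
#' bead-bead minimum-image distance between two entities. Defaults follow the
#' analysis protocol: eps 8 A, min_samples 5, entities either whole polymers
#' or M1 side-chain groups (one entity per M1 monomer instance).
#'
#' @param eps Neighbourhood radius in A (> 0).
#' @param min_samples Minimum neighbourhood size (including the point itself,
#'   sklearn convention) for a core point; >= 1.
#' @param entity `"polymer"` (all beads of one molecule) or `"m1_sidechain"`
#'   (non-backbone beads of each M1 monomer).
#' @param molecules Optional character vector restricting entities to the
#'   named molecule types (e.g. `"P1"` to count polymers while ignoring
#'   proteins and cargo); `NULL` uses every molecule.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(eps = 8, min_samples = 5,
                           entity = c("polymer", "m1_sidechain"),
                           molecules = NULL) {
  stopifnot(eps > 0, min_samples >= 1)
  structure(list(eps = eps, min_samples = as.integer(min_samples),
                 entity = match.arg(entity), molecules = molecules),
            class = "cluster_params")
}

#' Split a frame into clustering entities
#'
#' @param frame A `cg_frame`.
#' @param entity Entity definition, see [cluster_params()].
#' @param molecules Optional molecule-name filter.
#' @return A list of integer bead-index vectors, one per entity, named by
#'   entity id.
#' @export
frame_entities <- function(frame, entity = "polymer", molecules = NULL) {
  b <- frame$beads
  ok <- if (is.null(molecules)) rep(TRUE, nrow(b)) else b$molecule %in% molecules
  if (entity == "polymer") {
    ids <- unique(b$mol_id[ok])
    out <- lapply(ids, function(id) which(b$mol_id == id & ok))
    if (length(ids)) names(out) <- paste0("mol", ids)
  } else if (entity == "m1_sidechain") {
    sel <- which(b$monomer == "M1" & b$role != "backbone" & ok)
    if (!length(sel)) return(list())
    key <- paste(b$mol_id[sel], b$monomer_index[sel], sep = ".")
    out <- split(sel, factor(key, levels = unique(key)))
    names(out) <- paste0("m1_", names(out))
  } else {
    stop("unknown entity definition '", entity, "'", call. = FALSE)
  }
  out
}

# Minimum bead-bead (minimum-image) distance between every pair of entities.
entity_min_dist <- function(frame, entities) {
  n <- length(entities)
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  ent_id <- integer(nrow(frame$coords))
  for (k in seq_len(n)) ent_id[entities[[k]]] <- k
  used <- which(ent_id > 0L)
  xyz <- frame$coords[used, , drop = FALSE]
  eid <- ent_id[used]
  for (k in seq_len(n - 1L)) {
    mine <- which(eid == k)
    rest <- which(eid > k)
    if (!length(mine) || !length(rest)) next
    d <- pair_min_dist(xyz[mine, , drop = FALSE], xyz[rest, , drop = FALSE],
                       frame$box)
    dm <- apply(d, 2, min)
    mins <- tapply(dm, eid[rest], min)
    idx <- as.integer(names(mins))
    D[k, idx] <- mins
    D[idx, k] <- mins
  }
  D
}

# Classic DBSCAN on a precomputed distance matrix. Cluster ids 1..k in order
# of discovery (entity index order), noise = NA. Border points join the first
# cluster that reaches them (deterministic in index order).
dbscan_precomputed <- function(D, eps, min_samples) {
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))  # includes self
  core <- vapply(nbrs, length, integer(1)) >= min_samples
  labels <- rep(NA_integer_, n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (is.na(labels[q])) labels[q] <- cl
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Density-based aggregation clustering of one frame
#'
#' Runs DBSCAN over the frame's entities using the minimum bead-bead
#' minimum-image distance as the metric. Entities in no cluster are noise
#' (`NA` label); a fully dispersed frame therefore has 0 clusters.
#'
#' @param frame A `cg_frame` with at least one entity.
#' @param params A [cluster_params()].
#' @return A `cluster_result`: list with `labels` (integer vector, `NA` =
#'   noise), `sizes` (tibble `cluster`, `size`), `n_clusters`, `entity`,
#'   `entities` (the bead-index list).
#' @export
cluster_entities <- function(frame, params = cluster_params()) {
  entities <- frame_entities(frame, params$entity, params$molecules)
  if (!length(entities)) {
    stop("frame contains no '", params$entity, "' entities", call. = FALSE)
  }
  D <- entity_min_dist(frame, entities)
  labels <- dbscan_precomputed(D, params$eps, params$min_samples)
  sizes <- if (all(is.na(labels))) {
    tibble::tibble(cluster = integer(), size = integer())
  } else {
    tb <- table(labels)
    tibble::tibble(cluster = as.integer(names(tb)), size = as.integer(tb))
  }
  structure(list(labels = labels, sizes = sizes,
                 n_clusters = nrow(sizes), entity = params$entity,
                 entities = entities),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$labels), " ", x$entity, " entities: ",
      x$n_clusters, " cluster(s), ", sum(is.na(x$labels)), " noise\n",
      sep = "")
  invisible(x)
}

#' Aggregation time series over a trajectory
#'
#' Applies [cluster_entities()] frame by frame and reduces each result to the
#' plotted aggregation observables: cluster count, largest aggregate size and
#' the full size list. Supports both entity definitions so that the
#' polymer-level and M1-side-chain-level traces can be compared.
#'
#' @param trajectory A `cg_trajectory` (or list of `cg_frame`s) with >= 1
#'   frame.
#' @param params A [cluster_params()].
#' @return A tibble with columns `time` (ns), `n_clusters`, `largest_size`,
#'   `n_noise` and a `sizes` list-column.
#' @export
cluster_timeseries <- function(trajectory, params = cluster_params()) {
  stopifnot(length(trajectory) >= 1L)
  purrr::map_dfr(trajectory, function(fr) {
    cr <- cluster_entities(fr, params)
    tibble::tibble(
      time = fr$time,
      n_clusters = cr$n_clusters,
      largest_size = if (nrow(cr$sizes)) max(cr$sizes$size) else 0L,
      n_noise = sum(is.na(cr$labels)),
      sizes = list(cr$sizes$size)
    )
  })
}

#' Micelle core-size histogram
#'
#' Clusters the M1 side-chain entities of a frame (the hydrophobic cores) and
#' tabulates cluster sizes — the per-core count of M1 side chains.
#'
#' @param frame A `cg_frame`.
#' @param params A [cluster_params()]; the entity definition is forced to
#'   `"m1_sidechain"`.
#' @return A tibble with columns `size` (M1 side chains in a core) and `n`
#'   (number of cores of that size).
#' @export
micelle_core_sizes <- function(frame, params = cluster_params()) {
  params$entity <- "m1_sidechain"
  cr <- cluster_entities(frame, params)
  if (!nrow(cr$sizes)) return(tibble::tibble(size = integer(), n = integer()))
  dplyr::count(cr$sizes, size = .data$size, name = "n")
}
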