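test_that("two micelles 30 A apart give two clusters", {
  # surfaces 30 A apart: nearest inter-micelle entity distance ~30 A >> eps
  fr <- make_multicore_aggregate(2, 10, packing = 2 * 27 + 30, seed = 1)
  cr <- cluster_entities(fr, cluster_params(entity = "polymer"))
  expect_equal(cr$n_clusters, 2L)
  expect_equal(sort(cr$sizes$size), c(10L, 10L))
  # oracle: connected components at threshold 8 on the same distance matrix
  ents <- frame_entities(fr, "polymer")
  D <- cgkit:::entity_min_dist(fr, ents)
  expect_true(same_partition(cr$labels, oracle_components(D, 8)))
})

test_that("a fully dispersed frame has zero clusters, all noise", {
  fr <- make_dispersed(20, seed = 2)
  # construction predicate validated independently: all entity distances > 8
  ents <- frame_entities(fr, "polymer")
  D <- cgkit:::entity_min_dist(fr, ents)
  expect_gt(min(D[upper.tri(D)]), 8)
  cr <- cluster_entities(fr)
  expect_equal(cr$n_clusters, 0L)
  expect_true(all(is.na(cr$labels)))
})

test_that("one dense 320-entity aggregate is a single cluster", {
  # dense blob of 320 single-bead entities at ~4 A spacing
  g <- expand.grid(x = 1:8, y = 1:8, z = 1:5)[1:320, ]
  xyz <- as.matrix(g) * 4 + 100
  fr <- point_entity_frame(xyz)
  cr <- cluster_entities(fr)
  expect_equal(cr$n_clusters, 1L)
  expect_equal(cr$sizes$size, 320L)
  expect_equal(sum(is.na(cr$labels)), 0L)
})

test_that("DBSCAN equals threshold-graph components on 50 constructed instances", {
  for (s in 1:50) {
    xyz <- random_blob_instance(s)
    fr <- point_entity_frame(xyz)
    cr <- cluster_entities(fr)
    D <- cgkit:::entity_min_dist(fr, frame_entities(fr, "polymer"))
    comp <- oracle_components(D, 8)
    expect_true(same_partition(cr$labels, comp),
                label = sprintf("instance %d partitions agree", s))
    expect_equal(cr$n_clusters, length(unique(comp)))
  }
})

test_that("the stepwise disassembly series is recovered exactly", {
  tr <- make_disassembly_series(c(80, 60, 40, 20), seed = 5)
  ts <- cluster_timeseries(tr, cluster_params(entity = "polymer",
                                              molecules = "P1"))
  expect_equal(ts$largest_size, c(80L, 60L, 40L, 20L))
  # detached micelles remain intact clusters of 10
  expect_equal(ts$n_clusters, c(1L, 3L, 5L, 7L))
  expect_true(all(ts$n_noise == 0))
})

test_that("a constant single-micelle trajectory has cluster count 1 throughout", {
  mic <- make_micelle(10, seed = 3)
  tr <- cg_trajectory(lapply(0:3, function(t) {
    f <- mic; f$time <- t; f
  }))
  ts <- cluster_timeseries(tr)
  expect_true(all(ts$n_clusters == 1L))
  expect_true(all(ts$largest_size == 10L))
})

test_that("the time series equals frame-wise clustering", {
  tr <- make_disassembly_series(c(30, 20, 10), seed = 8)
  params <- cluster_params(entity = "polymer", molecules = "P1")
  ts <- cluster_timeseries(tr, params)
  for (i in seq_along(tr)) {
    cr <- cluster_entities(tr[[i]], params)
    expect_equal(ts$n_clusters[i], cr$n_clusters)
    expect_equal(ts$largest_size[i],
                 if (nrow(cr$sizes)) max(cr$sizes$size) else 0L)
  }
})

test_that("clustering is invariant to entity relabeling and rigid motion", {
  xyz <- random_blob_instance(99)
  fr <- point_entity_frame(xyz)
  base <- cluster_entities(fr)
  # permute entity order
  set.seed(1)
  perm <- sample(nrow(xyz))
  fr_p <- point_entity_frame(xyz[perm, ])
  cr_p <- cluster_entities(fr_p)
  expect_true(same_partition(base$labels[perm], cr_p$labels))
  # rigid rotation + translation about the cloud centre (stays in the box)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cen <- colMeans(xyz)
  xyz_r <- sweep(sweep(xyz, 2, cen) %*% R, 2, cen + c(5, -3, 2), "+")
  cr_r <- cluster_entities(point_entity_frame(xyz_r))
  expect_true(same_partition(base$labels, cr_r$labels))
})

test_that("clustering respects periodic boundaries", {
  # two half-blobs on opposite faces of the box form one cluster through the
  # boundary; 12 points each so both halves are core-dense
  set.seed(4)
  box <- c(60, 60, 60)
  a <- cbind(stats::runif(12, 0, 2), stats::runif(12, 20, 26),
             stats::runif(12, 20, 26))
  b <- cbind(stats::runif(12, 57.5, 60), stats::runif(12, 20, 26),
             stats::runif(12, 20, 26))
  fr <- point_entity_frame(rbind(a, b), box = box)
  cr <- cluster_entities(fr, cluster_params(eps = 8, min_samples = 5))
  expect_equal(cr$n_clusters, 1L)
  expect_equal(cr$sizes$size, 24L)
})

test_that("micelle core sizes recover constructed core populations exactly", {
  # uniform (5,4,1) chains: a 10-polymer core holds exactly 50 M1 side chains,
  # a 40-polymer core exactly 200
  cons <- list(m1 = c(5, 5), m2 = c(4, 4), m3 = c(1, 1))
  ch10 <- generate_chain_set(10, constraints = cons, seed = 1, balanced = FALSE)
  ch40 <- generate_chain_set(40, constraints = cons, seed = 2, balanced = FALSE)
  fr <- make_multicore_aggregate(2, c(10, 40), packing = 100, seed = 3,
                                 chain_sets = list(ch10, ch40))
  h <- micelle_core_sizes(fr)
  expect_equal(h$size, c(50L, 200L))
  expect_equal(h$n, c(1L, 1L))
  # oracle equivalence on the same frame
  ents <- frame_entities(fr, "m1_sidechain")
  D <- cgkit:::entity_min_dist(fr, ents)
  comp <- oracle_components(D, 8)
  expect_equal(sort(as.integer(table(comp))), c(50L, 200L))
})

test_that("clustering rejects an empty frame", {
  e <- cgkit:::empty_frame(c(50, 50, 50))
  expect_error(cluster_entities(e), "entities")
})
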