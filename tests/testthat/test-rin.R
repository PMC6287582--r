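make_hb_traj <- function(schedules, n_frames) {
  planted <- lapply(schedules, function(s) {
    list(type = "HBOND", formed = list(distance = 2.9, angle = 180),
         broken = list(distance = 4.2, angle = 180), schedule = s)
  })
  make_trajectory(planted, n_frames)
}

frame_graphs_of <- function(sys, types = c("HBOND", "CALPHA")) {
  lapply(seq_along(sys$frames), function(f) {
    build_frame_graph(detect_all(sys, f, enabled_types = types), sys, f)
  })
}

test_that("frame graph groups records into typed edges with counts", {
  sys <- random_system(20, seed = 61)
  rec <- suppressWarnings(detect_all(
    sys, 1, enabled_types = c("CALPHA", "HBOND", "SALT_BRIDGE")))
  fg <- build_frame_graph(rec, sys, 1)
  expect_equal(nrow(fg$nodes), nrow(sys$residues))
  # group-by oracle: one edge per (type, unordered pair), count = records
  key <- paste(rec$type, pmin(rec$res_i, rec$res_j),
               pmax(rec$res_i, rec$res_j))
  expect_equal(nrow(fg$edges), length(unique(key)))
  tab <- table(key)
  got <- setNames(fg$edges$count,
                  paste(fg$edges$type, fg$edges$res_i, fg$edges$res_j))
  expect_equal(sort(names(got)), sort(names(tab)))
  expect_equal(unname(got[names(tab)]), unname(as.numeric(tab)))
  # empty record list keeps all nodes, zero edges
  fg0 <- build_frame_graph(detect_all(sys, 1, enabled_types = character(0)),
                           sys, 1)
  expect_equal(nrow(fg0$edges), 0)
  expect_equal(nrow(fg0$nodes), nrow(sys$residues))
})

test_that("consensus keeps exact persistence fractions and filters on them", {
  sched <- c(rep(TRUE, 8), rep(FALSE, 2))
  sys <- make_hb_traj(list(sched), 10)
  fgs <- frame_graphs_of(sys, "HBOND")
  rin <- build_consensus(fgs, persistence_min = 0.75)
  expect_equal(nrow(rin$edges), 1)
  expect_equal(rin$edges$persistence, 0.8)
  expect_equal(rin$edges$frame_count, 8)
  # 7/10 is dropped at 0.75
  sys7 <- make_hb_traj(list(c(rep(TRUE, 7), rep(FALSE, 3))), 10)
  rin7 <- build_consensus(frame_graphs_of(sys7, "HBOND"), 0.75)
  expect_equal(nrow(rin7$edges), 0)
  # persistence_min = 0 gives the union of frame edge sets
  rin0 <- build_consensus(frame_graphs_of(sys7, "HBOND"), 0)
  expect_equal(nrow(rin0$edges), 1)
})

test_that("9-of-12 frames survives a 0.75 cutoff exactly", {
  sys <- make_hb_traj(list(c(rep(TRUE, 9), rep(FALSE, 3))), 12)
  rin <- build_consensus(frame_graphs_of(sys, "HBOND"), 0.75)
  expect_equal(rin$edges$persistence, 0.75)
  expect_equal(nrow(rin$edges), 1)
})

test_that("consensus is monotone in the cutoff and frame-order invariant", {
  set.seed(71)
  scheds <- lapply(1:4, function(i) runif(20) < 0.6)
  sys <- make_hb_traj(scheds, 20)
  fgs <- frame_graphs_of(sys)
  cuts <- c(0.05, 0.25, 0.5, 0.75, 1)
  sizes <- vapply(cuts, function(p) nrow(build_consensus(fgs, p)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
  perm <- sample(length(fgs))
  a <- build_consensus(fgs, 0.5)
  b <- build_consensus(fgs[perm], 0.5)
  expect_equal(a$edges[, c("res_i", "res_j", "type", "persistence",
                           "distance_mean")],
               b$edges[, c("res_i", "res_j", "type", "persistence",
                           "distance_mean")])
})

test_that("a single static frame reproduces the frame graph exactly", {
  sys <- random_system(15, seed = 81)
  rec <- detect_all(sys, 1, enabled_types = c("CALPHA", "SALT_BRIDGE"))
  fg <- build_frame_graph(rec, sys, 1)
  rin <- build_consensus(list(fg), persistence_min = 1)
  expect_equal(nrow(rin$edges), nrow(fg$edges))
  expect_true(all(rin$edges$persistence == 1))
  expect_equal(rin$edges$distance_mean, fg$edges$distance)
})

test_that("inconsistent node sets across frames are rejected", {
  s1 <- random_system(5, seed = 91)
  s2 <- random_system(6, seed = 92)
  fg1 <- build_frame_graph(detect_all(s1, 1, enabled_types = "CALPHA"), s1, 1)
  fg2 <- build_frame_graph(detect_all(s2, 1, enabled_types = "CALPHA"), s2, 1)
  expect_error(build_consensus(list(fg1, fg2)), "node sets")
})

test_that("edge classification splits intra-chain / inter-chain / inter-assembly", {
  asm <- make_assembly(4, 2, planted = list(
    list(type = "HBOND", chain_i = "A", chain_j = "B",
         params = list(distance = 2.9, angle = 180)),
    list(type = "SALT_BRIDGE", chain_i = "A", chain_j = "C",
         params = list(distance = 3.5)),
    list(type = "PI_PI", chain_i = "D", chain_j = "D",
         params = list(distance = 4.5))
  ))
  rec <- detect_all(asm$system, 1,
                    enabled_types = c("HBOND", "SALT_BRIDGE", "PI_PI"))
  rin <- build_consensus(list(build_frame_graph(rec, asm$system, 1)), 1)
  rin <- classify_edges(rin, asm$assembly_map)
  cc <- rin$class_counts
  expect_equal(cc["HBOND", "INTER_CHAIN"], 1)     # A-B, same assembly
  expect_equal(cc["SALT_BRIDGE", "INTER_ASSEMBLY"], 1)  # A-C crosses
  expect_equal(cc["PI_PI", "INTRA_CHAIN"], 1)
  # conservation: class counts sum to the edge count per type
  expect_equal(sum(cc), nrow(rin$edges))
  for (ty in rownames(cc)) {
    expect_equal(sum(cc[ty, ]), sum(rin$edges$type == ty))
  }
  # without a map, cross-chain edges are INTER_CHAIN
  rin2 <- classify_edges(rin, NULL)
  expect_equal(sum(rin2$class_counts[, "INTER_ASSEMBLY"]), 0)
  bad_map <- asm$assembly_map[-1]
  expect_error(classify_edges(rin, bad_map), "A")
})

test_that("centralities match textbook formulas on closed-form graphs", {
  # path graph a-b-c through two typed edges
  sys <- make_trajectory(list(
    list(type = "HBOND", formed = list(distance = 2.9, angle = 180),
         broken = list(distance = 4.2, angle = 180),
         schedule = TRUE)
  ), 1)
  # build a 3-node path by hand instead: use an assembly fixture
  asm <- make_assembly(3, 1, planted = list(
    list(type = "HBOND", chain_i = "A", chain_j = "B",
         params = list(distance = 2.9, angle = 180)),
    list(type = "SALT_BRIDGE", chain_i = "B", chain_j = "C",
         params = list(distance = 3.5))
  ))
  rec <- detect_all(asm$system, 1, enabled_types = c("HBOND", "SALT_BRIDGE"))
  rin <- build_consensus(list(build_frame_graph(rec, asm$system, 1)), 1)
  cent <- centralities(rin)
  on_path <- cent[cent$degree > 0, ]
  expect_equal(nrow(on_path), 4)  # two pairs share no residue: 2 components
  expect_true(all(on_path$betweenness == 0))
  # K4: complete graph has equal degree everywhere
  sysk <- random_system(4, seed = 101, spacing = 4)
  reck <- detect_all(sysk, 1, enabled_types = "CALPHA")
  rink <- build_consensus(list(build_frame_graph(reck, sysk, 1)), 1)
  if (nrow(rink$edges) == 6) {
    ck <- centralities(rink)
    expect_true(all(ck$degree == 3))
    expect_true(all(abs(ck$eigenvector - 1) < 1e-9))
  }
})

test_that("centralities match an independent implementation on random graphs", {
  for (seed in c(5, 6)) {
    sys <- random_system(15, seed = seed, spacing = 5.5)
    rec <- detect_all(sys, 1, enabled_types = c("CALPHA", "SALT_BRIDGE",
                                                "PI_PI"))
    rin <- build_consensus(list(build_frame_graph(rec, sys, 1)), 1)
    g <- rin_igraph(rin)
    comp <- igraph::components(g)
    if (comp$no > 1) next  # oracle comparison on connected graphs
    el <- igraph::as_edgelist(g, names = FALSE)
    ora <- oracle_centralities(nrow(rin$nodes), el, igraph::E(g)$weight)
    cent <- centralities(rin)
    expect_equal(cent$degree, unname(ora$degree), tolerance = 1e-9)
    expect_equal(cent$weighted_degree, unname(ora$weighted_degree),
                 tolerance = 1e-9)
    expect_equal(cent$betweenness, ora$betweenness, tolerance = 1e-9)
    expect_equal(cent$closeness, ora$closeness, tolerance = 1e-9)
    expect_equal(cent$eigenvector, ora$eigenvector, tolerance = 1e-6)
  }
})

test_that("GraphML write -> read reproduces the network exactly", {
  set.seed(111)
  sys <- make_hb_traj(lapply(1:3, function(i) runif(12) < 0.7), 12)
  fgs <- frame_graphs_of(sys)
  rin <- build_consensus(fgs, 0.25)
  td <- withr::local_tempdir()
  paths <- write_network(rin, td, "t", types = c("HBOND", "CALPHA"))
  back <- read_network(file.path(td, "t_global.graphml"))
  expect_identical(back$nodes$label, rin$nodes$label)
  expect_identical(back$edges$type, rin$edges$type)
  expect_equal(back$edges$persistence, rin$edges$persistence,
               tolerance = 1e-12)
  expect_equal(back$edges$distance_mean, rin$edges$distance_mean,
               tolerance = 1e-12)
  expect_equal(back$n_frames, rin$n_frames)
  # per-type partition: HBOND file holds only HBOND edges
  hb <- read_network(file.path(td, "t_HBOND.graphml"))
  expect_true(all(hb$edges$type == "HBOND"))
  expect_equal(nrow(hb$edges), sum(rin$edges$type == "HBOND"))
  # empty-edge network still round-trips nodes
  rin_empty <- build_consensus(fgs, 1.0)
  rin_empty$edges <- rin_empty$edges[rin_empty$edges$persistence > 2, ]
  write_network(rin_empty, td, "e", types = "HBOND")
  back_e <- read_network(file.path(td, "e_global.graphml"))
  expect_equal(nrow(back_e$edges), 0)
  expect_identical(back_e$nodes$label, rin$nodes$label)
})

test_that("per-residue SASA is positive and roughly additive for far atoms", {
  sys <- make_dipeptide_pair("CALPHA", distance = 30)
  sasa <- shrake_rupley_sasa(sys)
  expect_length(sasa, 2)
  expect_true(all(sasa > 0))
  # two isolated carbon atoms: full sphere area of radius (1.7 + 1.4)
  full <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sasa, c(full, full), tolerance = 1e-6)
})
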