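# Graph construction, shortest-path peptides and TSP peptides.

test_that("design graphs have the expected nodes, edges and symmetry", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 12, 0))
  seg <- point_segments(pts)
  s <- ca_structure(pts)
  g_nat <- build_design_graph(s, seg, "natural")
  expect_equal(igraph::gorder(g_nat), 3)
  expect_equal(igraph::gsize(g_nat), 6) # complete directed
  g_rev <- build_design_graph(s, seg, "reversed")
  expect_equal(igraph::gsize(g_rev), 3) # complete undirected
  # undirected weights are symmetric by construction
  w <- igraph::as_adjacency_matrix(g_rev, attr = "weight", sparse = FALSE)
  expect_equal(w, t(w))
  g_aa <- build_design_graph(s, mode = "aa")
  expect_equal(igraph::gorder(g_aa), nrow(residues(s)))
})

test_that("SHP picks the connected path covering the most residues", {
  # five residues on a line, 3.8 A apart, edges only between neighbours:
  # the 1..5 path covers all five residues
  xyz <- cbind(seq(0, 4) * 3.8, 0, 0)
  s <- ca_structure(xyz)
  g <- build_design_graph(s, mode = "aa", cutoff = 5)
  area <- tibble::tibble(area_id = "vpatch_all", kind = "varying_patch",
                         reference = "A:1:",
                         members = list(residues(s)$key), n_aa = 5)
  p <- design_shp("SHPaa", area, g, structure = s)
  expect_equal(p$final_length, 5L)
  expect_equal(p$positions[[1]]$source_key, residues(s)$key)

  # two-element area: the single path between them
  area2 <- area
  area2$members <- list(residues(s)$key[1:2])
  p2 <- design_shp("SHPaa", area2, g, structure = s)
  expect_equal(p2$final_length, 2L)
})

test_that("a disconnected area yields a degenerate single-element peptide, never an error", {
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  s <- ca_structure(xyz)
  g <- build_design_graph(s, mode = "aa", cutoff = 5) # no edges
  area <- tibble::tibble(area_id = "a", kind = "varying_patch",
                         reference = "A:1:",
                         members = list(residues(s)$key), n_aa = 2)
  p <- design_shp("SHPaa", area, g, structure = s)
  expect_equal(p$final_length, 1L)
})

test_that("TSP ordering matches brute force over all open paths", {
  set.seed(7)
  for (trial in 1:8) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(n * 3, 0, 40), n, 3)
    D <- as.matrix(dist(pts))
    path <- solve_tsp_path(D)
    expect_equal(pepmimic:::path_cost(D, path), brute_force_path_cost(D),
                 tolerance = 1e-9)
  }
})

test_that("TSPaa returns exactly the requested length when the area is large enough", {
  ag <- antigen_structure(make_benchmark_complex(31))
  vp <- build_varying_patches(ag)
  big <- vp[vp$n_aa >= 8, ]
  for (i in seq_len(min(5, nrow(big)))) {
    p <- design_tsp("TSPaa", big[i, ], 8, structure = ag)
    expect_equal(p$final_length, 8L)
    expect_equal(p$status, "ok")
  }
})

test_that("an area smaller than the requested length is returned whole and flagged", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  s <- ca_structure(xyz)
  area <- tibble::tibble(area_id = "a", kind = "varying_patch",
                         reference = "A:1:",
                         members = list(residues(s)$key), n_aa = 3)
  p <- design_tsp("TSPaa", area, 10, structure = s)
  expect_equal(p$final_length, 3L)
  expect_equal(p$status, "short")
})

test_that("TSPnat4 output contains the two closest segments of the area", {
  # segments at 0, 7, 9, 30: the closest pair is (2, 3)
  pts <- rbind(c(0, 0, 0), c(7, 0, 0), c(9, 0, 0), c(30, 0, 0))
  seg <- point_segments(pts)
  area <- tibble::tibble(area_id = "c", kind = "cluster", reference = NA,
                         members = list(1:4), n_aa = 4)
  p <- design_tsp("TSPnat4", area, 2, segments = seg)
  ids <- p$segments_used[[1]]$segment_id
  expect_true(all(c(2, 3) %in% ids))
})

test_that("TSPnat2 picks the run with the shortest traveled distance", {
  # singleton segments on a line with uneven spacing; requested length 2
  # means candidate runs are consecutive pairs; the closest pair wins
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(13, 0, 0), c(25, 0, 0))
  seg <- point_segments(pts)
  area <- tibble::tibble(area_id = "c", kind = "cluster", reference = NA,
                         members = list(1:4), n_aa = 4)
  p <- design_tsp("TSPnat2", area, 2, segments = seg)
  expect_setequal(p$segments_used[[1]]$segment_id, c(2, 3))
  expect_equal(p$path_distance, 3)
})

test_that("SHP peptides ignore the requested length", {
  ag <- antigen_structure(make_benchmark_complex(32))
  model <- surface_model(ag)
  banks <- lapply(c(8, 12, 16), function(L) {
    generate_peptide_bank(ag, methods = "SHPrev", requested_length = L,
                          model = model, score = FALSE)
  })
  expect_equal(banks[[1]]$sequence, banks[[2]]$sequence)
  expect_equal(banks[[2]]$sequence, banks[[3]]$sequence)
})
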