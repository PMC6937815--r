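# Segments, clusters, fixed-radius patches and varying-radius patches.

test_that("segments are maximal runs of accessible residues", {
  s <- make_structure(5, "strand", mask = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  seg <- build_segments(s)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$length, c(2L, 2L))

  s8 <- make_structure(8, "helix", mask = rep(TRUE, 8))
  expect_equal(build_segments(s8)$length, 8L)

  alt <- make_structure(10, "strand", mask = rep(c(TRUE, FALSE), 5))
  seg_alt <- build_segments(alt)
  expect_equal(nrow(seg_alt), 5)
  expect_true(all(seg_alt$length == 1))

  none <- make_structure(4, "strand", mask = rep(FALSE, 4))
  expect_warning(seg0 <- build_segments(none), "no accessible")
  expect_equal(nrow(seg0), 0)
})

test_that("segments partition the accessible residues in chain order", {
  for (seed in c(2, 9, 17)) {
    ag <- antigen_structure(make_benchmark_complex(seed))
    seg <- build_segments(ag)
    res <- residues(ag)
    acc_keys <- res$key[which(res$accessible)]
    seg_keys <- unlist(seg$keys)
    expect_equal(seg_keys, acc_keys) # order and coverage, no duplicates
    expect_equal(paste(seg$sequence, collapse = ""),
                 paste(res$aa[which(res$accessible)], collapse = ""))
  }
})

test_that("segment distances follow the Euclidean formula and are symmetric", {
  pts <- rbind(c(0, 0, 0), c(3, 4, 0))
  seg <- point_segments(pts)
  expect_equal(segment_distance(seg[1, ], seg[2, ]), 5)
  expect_equal(segment_distance(seg[1, ], seg[1, ]), 0)
  expect_equal(segment_distance(seg[1, ], seg[2, ]),
               segment_distance(seg[2, ], seg[1, ]))
  term <- segment_distance(seg[1, ], seg[2, ], anchor = "termini")
  expect_equal(term$dist, 5)
  expect_true(term$pairing %in% c("N1-N2", "N1-C2", "C1-N2", "C1-C2"))
})

test_that("clustering separates distant groups and merges close ones", {
  near <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  far <- sweep(near, 2, c(100, 0, 0), `+`)
  cl2 <- build_clusters(point_segments(rbind(near, far)), cutoff = 20)
  expect_equal(nrow(cl2), 2)
  cl1 <- build_clusters(point_segments(near), cutoff = 20)
  expect_equal(nrow(cl1), 1)
  single <- build_clusters(point_segments(near[1, , drop = FALSE]))
  expect_equal(nrow(single), 1)
  # every segment in exactly one cluster
  expect_setequal(unlist(cl2$members), 1:6)
})

test_that("fixed-radius patches: one per segment, inclusive boundary, 10 within 15", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 14, 0), c(40, 0, 0))
  seg <- point_segments(pts)
  p10 <- build_patches(seg, 10)
  p15 <- build_patches(seg, 15)
  expect_equal(nrow(p10), nrow(seg))
  expect_equal(nrow(p15), nrow(seg))
  # member at exactly the radius is included
  expect_true(2 %in% p10$members[[1]])
  # isolated reference -> only itself
  expect_equal(p10$members[[4]], 4)
  # patch10 subset of patch15 for the same reference
  for (i in seq_len(nrow(seg))) {
    expect_true(all(p10$members[[i]] %in% p15$members[[i]]))
  }
})

test_that("patch membership is preserved under rigid-body motion", {
  ag <- antigen_structure(make_benchmark_complex(4))
  seg1 <- build_segments(ag)
  ag2 <- transform_structure(ag, rotation_z(121), t = c(-3, 8, 2))
  seg2 <- build_segments(ag2)
  p1 <- build_patches(seg1, 15)
  p2 <- build_patches(seg2, 15)
  expect_equal(p1$members, p2$members)
})

test_that("varying patch selects the smallest radius reaching the mean count", {
  # plant counts (10, 12, 14, 16, 18, 20) at radii 15..20 around residue 1
  xyz <- rbind(c(0, 0, 0))
  add_shell <- function(xyz, r, k) {
    ang <- seq(0, pi, length.out = k + 2)[2:(k + 1)]
    rbind(xyz, cbind(r * cos(ang), r * sin(ang), 0))
  }
  xyz <- add_shell(xyz, 14, 9)    # 10 within 15 A (incl. reference)
  for (r in c(15.5, 16.5, 17.5, 18.5, 19.5)) xyz <- add_shell(xyz, r, 2)
  s <- ca_structure(xyz)
  vp <- build_varying_patches(s)
  ref_row <- vp[vp$reference == "A:1:", ]
  expect_equal(ref_row$radius, 18) # first count (16) >= mean (15)
  expect_equal(ref_row$n_aa, 16)

  # uniform counts: the smallest radius already achieves the mean
  s2 <- ca_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)))
  vp2 <- build_varying_patches(s2)
  expect_true(all(vp2$radius == 15))
})

test_that("there is one varying patch per accessible residue", {
  for (seed in c(6, 13)) {
    ag <- antigen_structure(make_benchmark_complex(seed))
    vp <- build_varying_patches(ag)
    expect_equal(nrow(vp), sum(residues(ag)$accessible))
  }
})
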