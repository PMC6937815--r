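# Prime design methods, linker insertion and peptide scoring.

# extended chain with 4-residue segments separated by 2 buried residues:
# segment cogs are spaced along the chain axis
segmented_antigen <- function(n_seg = 4, seg_len = 4, gap = 2) {
  n <- n_seg * seg_len + (n_seg - 1) * gap
  mask <- rep(FALSE, n)
  for (k in seq_len(n_seg)) {
    st <- (k - 1) * (seg_len + gap) + 1
    mask[st:(st + seg_len - 1)] <- TRUE
  }
  make_structure(n, "strand", mask = mask,
                 sequence = paste(rep(LETTERS_AA20, length.out = n),
                                  collapse = ""))
}
LETTERS_AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

test_that("NN alone returns the reference when it already satisfies the length", {
  s <- make_structure(10, "strand", mask = rep(TRUE, 10))
  seg <- build_segments(s)
  p <- design_nn(seg, 1, 8)
  expect_equal(p$final_length, 10L)
  expect_equal(nrow(p$segments_used[[1]]), 1)
  expect_equal(p$sequence, seg$sequence[1])
})

test_that("NN appends segments in order of spatial proximity (chained)", {
  s <- segmented_antigen(4)
  seg <- build_segments(s)
  p <- design_nn(seg, 1, 16)
  # along an extended chain the spatial order is the chain order
  expect_equal(p$segments_used[[1]]$segment_id, 1:4)
  # exhaustive distance re-check of each greedy choice
  cogs <- lapply(seg$cog, identity)
  used <- 1L
  while (length(used) < 4) {
    rest <- setdiff(1:4, used)
    d <- vapply(rest, function(j) {
      sqrt(sum((cogs[[used[length(used)]]] - cogs[[j]])^2))
    }, numeric(1))
    used <- c(used, rest[which.min(d)])
  }
  expect_equal(p$segments_used[[1]]$segment_id, used)
})

test_that("overshooting segments are added whole (final length >= requested)", {
  s <- segmented_antigen(4)
  seg <- build_segments(s)
  for (L in c(5, 9, 13)) {
    p <- design_nn(seg, 2, L)
    expect_gte(p$final_length, L)
    expect_equal(p$final_length %% 4, 0) # whole 4-residue segments only
  }
})

test_that("uNN reverses a segment whose C-terminus is nearer the growing end", {
  # chain A runs +x; chain B is chain A rotated 180 deg so B's C-terminus
  # faces A's C-terminus
  a <- make_structure(4, "strand", chain = "A", mask = rep(TRUE, 4))
  b <- make_structure(4, "strand", chain = "B", mask = rep(TRUE, 4))
  b <- transform_structure(b, rotation_z(180), t = c(30, 2, 0))
  comb <- new_pep_structure(
    dplyr::bind_rows(atoms(a)[, -match("key", names(atoms(a)))],
                     atoms(b)[, -match("key", names(atoms(b)))]),
    id = "two-chain")
  comb <- set_accessibility(comb, rep(TRUE, 8))
  seg <- build_segments(comb)
  expect_equal(nrow(seg), 2)
  p <- design_unn(seg, 1, 8)
  su <- p$segments_used[[1]]
  # independent re-check of the four end-to-end distances
  dNN <- sqrt(sum((seg$cterm_ca[[1]] - seg$nterm_ca[[2]])^2))
  dCC <- sqrt(sum((seg$cterm_ca[[1]] - seg$cterm_ca[[2]])^2))
  expect_true(dCC < dNN)
  expect_equal(su$orientation[2], "reversed")
  expect_equal(p$sequence,
               paste0(seg$sequence[1],
                      paste(rev(strsplit(seg$sequence[2], "")[[1]]),
                            collapse = "")))
  # provenance of the reversed segment runs C -> N
  pos <- p$positions[[1]]
  rev_keys <- pos$source_key[pos$segment_id == 2]
  expect_equal(rev_keys, rev(seg$keys[[2]]))
})

test_that("uNN keeps natural sense on a tie", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0))
  seg <- point_segments(pts) # singleton segments: N and C coincide
  p <- design_unn(seg, 1, 2)
  expect_true(all(p$segments_used[[1]]$orientation == "natural"))
})

test_that("FN keeps the reference centrally placed", {
  s <- segmented_antigen(5)
  seg <- build_segments(s)
  p <- design_fn(seg, 3, 20)
  su <- p$segments_used[[1]]$segment_id
  ref_pos <- which(su == 3)
  expect_lte(abs(ref_pos - (length(su) + 1) / 2), 1)
  # two neighbours, one strictly closer: the closer is appended C-terminally
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(18, 0, 0))
  seg3 <- point_segments(pts)
  p2 <- design_fn(seg3, 2, 3)
  expect_equal(p2$segments_used[[1]]$segment_id, c(1, 2, 3))
  # reference offset from the peptide centre <= max segment length
  centre <- (p$final_length + 1) / 2
  ref_keys <- p$positions[[1]]$pos[p$positions[[1]]$segment_id == 3]
  expect_lte(min(abs(ref_keys - centre)), max(seg$length))
})

test_that("optimised orderings match brute-force enumeration and beat greedy", {
  set.seed(42)
  for (trial in 1:10) {
    n <- sample(3:6, 1)
    pts <- matrix(runif(n * 3, 0, 30), n, 3)
    seg <- point_segments(pts)
    p <- design_optimized(seg, 1, n, "ONN")
    D <- as.matrix(dist(pts))
    expect_equal(p$path_distance, brute_force_path_cost(D),
                 tolerance = 1e-9)
    greedy <- design_nn(seg, 1, n)
    expect_lte(p$path_distance, greedy$path_distance + 1e-9)
  }
  # single segment: identity
  one <- point_segments(matrix(0, 1, 3))
  expect_equal(design_optimized(one, 1, 1, "ONN")$segments_used[[1]]$segment_id, 1L)
})

test_that("OPP orders exactly the 10 A patch members of the reference", {
  pts <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 8, 0), c(25, 0, 0))
  seg <- point_segments(pts)
  p <- design_optimized(seg, 1, 99, "OPP")
  expect_setequal(p$segments_used[[1]]$segment_id, c(1, 2, 3))
})

test_that("ONN uses the same segment multiset as NN", {
  s <- segmented_antigen(5)
  seg <- build_segments(s)
  for (L in c(8, 12, 16)) {
    nn <- design_nn(seg, 2, L)
    onn <- design_optimized(seg, 2, L, "ONN")
    expect_setequal(onn$segments_used[[1]]$segment_id,
                    nn$segments_used[[1]]$segment_id)
  }
})

# two 2-residue segments with an exactly known junction gap
gap_structure <- function(gap) {
  row <- function(resno, elety, x) {
    data.frame(chain = "A", resno = resno, aa = "G", elety = elety,
               x = x, y = ifelse(elety == "CA", 0.5, 0), z = 0)
  }
  spec <- rbind(
    row(1, "N", -5), row(1, "CA", -4.5), row(1, "C", -4),
    row(2, "N", -1), row(2, "CA", -0.5), row(2, "C", 0),
    row(4, "N", gap), row(4, "CA", gap + 0.5), row(4, "C", gap + 1),
    row(5, "N", gap + 4), row(5, "CA", gap + 4.5), row(5, "C", gap + 5)
  )
  make_point_structure(spec)
}

test_that("alanine linker count follows the peptide-bond gap rule", {
  for (case in list(list(gap = 3.8, n = 0), list(gap = 11.4, n = 2),
                    list(gap = 7.6, n = 1), list(gap = 1.0, n = 0))) {
    s <- gap_structure(case$gap)
    seg <- build_segments(s)
    expect_equal(nrow(seg), 2)
    p <- design_nn(seg, 1, 4)
    pa <- add_linkers(p, "ALA", s, seg)
    ins <- pa$positions[[1]]
    expect_equal(sum(ins$origin == "ALA"), case$n)
    if (case$n > 0) {
      expect_true(all(ins$aa[ins$origin == "ALA"] == "A"))
    }
    # verify the formula independently
    expect_equal(case$n, max(0, round(case$gap / 3.8) - 1))
  }
})

test_that("stripping linker positions recovers the prime peptide", {
  ag <- antigen_structure(make_benchmark_complex(21))
  seg <- build_segments(ag)
  pb_cache <- pepmimic:::pb_labels_by_key(ag)
  for (ref in seg$segment_id) {
    base <- design_nn(seg, ref, 12)
    for (lk in c("ALA", "SA", "SAS")) {
      lp <- add_linkers(base, lk, ag, seg, pb_cache = pb_cache)
      if (lp$status == "not_possible") next
      pos <- lp$positions[[1]]
      stripped <- paste(pos$aa[pos$origin == "segment"], collapse = "")
      expect_equal(stripped, base$sequence)
      expect_equal(pos$source_key[pos$origin == "segment"],
                   base$positions[[1]]$source_key)
    }
  }
})

test_that("SAS inserts exactly one residue per junction", {
  ag <- antigen_structure(make_benchmark_complex(22))
  seg <- build_segments(ag)
  base <- design_nn(seg, seg$segment_id[1], 14)
  n_junction <- nrow(base$segments_used[[1]]) - 1
  ps <- add_linkers(base, "SAS", ag, seg)
  expect_equal(sum(ps$positions[[1]]$origin == "SAS"), n_junction)
})

test_that("an unbridgeable SA junction marks the peptide not possible", {
  s <- gap_structure(6)
  seg <- build_segments(s)
  p <- design_nn(seg, 1, 4)
  # plant junction PB labels that the bundled matrix cannot bridge
  trans <- pb_transitions()
  labels <- rownames(trans)
  bridge2 <- (trans > 0) %*% (trans > 0)
  bridge3 <- bridge2 %*% (trans > 0)
  bad <- which(trans == 0 & bridge2 == 0 & bridge3 == 0, arr.ind = TRUE)
  skip_if(nrow(bad) == 0, "bundled matrix bridges every pair")
  cache <- setNames(c(NA, labels[bad[1, 1]], labels[bad[1, 2]], NA),
                    c("A:1:", "A:2:", "A:4:", "A:5:"))
  psa <- add_linkers(p, "SA", s, seg, pb_cache = cache)
  expect_equal(psa$status, "not_possible")
})

test_that("segment score follows Ss = Naa + Naccess + Nhyd + Nwryp + Nturn", {
  spec <- rbind(
    data.frame(chain = "A", resno = 1, aa = "G", elety = "CA",
               x = 0, y = 0, z = 0),
    data.frame(chain = "A", resno = 2, aa = "G", elety = "CA",
               x = 3.8, y = 0, z = 0)
  )
  s <- make_point_structure(spec)
  s$residues$sasa_rel <- 0.5 # both 50% accessible
  seg <- build_segments(s)
  p <- design_nn(seg, 1, 2)
  p <- score_peptide(p, s, turns = FALSE)
  expect_equal(p$score, 2 + 5 + 0 + 0 + 0)

  # adding a tryptophan raises the segment score by at least 2
  s2 <- make_point_structure(rbind(
    spec, data.frame(chain = "A", resno = 3, aa = "W", elety = "CA",
                     x = 7.6, y = 0, z = 0)))
  s2$residues$sasa_rel <- 0.5
  seg2 <- build_segments(s2)
  p2 <- score_peptide(design_nn(seg2, 1, 3), s2, turns = FALSE)
  expect_gte(p2$score, p$score + 2)
})

test_that("the peptide score is additive over segments", {
  ag <- antigen_structure(make_benchmark_complex(23))
  seg <- build_segments(ag)
  turns <- assign_turns(ag)
  p <- design_nn(seg, seg$segment_id[1], 15)
  sp <- score_peptide(p, ag, turns = turns)
  # recompute each segment in isolation
  parts <- vapply(p$segments_used[[1]]$segment_id, function(id) {
    single <- design_nn(seg, id, 1)
    score_peptide(single, ag, turns = turns)$score
  }, numeric(1))
  expect_equal(sp$score, sum(parts), tolerance = 1e-9)
})

test_that("a helical stretch scores turn residues", {
  s <- compute_accessibility(make_structure(12, "helix"))
  turns <- assign_turns(s)
  expect_gt(sum(turns), 0) # alpha-helical H-bonds are 4-turns
})
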