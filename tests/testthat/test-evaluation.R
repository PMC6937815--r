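# Se/PPV evaluation, method summaries, size analysis and chance baselines.

test_that("composition evaluation follows the multiset Se/PPV formulas", {
  ep <- toy_epitope(c("A", "K", "D"))
  r <- evaluate_composition("AKGG", ep)
  expect_equal(r$tp, 2L)
  expect_equal(r$se, 2 / 3)
  expect_equal(r$ppv, 2 / 4)

  # a peptide with exactly the epitope composition is perfect
  perfect <- evaluate_composition("DAK", ep)
  expect_equal(perfect$se, 1)
  expect_equal(perfect$ppv, 1)

  # empty inputs are flagged, not crashed
  r0 <- evaluate_composition("", ep)
  expect_true(is.na(r0$se))
})

test_that("composition evaluation is order-invariant, position-aware is not", {
  ep <- toy_epitope(c("A", "C", "D"), keys = c("A:1:", "A:2:", "A:3:"))
  mk <- function(aa, keys) {
    pepmimic:::new_peptide("toy", "r", 3, tibble::tibble(
      segment_id = 1L, orientation = "natural"),
      tibble::tibble(pos = seq_along(aa), aa = aa, source_key = keys,
                     origin = "segment", segment_id = 1L))
  }
  p1 <- mk(c("A", "C", "D"), c("A:1:", "A:2:", "A:3:"))
  # same letters, but sourced from non-epitope residues
  p2 <- mk(c("D", "C", "A"), c("A:9:", "A:8:", "A:7:"))
  expect_equal(evaluate_composition(p1, ep)$se,
               evaluate_composition(p2, ep)$se)
  expect_equal(evaluate_position_aware(p1, ep)$se, 1)
  # composition still credits the letters; position-aware does not
  expect_equal(evaluate_position_aware(p2, ep)$tp, 0L)
})

test_that("a peptide built from epitope residues in any order is perfect position-aware", {
  ep <- toy_epitope(c("W", "K", "D", "F"))
  keys <- rev(ep$key)
  p <- pepmimic:::new_peptide("toy", "r", 4, tibble::tibble(
    segment_id = 1L, orientation = "natural"),
    tibble::tibble(pos = 1:4, aa = rev(ep$aa), source_key = keys,
                   origin = "segment", segment_id = 1L))
  r <- evaluate_position_aware(p, ep)
  expect_equal(r$se, 1)
  expect_equal(r$ppv, 1)
})

test_that("linker positions are credited only after sourced positions", {
  ep <- toy_epitope(c("A", "K"), keys = c("A:1:", "A:2:"))
  p <- pepmimic:::new_peptide("toy", "r", 3, tibble::tibble(
    segment_id = 1L, orientation = "natural"),
    tibble::tibble(pos = 1:3, aa = c("A", "A", "K"),
                   source_key = c(NA, "A:5:", "A:2:"),
                   origin = c("ALA", "segment", "segment"),
                   segment_id = c(NA, 1L, 1L)))
  r <- evaluate_position_aware(p, ep)
  # sourced K credits A:2:; the alanine linker then matches epitope A
  expect_equal(r$tp, 2L)
})

test_that("method performance applies a strict > threshold on both metrics", {
  res <- tibble::tibble(
    method = "m", mode = "composition", antigen = c("x", "x", "y"),
    sequence = c("a", "b", "c"), final_length = 10L,
    se = c(0.7, 0.8, 0.9), ppv = c(0.9, 0.7, 0.8), epitope_size = 10L
  )
  mp <- method_performance(res, threshold = 0.7)
  # se == 0.7 and ppv == 0.7 both fail the strict inequality
  expect_equal(mp$prop_above, 1 / 3)
  expect_equal(mp$n_antigens_hit, 1L)

  # prop_above is non-increasing in the threshold
  ag <- antigen_structure(make_benchmark_complex(51))
  bank <- generate_peptide_bank(ag, c("NN", "TSPaa"))
  ev <- evaluate_bank(bank, extract_epitope(make_benchmark_complex(51)))
  p07 <- method_performance(ev, 0.7)$prop_above
  p08 <- method_performance(ev, 0.8)$prop_above
  expect_true(all(p08 <= p07))
})

test_that("a bank made of the epitopes themselves yields perfect summaries", {
  ep <- toy_epitope(c("A", "K", "D", "W", "F"))
  p <- pepmimic:::new_peptide("epitope", "r", 5, tibble::tibble(
    segment_id = 1L, orientation = "natural"),
    tibble::tibble(pos = 1:5, aa = ep$aa, source_key = ep$key,
                   origin = "segment", segment_id = 1L))
  p$antigen <- "x"
  ev <- evaluate_bank(p, ep)
  mp <- method_performance(ev)
  expect_true(all(mp$prop_above == 1))
  expect_true(all(mp$n_antigens_hit == 1))
})

test_that("size-difference analysis bins on the absolute difference", {
  res <- tibble::tibble(
    method = "m", mode = "composition", antigen = "x",
    sequence = letters[1:4], final_length = c(10L, 13L, 7L, 10L),
    se = c(0.9, 0.9, 0.9, 0.2), ppv = c(0.9, 0.9, 0.9, 0.2),
    epitope_size = 10L
  )
  sd <- size_difference_analysis(res)
  expect_equal(sd$size_diff, c(0, 3))
  # +3 and -3 share one bin
  expect_equal(sd$n_peptides[sd$size_diff == 3], 2L)
  expect_equal(sd$n_qualifying[sd$size_diff == 0], 1L)
})

test_that("the random baseline reflects the antigen composition and the seed", {
  ag <- make_structure(20, "strand",
                       sequence = paste(rep(c("A", "K"), 10), collapse = ""))
  ag <- set_accessibility(ag, rep(TRUE, 20))
  r1 <- random_baseline(ag, 50, lengths = 10:14, seed = 99)
  r2 <- random_baseline(ag, 50, lengths = 10:14, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(strsplit(paste(r1$sequence, collapse = ""), "")[[1]]
                  %in% c("A", "K")))

  # degenerate composition: an all-alanine antigen gives all-Ala peptides
  mono <- set_accessibility(make_structure(10, "helix"), rep(TRUE, 10))
  rm <- random_baseline(mono, 5, lengths = 8, seed = 1)
  expect_true(all(grepl("^A+$", rm$sequence)))

  # law of large numbers: 1e5 sampled positions match the composition to 1%
  big <- random_baseline(ag, 10000, lengths = 10, seed = 7)
  freq <- table(strsplit(paste(big$sequence, collapse = ""), "")[[1]])
  expect_equal(unname(freq["A"] / sum(freq)), 0.5, tolerance = 0.02)
})

test_that("chance probability reduces to the closed forms", {
  ag <- set_accessibility(
    make_structure(10, "strand",
                   sequence = paste(c(rep("A", 4), rep("K", 3),
                                      rep("D", 2), "Y"), collapse = "")),
    rep(TRUE, 10))
  # single residue: n_X / n
  expect_equal(chance_probability("A", ag), 4 / 10)
  expect_equal(chance_probability("Y", ag), 1 / 10)
  # impossible composition
  expect_equal(chance_probability("YY", ag), 0)

  # all-distinct protein: P(any k-sequence of distinct residues) = (n-k)!/n!
  dist10 <- set_accessibility(
    make_structure(10, "strand", sequence = "ACDEFGHIKL"), rep(TRUE, 10))
  expect_equal(chance_probability("ACD", dist10),
               factorial(7) / factorial(10))
})

test_that("chance probabilities sum to one over all orderable selections", {
  ag <- set_accessibility(
    make_structure(6, "strand", sequence = "AAKKDY"), rep(TRUE, 6))
  letters_here <- c("A", "K", "D", "Y")
  for (P in c(1, 2, 3, 6)) {
    seqs <- do.call(expand.grid,
                    c(rep(list(letters_here), P),
                      stringsAsFactors = FALSE))
    total <- sum(apply(seqs, 1, function(ch) {
      chance_probability(paste(ch, collapse = ""), ag)
    }))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})
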