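# Open-path travelling-salesman ordering of surface elements.
#
# Exact dynamic programming (Held-Karp) up to a size limit, then greedy
# nearest-neighbour construction refined by 2-opt. Distance matrices may be
# asymmetric (the "natural" segment graph is directed).

path_cost <- function(D, path) {
  if (length(path) < 2) return(0)
  sum(D[cbind(path[-length(path)], path[-1])])
}

held_karp_path <- function(D) {
  n <- nrow(D)
  if (n == 1) return(1L)
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, nrow = full, ncol = n)
  parent <- matrix(NA_integer_, nrow = full, ncol = n)
  for (j in seq_len(n)) {
    dp[bitwShiftL(1L, j - 1L), j] <- 0
  }
  masks <- order(vapply(seq_len(full), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0), numeric(1)))
  for (mask in masks) {
    bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0)
    if (length(bits) < 2) next
    for (j in bits) {
      prev_mask <- mask - bitwShiftL(1L, j - 1L)
      ks <- bits[bits != j]
      cand <- dp[prev_mask, ks] + D[ks, j]
      b <- which.min(cand)
      if (cand[b] < dp[mask, j]) {
        dp[mask, j] <- cand[b]
        parent[mask, j] <- ks[b]
      }
    }
  }
  j <- which.min(dp[full, ])
  path <- integer(n)
  mask <- full
  for (i in n:1) {
    path[i] <- j
    pj <- parent[mask, j]
    mask <- mask - bitwShiftL(1L, j - 1L)
    j <- pj
  }
  path
}

nn_two_opt_path <- function(D, max_pass = 50) {
  n <- nrow(D)
  best <- NULL
  best_cost <- Inf
  for (start in seq_len(n)) {
    path <- start
    left <- setdiff(seq_len(n), start)
    while (length(left) > 0) {
      d <- D[path[length(path)], left]
      nxt <- left[which.min(d)]
      path <- c(path, nxt)
      left <- setdiff(left, nxt)
    }
    cost <- path_cost(D, path)
    if (cost < best_cost) {
      best <- path
      best_cost <- cost
    }
  }
  # 2-opt: reverse sub-paths while it improves (recomputed cost handles
  # asymmetric matrices)
  improved <- TRUE
  pass <- 0
  while (improved && pass < max_pass) {
    improved <- FALSE
    pass <- pass + 1
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cand <- best
        cand[i:j] <- rev(cand[i:j])
        cc <- path_cost(D, cand)
        if (cc < best_cost - 1e-12) {
          best <- cand
          best_cost <- cc
          improved <- TRUE
        }
      }
    }
  }
  best
}

#' Minimum-distance open path over a distance matrix
#'
#' @param D square distance matrix (rows/columns in element order); may be
#'   asymmetric.
#' @param exact_limit exact dynamic programming is used up to this many
#'   elements; larger instances fall back to nearest-neighbour construction
#'   plus 2-opt refinement.
#' @return integer vector: the visiting order (indices into `D`). For
#'   symmetric matrices the direction is canonicalised to the
#'   lexicographically smaller of the path and its reverse.
#' @export
solve_tsp_path <- function(D, exact_limit = 12) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  path <- if (n <= exact_limit) held_karp_path(D) else nn_two_opt_path(D)
  symmetric <- isTRUE(all.equal(D, t(D), tolerance = 1e-9,
                                check.attributes = FALSE))
  if (symmetric) {
    rp <- rev(path)
    if (paste(rp, collapse = ",") < paste(path, collapse = ",")) {
      path <- rp
    }
  }
  path
}
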