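#' Permutation schedule
#'
#' The null-model schedule: `total` chained permutations per period, the
#' first `burn_in` discarded, `keep = total - burn_in` retained, and (for
#' datastream permutations) `swaps` successful checkerboard flips per chain
#' step. The default (300, 200, 100, 20) is the schedule of the analysis the
#' package replicates.
#'
#' @param total Total permutations per period.
#' @param burn_in Discarded initial permutations.
#' @param keep Retained permutations (must equal `total - burn_in`).
#' @param swaps Checkerboard flips per datastream step.
#' @param method `"datastream"` or `"node"`.
#' @param rng_seed Chain seed.
#' @return List of class `perm_schedule`.
#' @export
permutation_schedule <- function(total = 300, burn_in = 200,
                                 keep = total - burn_in, swaps = 20,
                                 method = c("datastream", "node"),
                                 rng_seed = 1L) {
  method <- match.arg(method)
  if (keep != total - burn_in) {
    stop("permutation_schedule: keep must equal total - burn_in",
         call. = FALSE)
  }
  if (any(c(total, burn_in, keep, swaps) <= 0)) {
    stop("permutation_schedule: all counts must be positive", call. = FALSE)
  }
  structure(list(total = total, burn_in = burn_in, keep = keep,
                 swaps = swaps, method = method,
                 rng_seed = as.integer(rng_seed)),
            class = "perm_schedule")
}

#' One datastream permutation step (checkerboard swaps)
#'
#' Performs `n_swaps` successful checkerboard flips on a group-by-individual
#' matrix: a pair of rows (g, h) and columns (i, j) showing the pattern
#' `[[1,0],[0,1]]` is flipped to `[[0,1],[1,0]]`, swapping two observations
#' between individuals while preserving every row sum (subgroup size) and
#' column sum (sightings per individual) exactly. Swaps stay inside the
#' period's matrix.
#'
#' @param gbi Binary group-by-individual matrix (>= 2 rows and columns).
#' @param n_swaps Number of successful flips to perform.
#' @param max_tries Bound on candidate draws before giving up.
#' @return The permuted matrix.
#' @export
datastream_swap_step <- function(gbi, n_swaps = 20, max_tries = 100000) {
  if (nrow(gbi) < 2 || ncol(gbi) < 2) {
    stop("datastream_swap_step: need >= 2 rows and columns", call. = FALSE)
  }
  ones <- which(gbi == 1L)
  if (length(ones) < 2) {
    stop("datastream_swap_step: no swappable submatrix", call. = FALSE)
  }
  nr <- nrow(gbi)
  done <- 0
  tries <- 0
  while (done < n_swaps) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("datastream_swap_step: no swappable submatrix found within the ",
           "search bound", call. = FALSE)
    }
    pick <- sample.int(length(ones), 2)
    a <- ones[pick[1]]; b <- ones[pick[2]]
    ra <- (a - 1L) %% nr + 1L; ca <- (a - 1L) %/% nr + 1L
    rb <- (b - 1L) %% nr + 1L; cb <- (b - 1L) %/% nr + 1L
    if (ra == rb || ca == cb) next
    if (gbi[ra, cb] == 1L || gbi[rb, ca] == 1L) next
    gbi[ra, ca] <- 0L; gbi[rb, cb] <- 0L
    gbi[ra, cb] <- 1L; gbi[rb, ca] <- 1L
    ones[pick[1]] <- ra + (cb - 1L) * nr
    ones[pick[2]] <- rb + (ca - 1L) * nr
    done <- done + 1
  }
  gbi
}

#' Chained datastream permutations for one period
#'
#' The observed matrix seeds the chain: each successive state re-permutes
#' the previous one with `schedule$swaps` checkerboard flips, so matrices
#' become progressively more randomized; the first `burn_in` states are
#' discarded and the remaining `keep` states are converted to SRI matrices.
#'
#' @param gbi Observed group-by-individual matrix.
#' @param schedule A `perm_schedule` with `method = "datastream"`.
#' @return List of class `permuted_set`: `method`, `sri` (list of `keep` SRI
#'   matrices), `gbi` (the corresponding GBI states), `chain_index`.
#' @export
datastream_chain <- function(gbi, schedule) {
  stopifnot(inherits(schedule, "perm_schedule"),
            schedule$method == "datastream")
  set.seed(schedule$rng_seed)
  kept_sri <- vector("list", schedule$keep)
  kept_gbi <- vector("list", schedule$keep)
  state <- gbi
  for (s in seq_len(schedule$total)) {
    state <- datastream_swap_step(state, schedule$swaps)
    if (s > schedule$burn_in) {
      k <- s - schedule$burn_in
      kept_gbi[[k]] <- state
      kept_sri[[k]] <- sri_matrix(state)
    }
  }
  structure(list(method = "datastream", sri = kept_sri, gbi = kept_gbi,
                 chain_index = seq_len(schedule$keep) + schedule$burn_in),
            class = "permuted_set")
}

#' Node-label permutation of a network matrix
#'
#' Applies one random permutation jointly to rows and columns — entry (i, j)
#' moves to (pi(i), pi(j)) — redistributing individuals over network
#' positions while leaving the association structure (the multiset of
#' entries, and each node position's edges) untouched.
#'
#' @param mat Square matrix with id dimnames.
#' @param perm Optional explicit permutation (integer vector); drawn
#'   uniformly if missing.
#' @return The relabeled matrix (dimnames preserved in original order).
#' @export
node_permute <- function(mat, perm = NULL) {
  n <- nrow(mat)
  if (is.null(perm)) perm <- sample.int(n)
  out <- mat
  out[perm, perm] <- mat
  dimnames(out) <- dimnames(mat)
  out
}

#' Chained node-label permutations for one period
#'
#' Applies `total` sequentially composed relabelings and keeps the last
#' `keep` states, mirroring the datastream schedule procedurally (the
#' composition of uniform permutations is itself uniform; the chain form is
#' retained for fidelity to the replicated procedure).
#'
#' @param mat Observed matrix (e.g. grooming counts or SRI).
#' @param schedule A `perm_schedule` with `method = "node"`.
#' @return List of class `permuted_set`: `method`, `matrices`, `chain_index`.
#' @export
node_chain <- function(mat, schedule) {
  stopifnot(inherits(schedule, "perm_schedule"), schedule$method == "node")
  set.seed(schedule$rng_seed)
  kept <- vector("list", schedule$keep)
  state <- mat
  for (s in seq_len(schedule$total)) {
    state <- node_permute(state)
    if (s > schedule$burn_in) kept[[s - schedule$burn_in]] <- state
  }
  structure(list(method = "node", matrices = kept,
                 chain_index = seq_len(schedule$keep) + schedule$burn_in),
            class = "permuted_set")
}
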