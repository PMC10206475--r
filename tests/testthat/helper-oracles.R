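# Independent brute-force oracles and small fixtures used across tests.
# These deliberately avoid the package's own computational paths.

# all permutations of 1..n as a matrix (rows)
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# SRI by direct recount over a list of subgroup id vectors
brute_sri <- function(subgroups, ids) {
  n <- length(ids)
  sri <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      x <- sum(vapply(subgroups, function(g) {
        ids[a] %in% g && ids[b] %in% g
      }, logical(1)))
      na <- sum(vapply(subgroups, function(g) ids[a] %in% g, logical(1)))
      nb <- sum(vapply(subgroups, function(g) ids[b] %in% g, logical(1)))
      denom <- na + nb - x
      sri[a, b] <- if (denom == 0) 0 else x / denom
    }
  }
  sri
}

# exhaustive I&SI optimum over all orderings (n <= 6); returns c(I, SI)
brute_isi <- function(wins) {
  n <- nrow(wins)
  best <- c(Inf, Inf)
  pm <- perms(n)
  for (r in seq_len(nrow(pm))) {
    ord <- pm[r, ]
    I <- 0; SI <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        hi <- ord[a]; lo <- ord[b]
        if (wins[lo, hi] > wins[hi, lo]) {
          I <- I + 1
          SI <- SI + (b - a)
        }
      }
    }
    if (I < best[1] || (I == best[1] && SI < best[2])) best <- c(I, SI)
  }
  best
}

# leading eigenvector (abs, max-scaled) by dense eigendecomposition
brute_eigen <- function(mat) {
  e <- eigen(mat, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  stats::setNames(v / max(v), colnames(mat))
}

# betweenness by exhaustive simple-path enumeration (symmetric matrices,
# weights as costs); unordered pairs counted once
brute_betweenness <- function(mat, inverse = FALSE) {
  n <- nrow(mat)
  w <- mat
  if (inverse) w[mat > 0] <- 1 / mat[mat > 0]
  bc <- stats::setNames(numeric(n), colnames(mat))
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(nodes = visited, len = len)
        return(invisible())
      }
      for (u in seq_len(n)) {
        if (mat[v, u] > 0 && !(u %in% visited)) {
          walk(u, c(visited, u), len + w[v, u])
        }
      }
    }
    walk(s, s, 0)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      shortest <- which(abs(lens - min(lens)) < 1e-12)
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(paths[[p]]$nodes, c(s, t))
        bc[inner] <- bc[inner] + 1 / sigma
      }
    }
  }
  bc
}

# random symmetric weighted matrix on n nodes (zero diagonal)
random_weighted_graph <- function(n, density = 0.6) {
  m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (stats::runif(1) < density) {
        m[a, b] <- m[b, a] <- stats::runif(1, 0.1, 1)
      }
    }
  }
  m
}

# random binary GBI with no empty rows/columns: every row gets at least one
# member (subgroups are never empty), every column at least one sighting
random_gbi <- function(n_rows, n_ids, p = 0.15) {
  ids <- sprintf("id%02d", seq_len(n_ids))
  g <- matrix(as.integer(stats::runif(n_rows * n_ids) < p), n_rows, n_ids,
              dimnames = list(NULL, ids))
  for (r in which(rowSums(g) == 0)) g[r, sample.int(n_ids, 1)] <- 1L
  for (cc in which(colSums(g) == 0)) g[sample.int(n_rows, 1), cc] <- 1L
  g
}

# small fast simulation configuration for pipeline-level tests
tiny_config <- function(seed = 1L, ...) {
  sim_config(
    n_matrilines = 6, adults_per_matriline = 2,
    immatures = default_immatures(12, 6),
    seasons = data.frame(year = c(2014, 2015), n_periods = c(1, 1)),
    scans_per_individual_per_month = 12,
    grooming_events_per_individual_per_month = 15,
    dominance_interactions_per_dyad = 6,
    rng_seed = seed, ...)
}

# zero-effect configuration for null-calibration runs: no inheritance, no
# homophily, constant mother association
null_config <- function(seed = 1L) {
  sim_config(
    n_matrilines = 6, adults_per_matriline = 2,
    immatures = default_immatures(12, 6),
    seasons = data.frame(year = c(2014, 2015), n_periods = c(1, 1)),
    scans_per_individual_per_month = 12,
    grooming_events_per_individual_per_month = 15,
    lambda0 = 0, same_sex_slope = 0, age_homophily_strength = 0,
    mother_assoc = c(intercept = 0.3, age = 0, sex = 0, age_sex = 0),
    dominance_interactions_per_dyad = 6,
    rng_seed = seed)
}

# scan records data frame from a list of subgroups (one troop-period)
scan_fixture <- function(subgroups, troop = "J", start = "2014-06-01") {
  data.frame(
    datetime = as.POSIXct(start, tz = "UTC") + seq_along(subgroups) * 3600,
    troop = troop,
    focal_id = vapply(subgroups, `[`, character(1), 1),
    subgroup_ids = vapply(subgroups, paste, character(1), collapse = ";"))
}

groom_fixture <- function(givers, recipients, troop = "J",
                          start = "2014-06-01", gap_hours = 1) {
  data.frame(
    datetime = as.POSIXct(start, tz = "UTC") +
      seq_along(givers) * gap_hours * 3600,
    troop = troop, giver_id = givers, recipient_id = recipients)
}
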