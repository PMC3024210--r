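# Independent oracles used across the suite. These re-derive expected
# values by direct transcription of the definitions (brute force where the
# package uses an optimised path) and stay independent of the package's
# internal geometry precomputations.

# Brute-force circular-scan maximiser: every area as a centre, every
# window radius, no shared precomputation with the package. Tie-break:
# smaller zone population, then fewer members, then lower centre index.
brute_force_mlc <- function(map, cases, max_pop_fraction = 0.5) {
  xy <- as.matrix(map$areas[, c("x", "y")])
  pop <- map$areas$population
  K <- nrow(xy)
  N <- sum(pop)
  C <- sum(cases$counts)
  cap <- max_pop_fraction * N
  best <- list(llr = 0, members = NULL, n_z = Inf, size = Inf, center = Inf)
  for (cc in seq_len(K)) {
    d <- sqrt((xy[, 1] - xy[cc, 1])^2 + (xy[, 2] - xy[cc, 2])^2)
    ord <- order(d)
    for (j in seq_len(K)) {
      members <- ord[seq_len(j)]
      n_z <- sum(pop[members])
      if (n_z > cap) break
      c_z <- sum(cases$counts[members])
      mu <- C * n_z / N
      llr <- if (c_z > mu) {
        c_z * log(c_z / mu) +
          (if (C - c_z > 0) (C - c_z) * log((C - c_z) / (C - mu)) else 0)
      } else 0
      if (llr == 0) next
      better <- llr > best$llr ||
        (llr == best$llr && (n_z < best$n_z ||
                             (n_z == best$n_z && (j < best$size ||
                                                  (j == best$size && cc < best$center)))))
      if (better) {
        best <- list(llr = llr, members = sort(members), n_z = n_z,
                     size = j, center = cc)
      }
    }
  }
  best
}

# Small random map with distinct centroids and nonuniform populations/cases.
random_small_map <- function(K, seed) {
  set.seed(seed)
  map <- area_map(sprintf("a%02d", seq_len(K)),
                  x = runif(K, 0, 10), y = runif(K, 0, 10),
                  population = sample(50:500, K, replace = TRUE))
  C <- sample(10:80, 1)
  p <- rgamma(K, shape = 0.8) * map$areas$population
  cases <- case_vector(as.integer(rmultinom(1, C, p / sum(p))), map)
  list(map = map, cases = cases)
}

# Direct evaluation of the per-area quantile definition: among the ranks
# whose replicate MLC contains the area, take those attaining the maximal
# intensity value, then the highest such rank, divided by m; 0 if the area
# is in no replicate MLC.
q_oracle <- function(membership, sorted_llr, K) {
  m <- length(membership)
  vapply(seq_len(K), function(i) {
    js <- which(vapply(membership, function(mb) i %in% mb, logical(1)))
    if (!length(js)) return(0)
    fmax <- max(sorted_llr[js])
    max(js[sorted_llr[js] == fmax]) / m
  }, numeric(1))
}

# Direct transcription of the Marshall method-of-moments smoother on an
# arbitrary index set (the whole map, or one area's neighbourhood).
marshall_oracle_theta <- function(y, n, idx_set, i) {
  t_all <- y / n
  ys <- y[idx_set]; ns <- n[idx_set]; ts <- ys / ns
  m <- sum(ys) / sum(ns)
  s2 <- sum(ns * (ts - m)^2) / sum(ns)
  nbar <- sum(ns) / length(ns)
  A <- max(0, s2 - m / nbar)
  w <- if (A <= 0) 0 else A / (A + m / n[i])
  w * t_all[i] + (1 - w) * m
}

# Neighbour ids of one cell on an unjittered hexagonal lattice: the ring of
# cells at unit centroid distance.
hex_ring_ids <- function(map, id) {
  lat <- map$lattice
  i <- match(id, map$areas$id)
  d <- sqrt((lat$x0 - lat$x0[i])^2 + (lat$y0 - lat$y0[i])^2)
  sort(map$areas$id[d > 0 & d < 1.01])
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

write_temp_area_csv <- function(df, lines = NULL) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  if (is.null(lines)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(lines, path)
  }
  path
}
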