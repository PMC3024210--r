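#' Poisson log-likelihood ratio of a zone
#'
#' The circular scan statistic compares the risk inside a candidate zone
#' against the uniform-risk null. With `C` total cases on a map of total
#' population `N`, a zone with population `n_z` has expectation
#' `mu_z = C * n_z / N`; writing `I = c_z / mu_z` for the relative risk
#' inside and `O = (C - c_z) / (C - mu_z)` outside, the statistic is
#' `c_z * log(I) + (C - c_z) * log(O)` when `I > 1` and 0 otherwise.
#' When the zone holds every case the outside term is `0 * log(0)`, taken
#' as 0 by continuity.
#'
#' All four arguments are recycled to a common length, so a vector of
#' candidate zones can be evaluated in one call.
#'
#' @param c_z observed cases in the zone (0..C).
#' @param n_z zone population (0 < n_z <= N).
#' @param C total cases on the map (>= 1).
#' @param N total population.
#' @return Numeric vector of nonnegative, finite log-likelihood ratios.
#' @examples
#' llr_poisson(30, 100, 100, 1000) # 30*log(3) + 70*log(70/90)
#' llr_poisson(10, 500, 100, 1000) # below expectation -> 0
#' @export
llr_poisson <- function(c_z, n_z, C, N) {
  args <- cbind(c_z = c_z, n_z = n_z, C = C, N = N)
  c_z <- args[, 1]; n_z <- args[, 2]; C <- args[, 3]; N <- args[, 4]
  if (any(C < 1)) stop("C must be >= 1")
  if (any(n_z <= 0 | n_z > N)) stop("n_z must satisfy 0 < n_z <= N")
  if (any(c_z < 0 | c_z > C)) stop("c_z must satisfy 0 <= c_z <= C")
  mu <- C * n_z / N
  out <- numeric(length(c_z))
  hot <- c_z > mu  # I(z) > 1
  if (any(hot)) {
    cz <- c_z[hot]; Ch <- C[hot]; muh <- mu[hot]
    inside <- cz * log(cz / muh)
    rem <- Ch - cz
    outside <- ifelse(rem > 0, rem * log(rem / (Ch - muh)), 0)
    out[hot] <- inside + outside
  }
  out
}

# Precomputed circular-window geometry for a map: per-center nearest-area
# orderings, cumulative populations, and the per-center window-count limit
# under the population cap. Distance ties are broken by area index.
scan_geometry <- function(map, max_pop_fraction) {
  if (max_pop_fraction <= 0 || max_pop_fraction > 1) {
    stop("max_pop_fraction must be in (0, 1]")
  }
  xy <- as.matrix(map$areas[, c("x", "y")])
  K <- nrow(xy)
  d <- unname(as.matrix(stats::dist(xy)))
  ord <- apply(d, 2, order)  # ties broken by index (order() is stable)
  if (K == 1) ord <- matrix(1L, 1, 1)
  pop <- map$areas$population
  popcum <- apply(ord, 2, function(o) cumsum(pop[o]))
  if (K == 1) popcum <- matrix(pop, 1, 1)
  dimnames(ord) <- dimnames(popcum) <- NULL
  cap <- max_pop_fraction * map$total_population
  limit <- vapply(seq_len(K), function(c) sum(popcum[, c] <= cap), integer(1))
  if (any(limit == 0)) {
    warning(sum(limit == 0), " area(s) exceed the population cap even as singletons; ",
            "windows centred there are skipped")
  }
  list(ord = ord, popcum = popcum, limit = limit, K = K,
       pop = pop, N = map$total_population)
}

#' Enumerate circular scan zones
#'
#' For every area taken as a window centre, grows the nested sequence of
#' zones obtained by adding areas in increasing centroid-distance order,
#' stopping before the zone population exceeds
#' `max_pop_fraction * N`. Duplicate member sets arising from different
#' centres are emitted once (first centre wins).
#'
#' @param map an [area_map()].
#' @param max_pop_fraction maximum zone population as a fraction of the
#'   total population (default 0.5, the conventional circular-scan cap).
#' @return A list of zones; each zone is a list with `member_indices`,
#'   `n_z` and `center_index`.
#' @export
enumerate_circular_zones <- function(map, max_pop_fraction = 0.5) {
  geo <- scan_geometry(map, max_pop_fraction)
  zones <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (cc in seq_len(geo$K)) {
    lim <- geo$limit[cc]
    if (lim == 0) next
    for (j in seq_len(lim)) {
      members <- sort(geo$ord[seq_len(j), cc])
      key <- paste(members, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      zones[[length(zones) + 1]] <- list(member_indices = members,
                                         n_z = geo$popcum[j, cc],
                                         center_index = cc)
    }
  }
  zones
}

#' Most likely cluster by the circular Poisson scan
#'
#' Maximises [llr_poisson()] over all circular windows (every area as a
#' centre, windows grown one nearest area at a time up to the population
#' cap) and returns the attaining zone. Ties in LLR are broken by smaller
#' zone population, then fewer member areas, then lower centre index, so
#' the result is deterministic. When no zone shows any case excess (every
#' zone's LLR is 0) the result carries `no_excess = TRUE` and no zone.
#'
#' @param map an [area_map()].
#' @param cases a [case_vector()] aligned with `map`; total `C >= 1`.
#' @param max_pop_fraction maximum zone population fraction (default 0.5).
#' @return A `scan_result`: list with `llr`, `zone` (or `NULL`),
#'   `no_excess`, and `p_value` (`NA` until [null_pvalue()] is run).
#' @examples
#' m <- hex_grid(rows = 5, cols = 5, seed = 1)
#' cs <- case_vector(rep(c(4, 1), length.out = 25), m)
#' scan_circular(m, cs)
#' @export
scan_circular <- function(map, cases, max_pop_fraction = 0.5) {
  stopifnot(inherits(map, "area_map"), inherits(cases, "case_vector"))
  if (cases$total < 1) stop("at least one case is required")
  geo <- scan_geometry(map, max_pop_fraction)
  hit <- .scan_mlc_cpp(geo$ord, geo$popcum, geo$limit,
                       as.numeric(cases$counts), cases$total, geo$N)
  res <- structure(
    list(llr = hit$llr, zone = NULL, no_excess = hit$center < 0,
         p_value = NA_real_, n_null_replicates = 0L,
         max_pop_fraction = max_pop_fraction),
    class = "scan_result"
  )
  if (!res$no_excess) {
    members <- geo$ord[seq_len(hit$size), hit$center]
    res$zone <- list(member_indices = sort(members),
                     member_ids = map$areas$id[sort(members)],
                     c_z = sum(cases$counts[members]),
                     n_z = geo$popcum[hit$size, hit$center],
                     mu_z = cases$total * geo$popcum[hit$size, hit$center] / geo$N,
                     center_index = hit$center)
  }
  res
}

#' @export
print.scan_result <- function(x, ...) {
  if (x$no_excess) {
    cat("scan_result: no case excess anywhere (max LLR = 0)\n")
  } else {
    cat("scan_result: most likely cluster of", length(x$zone$member_indices),
        "areas\n  LLR =", format(x$llr, digits = 6),
        "| cases =", x$zone$c_z, "| expected =", format(x$zone$mu_z, digits = 5), "\n")
    cat("  members:", paste(x$zone$member_ids, collapse = " "), "\n")
  }
  if (!is.na(x$p_value)) {
    cat("  Monte Carlo p =", format(x$p_value, digits = 4),
        "(", x$n_null_replicates, "null replicates )\n")
  }
  invisible(x)
}

#' Monte Carlo significance of the most likely cluster
#'
#' Under the null hypothesis cases are uniformly distributed in the
#' population: each of `B` replicates draws `C` cases multinomially with
#' per-area probability `n_i / N`, the circular scan is run on the
#' replicate, and the p-value is `(1 + #\{max LLR >= observed\}) / (1 + B)`
#' — guaranteed positive, with minimum `1 / (B + 1)`.
#'
#' @param map an [area_map()].
#' @param cases the observed [case_vector()].
#' @param scan_llr observed max LLR; defaults to running [scan_circular()].
#' @param B number of null replicates (default 999).
#' @param seed integer RNG seed.
#' @param max_pop_fraction window population cap, as for the observed scan.
#' @return A `scan_result` with `p_value` and `n_null_replicates` filled in.
#' @export
null_pvalue <- function(map, cases, scan_llr = NULL, B = 999, seed = 1,
                        max_pop_fraction = 0.5) {
  stopifnot(B >= 1)
  res <- scan_circular(map, cases, max_pop_fraction)
  if (is.null(scan_llr)) scan_llr <- res$llr
  geo <- scan_geometry(map, max_pop_fraction)
  p0 <- geo$pop / geo$N
  set.seed(seed)
  sims <- stats::rmultinom(B, cases$total, p0)
  null_max <- .scan_batch_cpp(geo$ord, geo$popcum, geo$limit,
                              matrix(as.numeric(sims), nrow = geo$K),
                              cases$total, geo$N)$llr
  res$p_value <- (1 + sum(null_max >= scan_llr)) / (1 + B)
  res$n_null_replicates <- as.integer(B)
  res
}
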