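#' Jittered hexagonal-lattice benchmark map
#'
#' Builds a rectangular array of hexagonal cells (offset rows, unit
#' spacing) with a fixed population per cell, the standard geometry for
#' benchmark disease maps. Centroids are displaced by a small uniform
#' jitter on both axes so that no two inter-centroid distances tie, which
#' would make circular-window ordering ambiguous; adjacency (up to 6 hex
#' neighbours) is computed on the unjittered lattice.
#'
#' The default 7 x 29 grid gives 203 cells of population 1000 each
#' (N = 203,000).
#'
#' @param rows,cols grid dimensions.
#' @param cell_population population at risk in every cell (default 1000).
#' @param jitter_scale jitter amplitude as a fraction of the cell spacing,
#'   in \[0, 0.5) (default 0.05); 0 gives a perfectly regular lattice.
#' @param seed integer RNG seed for the jitter.
#' @return An [area_map()] with adjacency attached; cell ids are
#'   `"r<row>c<col>"`.
#' @export
hex_grid <- function(rows = 7, cols = 29, cell_population = 1000,
                     jitter_scale = 0.05, seed = 1) {
  stopifnot(rows >= 1, cols >= 1, jitter_scale >= 0, jitter_scale < 0.5)
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x0 <- grid$col + 0.5 * (grid$row %% 2)
  y0 <- grid$row * sqrt(3) / 2
  K <- nrow(grid)
  set.seed(seed)
  repeat {
    x <- x0 + stats::runif(K, -jitter_scale, jitter_scale)
    y <- y0 + stats::runif(K, -jitter_scale, jitter_scale)
    if (jitter_scale == 0 || !anyDuplicated(stats::dist(cbind(x, y)))) break
    # measure-zero event: re-draw the jitter
  }
  ids <- paste0("r", grid$row, "c", grid$col)
  # hex neighbours are exactly the unjittered pairs at unit distance
  d0 <- as.matrix(stats::dist(cbind(x0, y0)))
  adj <- lapply(seq_len(K), function(i) ids[which(d0[i, ] > 0 & d0[i, ] < 1.01)])
  names(adj) <- ids
  map <- area_map(ids, x, y, rep(cell_population, K), adjacency = adj)
  map$lattice <- data.frame(row = grid$row, col = grid$col, x0 = x0, y0 = y0)
  map
}

#' Inject cluster cases into a benchmark map
#'
#' Distributes a fixed total number of cases multinomially with cell
#' weights proportional to population, multiplied by the relative risk for
#' cells inside the true cluster. The result is a "noisy" case map: cases
#' are not homogeneously distributed inside or outside the injected
#' cluster, as in real data.
#'
#' @param map an [area_map()] from [hex_grid()].
#' @param cluster_mask logical length-K vector marking true-cluster cells,
#'   or a numeric length-K vector of per-cell relative risks (1 outside).
#' @param rr_in relative risk inside the cluster (ignored when
#'   `cluster_mask` is numeric); `rr_in = 1` reduces to the uniform null.
#' @param total_cases total cases to distribute (default 406, i.e. 2 per
#'   cell on the default 203-cell grid).
#' @param seed integer RNG seed.
#' @return A [case_vector()].
#' @export
inject_cases <- function(map, cluster_mask, rr_in = 8, total_cases = 406,
                         seed = 1) {
  K <- nrow(map$areas)
  if (is.numeric(cluster_mask) && !is.logical(cluster_mask)) {
    rr <- cluster_mask
  } else {
    stopifnot(length(cluster_mask) == K, rr_in >= 1)
    rr <- ifelse(cluster_mask, rr_in, 1)
  }
  stopifnot(length(rr) == K, all(rr >= 0))
  w <- map$areas$population * rr
  set.seed(seed)
  case_vector(as.integer(stats::rmultinom(1, total_cases, w / sum(w))), map)
}

# Cells within `radius` lattice steps of a (row, col) centre, by unjittered
# Euclidean distance (radius 1 = the 7-cell hex flower).
hex_disc <- function(map, row, col, radius = 1) {
  lat <- map$lattice
  i0 <- which(lat$row == row & lat$col == col)
  if (!length(i0)) stop("centre cell (", row, ",", col, ") not on the grid")
  d <- sqrt((lat$x0 - lat$x0[i0])^2 + (lat$y0 - lat$y0[i0])^2)
  d <= radius + 0.01
}

#' Benchmark scenarios with injected true clusters
#'
#' Ready-made simulation scenarios on the default 203-cell hexagonal map
#' (population 1000 per cell, 406 total cases):
#'
#' * `A_circle_high` — a single 7-cell circular (hex-flower) cluster with
#'   very high relative risk (8): sharply detectable.
#' * `B_circle_moderate` — the same cluster at moderately high risk (3):
#'   detectable but diffuse.
#' * `C_Lshape` — an L-shaped cluster of two 5-cell braces meeting at a
#'   corner, relative risk 8; the circular scan cannot match its shape.
#' * `D_double_high` / `E_double_moderate` — two disjoint circular
#'   clusters with unequal risks (8 and 5; 3 and 2), so a single scan
#'   finds only the stronger component.
#' * `null` — uniform risk everywhere (no cluster).
#'
#' @param name scenario name (see above).
#' @param seed integer RNG seed driving jitter and case placement.
#' @param total_cases total cases (default 406).
#' @param rr optional length-1 or length-2 override of the scenario's
#'   relative risk(s).
#' @return A list with `map` (an [area_map()]), `cases` (a
#'   [case_vector()]), `truth` (logical true-cluster mask), and
#'   `components` (list of per-component masks, ordered by decreasing
#'   risk; empty for `null`).
#' @export
scenario_map <- function(name = c("A_circle_high", "B_circle_moderate",
                                  "C_Lshape", "D_double_high",
                                  "E_double_moderate", "null"),
                         seed = 1, total_cases = 406, rr = NULL) {
  name <- match.arg(name)
  map <- hex_grid(seed = seed)
  lat <- map$lattice
  K <- nrow(map$areas)
  risks <- rep(1, K)
  components <- list()

  if (name %in% c("A_circle_high", "B_circle_moderate")) {
    r_in <- if (!is.null(rr)) rr[1] else if (name == "A_circle_high") 8 else 3
    comp <- hex_disc(map, row = 4, col = 15)
    risks[comp] <- r_in
    components <- list(comp)
  } else if (name == "C_Lshape") {
    r_in <- if (!is.null(rr)) rr[1] else 8
    vertical <- lat$col == 8 & lat$row >= 2 & lat$row <= 6
    horizontal <- lat$row == 2 & lat$col >= 8 & lat$col <= 12
    comp <- vertical | horizontal
    risks[comp] <- r_in
    components <- list(comp)
  } else if (name %in% c("D_double_high", "E_double_moderate")) {
    pair <- if (!is.null(rr)) rr[1:2] else if (name == "D_double_high") c(8, 5) else c(3, 2)
    comp1 <- hex_disc(map, row = 4, col = 7)
    comp2 <- hex_disc(map, row = 4, col = 22)
    risks[comp1] <- pair[1]
    risks[comp2] <- pair[2]
    components <- list(comp1, comp2)
  }

  truth <- risks > 1
  cases <- inject_cases(map, risks, total_cases = total_cases, seed = seed + 1L)
  list(map = map, cases = cases, truth = truth, components = components,
       name = name, seed = as.integer(seed))
}
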