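#' Multinomial replication of a case map
#'
#' Draws one replicate of the observed case map: the `C` total cases are
#' redistributed over the K areas according to a multinomial distribution
#' with the supplied per-area probabilities (`c_i / C` for the raw mean
#' model, or normalised smoothed expected counts). Total cases are
#' conserved exactly.
#'
#' @param cases the observed [case_vector()] (supplies `C`).
#' @param probabilities length-K simplex vector (sums to 1 within 1e-12).
#' @return A [case_vector()] realisation with the same total.
#' @export
replicate_cases <- function(cases, probabilities) {
  stopifnot(inherits(cases, "case_vector"))
  check_simplex(probabilities)
  case_vector(as.integer(stats::rmultinom(1, cases$total, probabilities)))
}

check_simplex <- function(p) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (sum(p) <= 0) stop("all probabilities are zero; cases cannot be placed")
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

#' Intensity bounds for cluster delineation
#'
#' The package's central procedure. The observed map is treated as one
#' realisation of a random case vector; `m` Monte Carlo replicates are
#' drawn (multinomial, probabilities from the raw or smoothed mean model),
#' the circular-scan most likely cluster (MLC) of each replicate is
#' recorded, and the `m` MLC log-likelihood ratios are ranked in increasing
#' order to form the intensity function `f(j) = LLR_(j)`. Each area then
#' receives the quantile
#' `q(a_i) = (1/m) * max\{j : a_i in MLC_(j)\}` — the rank (as a fraction
#' of `m`) of the strongest replicate cluster containing it — or 0 if it
#' belongs to no replicate MLC. High `q` marks areas plausibly part of the
#' real cluster; blank (`q = 0`) areas were never part of any cluster.
#'
#' Replicates in which the scan finds no case excess keep their rank with
#' `f(j) = 0` but contribute no membership. LLR ties rank by replicate
#' order (stable sort); since `f` is nondecreasing, taking the highest
#' qualifying rank makes `q` well-defined under ties.
#'
#' For long runs a checkpoint file can be given: partial results are saved
#' every `checkpoint_every` replicates and a re-run with the same
#' configuration resumes from the checkpoint, producing a result identical
#' to an uninterrupted run with the same seed.
#'
#' @param map an [area_map()]; adjacency required for the smoothed model.
#' @param cases the observed [case_vector()], `C >= 1`.
#' @param m number of Monte Carlo replicates (default 999).
#' @param max_pop_fraction circular-window population cap (default 0.5).
#' @param mean_model `"raw"` (probabilities `c_i / C`) or `"smoothed"`
#'   (local Marshall estimates via [smoothed_probabilities()]).
#' @param seed integer RNG seed; fixed seed gives bit-identical results.
#' @param checkpoint_file optional path for resumable partial results.
#' @param checkpoint_every replicates between checkpoint saves (default 50).
#' @param progress_every if positive, log progress to stderr every so many
#'   replicates.
#' @param stop_after stop the run (leaving the checkpoint in place, and
#'   returning `NULL`) once at least this many replicates are done;
#'   `Inf` (the default) runs to completion. Exists to exercise and
#'   demonstrate resumption.
#' @return An `intensity_result`: list with `m`, `sorted_llr` (`f(1..m)`),
#'   `membership` (per rank, integer member indices of the replicate MLC),
#'   `q` (length-K), `q_rank` (the attaining rank, 0 if blank), `seed`,
#'   `mean_model`, `max_pop_fraction`.
#' @examples
#' bench <- scenario_map("A_circle_high", seed = 7)
#' ib <- intensity_bounds(bench$map, bench$cases, m = 99, seed = 7)
#' table(quantile_shading(ib$q))
#' @export
intensity_bounds <- function(map, cases, m = 999, max_pop_fraction = 0.5,
                             mean_model = c("raw", "smoothed"), seed = 1,
                             checkpoint_file = NULL, checkpoint_every = 50,
                             progress_every = 0, stop_after = Inf) {
  mean_model <- match.arg(mean_model)
  stopifnot(inherits(map, "area_map"), inherits(cases, "case_vector"), m >= 1)
  if (cases$total < 1) stop("at least one case is required")
  p <- if (mean_model == "raw") {
    cases$counts / cases$total
  } else {
    if (is.null(map$adjacency)) {
      stop("mean_model = \"smoothed\" requires adjacency; call build_adjacency() first")
    }
    smoothed_probabilities(marshall_smooth(map, cases, mode = "local"), map)
  }
  check_simplex(p)
  geo <- scan_geometry(map, max_pop_fraction)
  config <- paste(mean_model, m, max_pop_fraction, seed,
                  cases$total, geo$N, geo$K, sep = "|")

  # All replicate case vectors are drawn up front from the seed, so a
  # resumed run sees exactly the draws an uninterrupted run would.
  set.seed(seed)
  sims <- stats::rmultinom(m, cases$total, p)

  done <- 0L
  llr <- numeric(m); center <- integer(m); size <- integer(m)
  if (!is.null(checkpoint_file) && file.exists(checkpoint_file)) {
    ck <- readRDS(checkpoint_file)
    if (identical(ck$config, config)) {
      done <- ck$done; llr <- ck$llr; center <- ck$center; size <- ck$size
    } else {
      warning("checkpoint configuration mismatch; restarting from scratch")
    }
  }
  while (done < m) {
    chunk <- if (!is.null(checkpoint_file) || progress_every > 0) {
      seq(done + 1L, min(m, done + max(1L, checkpoint_every)))
    } else {
      seq(done + 1L, m)
    }
    hit <- .scan_batch_cpp(geo$ord, geo$popcum, geo$limit,
                           matrix(as.numeric(sims[, chunk, drop = FALSE]), nrow = geo$K),
                           cases$total, geo$N)
    llr[chunk] <- hit$llr; center[chunk] <- hit$center; size[chunk] <- hit$size
    done <- max(chunk)
    if (!is.null(checkpoint_file) && done < m) {
      saveRDS(list(config = config, done = done, llr = llr,
                   center = center, size = size), checkpoint_file)
    }
    if (progress_every > 0 && (done %% progress_every == 0 || done == m)) {
      message("intensity: ", done, "/", m, " replicates")
    }
    if (done >= stop_after && done < m) return(invisible(NULL))
  }
  if (!is.null(checkpoint_file) && file.exists(checkpoint_file)) {
    unlink(checkpoint_file)
  }

  rank_order <- order(llr)  # stable: ties keep replicate order
  sorted_llr <- llr[rank_order]
  membership <- lapply(rank_order, function(b) {
    if (center[b] < 0) integer(0) else sort(geo$ord[seq_len(size[b]), center[b]])
  })
  qr <- integer(geo$K)
  for (j in seq_len(m)) qr[membership[[j]]] <- j  # ascending j: last write wins
  structure(list(m = as.integer(m), sorted_llr = sorted_llr,
                 membership = membership, q = qr / m, q_rank = qr,
                 seed = as.integer(seed), mean_model = mean_model,
                 max_pop_fraction = max_pop_fraction),
            class = "intensity_result")
}

#' @export
print.intensity_result <- function(x, ...) {
  cat("intensity_result:", x$m, "replicates (", x$mean_model, "mean model, seed",
      x$seed, ")\n")
  cat("  f range:", format(x$sorted_llr[1], digits = 5), "-",
      format(x$sorted_llr[x$m], digits = 5), "\n")
  cat("  areas with q > 0:", sum(x$q > 0), "of", length(x$q),
      "| q = 1:", sum(x$q == 1), "\n")
  invisible(x)
}

#' Quantile shading classes for an intensity map
#'
#' Maps each area's quantile `q` to a shading class for choropleth display:
#' class 0 ("blank") for `q = 0` — areas never part of any replicate
#' cluster — and otherwise the index of the first breakpoint at or above
#' `q`, so higher classes are darker shades. Breakpoints are user-chosen;
#' the defaults highlight the upper tail where delineation evidence
#' concentrates.
#'
#' @param q numeric vector of quantiles in \[0, 1\].
#' @param levels strictly ascending breakpoints in (0, 1\].
#' @return Integer vector of classes, 0 (blank) to `length(levels)`.
#' @examples
#' quantile_shading(c(0, 0.51, 1), levels = c(0.5, 0.9, 1))
#' @export
quantile_shading <- function(q, levels = c(0.90, 0.95, 0.99, 1.0)) {
  if (length(levels) == 0) stop("at least one shading level is required")
  if (any(diff(levels) <= 0)) stop("levels must be strictly ascending")
  if (utils::tail(levels, 1) > 1) stop("levels must not exceed 1")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  cls <- integer(length(q))
  pos <- q > 0
  cls[pos] <- vapply(q[pos], function(v) which(levels >= v - 1e-12)[1], integer(1))
  if (anyNA(cls)) stop("some q exceed the largest level; include 1 in levels")
  cls
}

#' Intensity function as a plottable table
#'
#' @param result an `intensity_result`.
#' @return data.frame with columns `j` (rank) and `f` (the `j`-th smallest
#'   replicate MLC log-likelihood ratio); nondecreasing in `j`.
#' @export
intensity_curve <- function(result) {
  stopifnot(inherits(result, "intensity_result"))
  data.frame(j = seq_len(result$m), f = result$sorted_llr)
}
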