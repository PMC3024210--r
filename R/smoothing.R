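#' Marshall empirical-Bayes rate smoothing
#'
#' Shrinks each area's raw rate `t_i = y_i / n_i` toward a prior mean with
#' a weight governed by a method-of-moments prior variance:
#' `theta_hat_i = w_i * t_i + (1 - w_i) * m_i`, where
#' `w_i = A / (A + m / n_i)`.
#'
#' In the global mode the prior moments are pooled over the whole map:
#' `m = sum(y) / sum(n)`, `s2 = sum(n_i (t_i - m)^2) / sum(n_i)`,
#' `nbar = sum(n_i) / K` and `A = s2 - m / nbar`, clamped at 0 when the
#' moment estimate is negative (complete shrinkage). In the local mode the
#' same formulas are evaluated per area on its first-order neighbourhood
#' (the area itself plus its adjacent areas by default), which lets the
#' estimate borrow strength only from nearby areas — the variant suited to
#' maps with very few cases.
#'
#' @param map an [area_map()]; local mode requires adjacency
#'   (see [build_adjacency()]).
#' @param cases a [case_vector()] of event counts `y_i`.
#' @param mode `"global"` or `"local"`.
#' @param include_self whether area `i` belongs to its own neighbourhood in
#'   local mode (default `TRUE`; excluding self can leave estimates
#'   undefined when all neighbours have zero population).
#' @return A `smoothed_rates` object: list with `theta_hat`, `weights`,
#'   `prior_mean`, `prior_var`, `raw_rates`, `mode`.
#' @examples
#' m <- area_map(letters[1:3], x = 1:3, y = c(0, 0, 0), population = rep(100, 3))
#' cs <- case_vector(c(0, 3, 12), m)
#' marshall_smooth(m, cs)$theta_hat
#' @export
marshall_smooth <- function(map, cases, mode = c("global", "local"),
                            include_self = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "area_map"), inherits(cases, "case_vector"))
  n <- map$areas$population
  y <- cases$counts
  zero_pop <- which(n == 0)
  if (length(zero_pop)) {
    stop("area(s) with zero population cannot be rate-smoothed: ",
         paste(map$areas$id[zero_pop], collapse = ", "))
  }
  K <- length(n)
  t_i <- y / n

  if (mode == "global") {
    if (K < 2) stop("global smoothing needs at least 2 areas")
    mom <- marshall_moments(y, n, t_i)
    w <- marshall_weight(mom$A, mom$m, n)
    theta <- w * t_i + (1 - w) * mom$m
    prior_mean <- rep(mom$m, K)
    prior_var <- rep(mom$A, K)
  } else {
    nb <- neighbour_indices(map, include_self = include_self)
    isolated <- which(lengths(nb) == 0)
    if (length(isolated)) {
      stop("area(s) with empty neighbourhood: ",
           paste(map$areas$id[isolated], collapse = ", "),
           "; use include_self = TRUE or fix the adjacency")
    }
    if (any(lengths(nb) == 1)) {
      warning(sum(lengths(nb) == 1), " area(s) have no neighbours; ",
              "their local estimate falls back to the raw rate")
    }
    theta <- w <- prior_mean <- prior_var <- numeric(K)
    for (i in seq_len(K)) {
      j <- nb[[i]]
      mom <- marshall_moments(y[j], n[j], t_i[j])
      w[i] <- marshall_weight(mom$A, mom$m, n[i])
      theta[i] <- w[i] * t_i[i] + (1 - w[i]) * mom$m
      prior_mean[i] <- mom$m
      prior_var[i] <- mom$A
    }
  }
  structure(list(theta_hat = theta, weights = w, prior_mean = prior_mean,
                 prior_var = prior_var, raw_rates = t_i, mode = mode),
            class = "smoothed_rates")
}

# Method-of-moments prior mean and variance on a set of areas.
marshall_moments <- function(y, n, t_i) {
  m <- sum(y) / sum(n)
  s2 <- sum(n * (t_i - m)^2) / sum(n)
  nbar <- sum(n) / length(n)
  A <- max(0, s2 - m / nbar)
  list(m = m, s2 = s2, nbar = nbar, A = A)
}

# Shrinkage weight A / (A + m / n_i); zero prior variance means full
# shrinkage to the prior mean (also covers the m = 0 case).
marshall_weight <- function(A, m, n_i) {
  if (A <= 0) return(rep(0, length(n_i)))
  A / (A + m / n_i)
}

#' @export
print.smoothed_rates <- function(x, ...) {
  cat("smoothed_rates (", x$mode, "): ", length(x$theta_hat), " areas\n", sep = "")
  cat("  mean weight w =", format(mean(x$weights), digits = 4),
      "| rate range", format(min(x$theta_hat), digits = 4), "-",
      format(max(x$theta_hat), digits = 4), "\n")
  invisible(x)
}

#' Replication probabilities from smoothed rates
#'
#' Converts smoothed rates back to expected case counts `n_i * theta_hat_i`
#' and normalises them to a probability simplex for multinomial
#' replication. Areas with zero observed cases receive positive replication
#' probability whenever their neighbourhood carries cases — the motivation
#' for the smoothed mean model.
#'
#' @param sm a `smoothed_rates` object.
#' @param map the companion [area_map()].
#' @return Numeric simplex vector of length K.
#' @export
smoothed_probabilities <- function(sm, map) {
  stopifnot(inherits(sm, "smoothed_rates"))
  ev <- map$areas$population * sm$theta_hat
  tot <- sum(ev)
  if (tot <= 0) stop("all smoothed rates are zero; cannot form replication probabilities")
  ev / tot
}
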