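#' Permutation test for stochastic dominance
#'
#' Tests whether one sample is stochastically smaller than the other. "X is
#' stochastically smaller than Y" means \eqn{P(X > t) \le P(Y > t)} for every
#' threshold \eqn{t}; equivalently the empirical CDFs satisfy
#' \eqn{F_x \ge F_y} everywhere (the CDF graphs do not cross, though they may
#' touch). The test statistic for direction `"x_below_y"` is the one-sided
#' maximal CDF gap
#' \deqn{D = \max_t\,[\hat F_x(t) - \hat F_y(t)]}
#' over the pooled sample points, clipped at 0, so \eqn{D \in [0,1]}. Large
#' D is evidence *for* the ordering (and against exchangeability): the null
#' of the permutation test is equality of distributions, and the p-value is
#' the probability, under random relabeling of the pooled values, of a gap
#' at least as large as observed.
#'
#' When the combined sample size is at most `exhaustive_threshold`, all
#' \eqn{\binom{n_x + n_y}{n_x}} label splits are enumerated and the p-value
#' is exact (`exhaustive = TRUE`); otherwise `n_permutations` random
#' relabelings are drawn and the add-one Monte-Carlo estimator
#' \eqn{p = (1 + \#\{D^* \ge D\}) / (1 + B)} is used, so \eqn{p \ge 1/(B+1)}.
#'
#' @param x,y Non-empty numeric samples.
#' @param direction `"x_below_y"` (is x stochastically smaller?) or
#'   `"y_below_x"`.
#' @param n_permutations Monte-Carlo sample size B.
#' @param seed Integer seed (local RNG).
#' @param exhaustive_threshold Combined size at or below which the null is
#'   enumerated exactly.
#'
#' @return An object of class `dominance_result`: list with `direction`,
#'   `statistic`, `p_value`, `n_x`, `n_y`, `n_permutations`, `seed`,
#'   `exhaustive`.
#'
#' @examples
#' r <- dominance_test(c(1, 2, 3), c(101, 102, 103), "x_below_y")
#' c(r$statistic, r$p_value)  # D = 1, exact p = 1/20
#' @export
dominance_test <- function(x, y, direction = c("x_below_y", "y_below_x"),
                           n_permutations = 10000L, seed = 1L,
                           exhaustive_threshold = 12L) {
  if (is.character(direction) && length(direction) == 1L &&
      !direction %in% c("x_below_y", "y_below_x")) {
    stop("unknown direction: ", direction, call. = FALSE)
  }
  direction <- match.arg(direction)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n_x <- length(x)
  n_y <- length(y)
  if (n_x < 1L || n_y < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (direction == "y_below_x") {
    tmp <- x; x <- y; y <- tmp
    n_first <- n_y
  } else {
    n_first <- n_x
  }
  pooled <- c(x, y)
  N <- length(pooled)
  ord <- order(pooled)
  # index of the last occurrence of each distinct pooled value, in sorted
  # order: the ECDF difference must be evaluated after all ties at a value
  sorted <- pooled[ord]
  last_of_value <- which(c(sorted[-N] != sorted[-1L], TRUE))
  # labels in pooled sorted order (TRUE = first sample)
  lab_sorted <- rep(c(TRUE, FALSE), c(n_first, N - n_first))[ord]

  d_obs <- dominance_gap(lab_sorted, last_of_value, n_first, N - n_first)

  exhaustive <- N <= exhaustive_threshold
  if (exhaustive) {
    splits <- utils::combn(N, n_first)
    d_null <- apply(splits, 2L, function(idx) {
      lab <- logical(N)
      lab[idx] <- TRUE
      dominance_gap(lab, last_of_value, n_first, N - n_first)
    })
    p <- mean(d_null >= d_obs - 1e-12)
    n_perm_used <- ncol(splits)
  } else {
    if (n_permutations < 1L) {
      stop("n_permutations must be >= 1 for Monte-Carlo sampling",
           call. = FALSE)
    }
    count <- with_local_seed(seed, {
      hits <- 0L
      base <- logical(N)
      for (b in seq_len(n_permutations)) {
        lab <- base
        lab[sample.int(N, n_first)] <- TRUE
        if (dominance_gap(lab, last_of_value, n_first, N - n_first) >=
            d_obs - 1e-12) {
          hits <- hits + 1L
        }
      }
      hits
    })
    p <- (1 + count) / (1 + n_permutations)
    n_perm_used <- as.integer(n_permutations)
  }
  structure(
    list(direction = direction, statistic = d_obs, p_value = p,
         n_x = n_x, n_y = n_y, n_permutations = n_perm_used,
         seed = as.integer(seed), exhaustive = exhaustive),
    class = "dominance_result"
  )
}

# One-sided max ECDF gap max_t (F_first(t) - F_second(t)) clipped at 0.
# lab_sorted: logical labels in pooled sorted order (TRUE = first sample);
# last_of_value: sorted positions at which each distinct value ends.
dominance_gap <- function(lab_sorted, last_of_value, n1, n2) {
  cum1 <- cumsum(lab_sorted)
  gap <- cum1[last_of_value] / n1 -
    (last_of_value - cum1[last_of_value]) / n2
  max(0, gap)
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("stochastic dominance (", x$direction, "): D = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4),
      if (x$exhaustive) " [exhaustive]" else
        sprintf(" [%d permutations]", x$n_permutations),
      "\n", sep = "")
  invisible(x)
}
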