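# Analysis layer: round-by-round outcome proportions, repetition
# propensities and difference scores, r/RMSD fit statistics, paired
# transfer tests, Steiger's Z, and a plotting smoother.

# Split a round-log data.frame into per-run matrices of focal/agent
# moves ordered by global round.  All runs must share a round count.
split_runs <- function(runs) {
  if (nrow(runs) == 0L) stop("empty run set", call. = FALSE)
  key <- interaction(runs$condition_id, runs$run_id, drop = TRUE)
  pieces <- split(runs, key)
  n_rounds <- unique(vapply(pieces, nrow, integer(1)))
  if (length(n_rounds) != 1L) {
    stop("all runs must have the same number of rounds", call. = FALSE)
  }
  lapply(pieces, function(p) p[order(p$global_round), , drop = FALSE])
}

#' Round-by-round outcome proportions across runs
#'
#' For every round, the fraction of runs whose outcome falls in each of
#' the five classes (CC, CD, DC, DD, ALT).  Classification restarts at
#' each game's first round (alternation needs a previous round within
#' the same game), so the five proportions partition every round.
#'
#' @param runs A round-log data.frame as produced by [run_condition()]
#'   or read with [read_round_log()]; typically one condition.
#' @return A `rounds x 5` matrix of class `proportion_profile`; rows
#'   sum to 1.
#' @export
proportion_profile <- function(runs) {
  pieces <- split_runs(runs)
  n_rounds <- nrow(pieces[[1]])
  counts <- matrix(0L, n_rounds, length(OUTCOME_CLASSES),
                   dimnames = list(NULL, OUTCOME_CLASSES))
  for (p in pieces) {
    for (g in unique(p$game_index)) {
      idx <- which(p$game_index == g)
      cls <- classify_trajectory(p$focal_move[idx], p$agent_move[idx])
      for (j in seq_along(idx)) {
        counts[idx[j], cls[j]] <- counts[idx[j], cls[j]] + 1L
      }
    }
  }
  structure(counts / length(pieces), class = "proportion_profile")
}

#' Round-by-round repetition propensities
#'
#' For each round `N >= 2` and each previous-round outcome (the four
#' move-pair outcomes CC, CD, DC, DD from the focal perspective), the
#' fraction of runs experiencing that outcome at `N - 1` whose focal
#' player repeated their own `N - 1` move at `N` (e.g. "A after AA" is
#' the DD column).  Cells where the conditioning outcome did not occur
#' are `NA`; conditioning does not cross the between-game boundary.
#'
#' @param runs A round-log data.frame.
#' @return A `rounds x 4` matrix of class `propensity_profile` with
#'   columns `CC`, `CD`, `DC`, `DD`; round-1 rows are `NA`.
#' @export
repetition_propensity <- function(runs) {
  pieces <- split_runs(runs)
  n_rounds <- nrow(pieces[[1]])
  cats <- c("CC", "CD", "DC", "DD")
  rep_count <- tot_count <- matrix(0L, n_rounds, 4L,
                                   dimnames = list(NULL, cats))
  pair_class <- function(f, o) {
    paste0(if (f == "B") "C" else "D", if (o == "B") "C" else "D")
  }
  for (p in pieces) {
    for (i in 2:n_rounds) {
      if (p$game_index[i] != p$game_index[i - 1L]) next
      prev <- pair_class(p$focal_move[i - 1L], p$agent_move[i - 1L])
      tot_count[i, prev] <- tot_count[i, prev] + 1L
      if (p$focal_move[i] == p$focal_move[i - 1L]) {
        rep_count[i, prev] <- rep_count[i, prev] + 1L
      }
    }
  }
  out <- rep_count / tot_count
  out[tot_count == 0L] <- NA_real_
  structure(out, class = "propensity_profile")
}

#' Difference of two repetition-propensity profiles
#'
#' Computes `human - model` elementwise.  A positive score means the
#' model under-predicted the propensity to repeat; cells undefined in
#' either profile stay `NA`.
#'
#' @param human,model Congruent [repetition_propensity()] matrices.
#' @return A matrix of difference scores.
#' @export
propensity_difference <- function(human, model) {
  if (!identical(dim(human), dim(model))) {
    stop("profiles must have the same shape", call. = FALSE)
  }
  unclass(human) - unclass(model)
}

#' Correlation and RMSD between two sets of outcome profiles
#'
#' Flattens the paired profiles (a single matrix each, or lists of
#' matched per-condition matrices pooled into one vector pair) and
#' returns the Pearson correlation and the root mean squared deviation.
#'
#' @param a,b Matched `proportion_profile` matrices or lists thereof.
#' @param by_class If `TRUE` and the inputs are single profile
#'   matrices, `r` is instead the mean of the per-outcome-class
#'   correlations (RMSD is unaffected).
#' @return A list of class `fit_result` with elements `r`, `rmsd`, `n`.
#'   `r` is `NA` (with a warning) if either vector is constant.
#' @export
fit_statistics <- function(a, b, by_class = FALSE) {
  flatten <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      unlist(lapply(x, function(m) as.vector(unclass(m))))
    } else {
      as.vector(unclass(x))
    }
  }
  if (by_class) {
    if (!is.matrix(unclass(a)) || !identical(dim(a), dim(b))) {
      stop("by_class requires two congruent profile matrices",
           call. = FALSE)
    }
    rs <- vapply(seq_len(ncol(a)), function(j) {
      stats::cor(unclass(a)[, j], unclass(b)[, j])
    }, numeric(1))
    va <- flatten(a)
    vb <- flatten(b)
    return(structure(list(r = mean(rs), rmsd = sqrt(mean((va - vb)^2)),
                          n = length(va)), class = "fit_result"))
  }
  va <- flatten(a)
  vb <- flatten(b)
  if (length(va) != length(vb)) {
    stop("profiles must have matching sizes", call. = FALSE)
  }
  keep <- !is.na(va) & !is.na(vb)
  va <- va[keep]
  vb <- vb[keep]
  r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("constant vector: correlation undefined")
    NA_real_
  } else {
    stats::cor(va, vb)
  }
  structure(list(r = r, rmsd = sqrt(mean((va - vb)^2)), n = length(va)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> r = %.3f, RMSD = %.3f (n = %d)\n",
              x$r, x$rmsd, x$n))
  invisible(x)
}

#' Paired transfer test on round-by-round proportions
#'
#' Pairs the round-by-round proportion of an outcome when a game was
#' played first with the same outcome when the game was played second
#' (pairing by round index) and runs a paired t-test on `first -
#' second`.  A significant positive t indicates the proportion dropped
#' when the game was played second; a negative t indicates transfer of
#' learning raised it.
#'
#' @param first,second Equal-length numeric series of round-by-round
#'   proportions (one value per round).
#' @return A list with `t`, `df` (pairs - 1), `p`, and the means and
#'   SDs of both series as percentages.
#' @export
transfer_test <- function(first, second) {
  if (length(first) != length(second)) {
    stop("series must be paired by round and of equal length",
         call. = FALSE)
  }
  n <- length(first)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- first - second
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / (sd_d / sqrt(n))
  }
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       mean_first = 100 * mean(first), sd_first = 100 * stats::sd(first),
       mean_second = 100 * mean(second), sd_second = 100 * stats::sd(second))
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether `r1` (between X and Y1) differs from `r2` (between X
#' and Y2) given `r12` (between Y1 and Y2), via Fisher z-transforms and
#' Steiger's pooled-estimate covariance term (Z_H).
#'
#' @param r1,r2 The two correlations being compared.
#' @param r12 The correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return The Z statistic.
#' @export
steiger_z <- function(r1, r2, r12, n) {
  if (any(abs(c(r1, r2, r12)) >= 1) || n <= 3) {
    stop("require |r| < 1 and n > 3", call. = FALSE)
  }
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar <- (r1 + r2) / 2
  # covariance of the two Fisher z's under the pooled estimate
  s <- (r12 * (1 - 2 * rbar^2) -
          0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) / (1 - rbar^2)^2
  sqrt(n - 3) * (z1 - z2) / sqrt(2 - 2 * s)
}

#' Smooth a round-by-round series for plotting
#'
#' Local polynomial (loess) smoothing with the given span; a plotting
#' aid only, never used in any statistic.  `NA` gaps are dropped from
#' the fit and returned as `NA`.
#'
#' @param series Numeric series (may contain `NA`).
#' @param span Smoothing parameter in (0, 1]; default 0.2.
#' @param degree Local polynomial degree (default 2, falling back to
#'   the window size available).
#' @return The smoothed series, same length as the input.
#' @export
smooth_series <- function(series, span = 0.2, degree = 2) {
  stopifnot(span > 0, span <= 1)
  ok <- !is.na(series)
  out <- rep(NA_real_, length(series))
  window <- ceiling(span * sum(ok))
  if (window < degree + 2) degree <- 1
  if (sum(ok) < 5 || window < degree + 1) {
    out[ok] <- series[ok]
    return(out)
  }
  df <- data.frame(x = which(ok), y = series[ok])
  fit <- stats::loess(y ~ x, data = df, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  out[ok] <- stats::predict(fit, newdata = data.frame(x = df$x))
  out
}
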