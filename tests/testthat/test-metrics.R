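test_that("proportion profiles tally outcome classes per round", {
  # degenerate mixes give degenerate profiles
  cc <- synthetic_round_log(10, 20, mix = c(CC = 1, CD = 0, DC = 0, DD = 0),
                            seed = 1)
  pp <- proportion_profile(cc)
  expect_equal(dim(pp), c(20, 5))
  expect_true(all(pp[, "CC"] == 1))
  # a perfectly alternating pair of players
  alt <- data.frame(condition_id = 1, run_id = rep(1:3, each = 10),
                    game_index = 1, round = rep(1:10, 3),
                    global_round = rep(1:10, 3),
                    focal_move = rep(c("A", "B"), 15),
                    agent_move = rep(c("B", "A"), 15),
                    stringsAsFactors = FALSE)
  pa <- proportion_profile(alt)
  expect_equal(unname(pa[1, "DC"]), 1)    # no history yet on round 1
  expect_true(all(pa[2:10, "ALT"] == 1))
  # random mix: proportions equal an independent per-round tally
  runs <- synthetic_round_log(25, 15, mix = c(CC = 0.4, CD = 0.3,
                                              DC = 0.2, DD = 0.1),
                              seed = 42)
  pp <- proportion_profile(runs)
  expect_true(all(abs(rowSums(pp) - 1) < 1e-12))
  tally <- matrix(0, 15, 5,
                  dimnames = list(NULL, c("CC", "CD", "DC", "DD", "ALT")))
  for (id in unique(runs$run_id)) {
    x <- runs[runs$run_id == id, ]
    x <- x[order(x$round), ]
    for (r in 1:15) {
      cls <- if (r == 1) classify_round(x$focal_move[1], x$agent_move[1])
             else classify_round(x$focal_move[r], x$agent_move[r],
                                 x$focal_move[r - 1], x$agent_move[r - 1])
      tally[r, cls] <- tally[r, cls] + 1
    }
  }
  expect_equal(unclass(pp), tally / 25, ignore_attr = TRUE)
  expect_error(proportion_profile(runs[0, ]), "empty")
})

test_that("classification restarts at the second game's first round", {
  # moves that would be alternation across the boundary must not be
  d <- data.frame(condition_id = 1, run_id = 1, game_index = c(1, 1, 2, 2),
                  round = c(1, 2, 1, 2), global_round = 1:4,
                  focal_move = c("A", "B", "A", "B"),
                  agent_move = c("B", "A", "B", "A"),
                  stringsAsFactors = FALSE)
  pp <- proportion_profile(d)
  expect_equal(unname(pp[, "ALT"]), c(0, 1, 0, 1))
  expect_equal(unname(pp[3, "DC"]), 1)
})

test_that("repetition propensities condition on the previous outcome", {
  # constant mutual defection: defect is always repeated
  dd <- synthetic_round_log(8, 12, mix = c(CC = 0, CD = 0, DC = 0, DD = 1),
                            seed = 2)
  rp <- repetition_propensity(dd)
  expect_equal(dim(rp), c(12, 4))
  expect_true(all(rp[2:12, "DD"] == 1))
  expect_true(all(is.na(rp[, c("CC", "CD", "DC")])))
  expect_true(all(is.na(rp[1, ])))
  # constructed fixture: after CC on round 1, half the runs repeat B
  fx <- data.frame(condition_id = 1, run_id = rep(1:4, each = 2),
                   game_index = 1, round = rep(1:2, 4),
                   global_round = rep(1:2, 4),
                   focal_move = c("B", "B", "B", "B", "B", "A", "B", "A"),
                   agent_move = "B", stringsAsFactors = FALSE)
  rp <- repetition_propensity(fx)
  expect_equal(unname(rp[2, "CC"]), 0.5)
  # a brute-force tally on a random fixture
  runs <- synthetic_round_log(30, 10, seed = 7)
  rp <- repetition_propensity(runs)
  pair <- function(f, o) paste0(ifelse(f == "B", "C", "D"),
                                ifelse(o == "B", "C", "D"))
  for (r in 2:10) {
    for (cls in c("CC", "CD", "DC", "DD")) {
      tot <- 0; rep_ <- 0
      for (id in unique(runs$run_id)) {
        x <- runs[runs$run_id == id, ]
        x <- x[order(x$round), ]
        if (pair(x$focal_move[r - 1], x$agent_move[r - 1]) == cls) {
          tot <- tot + 1
          if (x$focal_move[r] == x$focal_move[r - 1]) rep_ <- rep_ + 1
        }
      }
      if (tot == 0) expect_true(is.na(rp[r, cls]))
      else expect_equal(unname(rp[r, cls]), rep_ / tot)
    }
  }
})

test_that("propensity differences subtract human minus model", {
  runs <- synthetic_round_log(10, 8, seed = 3)
  rp <- repetition_propensity(runs)
  expect_equal(propensity_difference(rp, rp), unclass(rp) - unclass(rp))
  h <- rp; m <- rp
  h[3, "DD"] <- 1; m[3, "DD"] <- 0
  expect_equal(unname(propensity_difference(h, m)[3, "DD"]), 1)
  # NA in either profile stays NA
  m[4, "CC"] <- NA
  expect_true(is.na(propensity_difference(h, m)[4, "CC"]))
  expect_error(propensity_difference(rp, rp[1:4, ]), "shape")
  # random pair equals direct subtraction
  r2 <- repetition_propensity(synthetic_round_log(10, 8, seed = 4))
  expect_equal(propensity_difference(rp, r2), unclass(rp) - unclass(r2))
})

test_that("fit statistics match textbook formulas and pool correctly", {
  a <- matrix(c(0.2, 0.5, 0.3, 0.1, 0.6, 0.3), 2, 3)
  b <- matrix(c(0.25, 0.4, 0.35, 0.1, 0.5, 0.4), 2, 3)
  fit <- fit_statistics(a, b)
  va <- as.vector(a); vb <- as.vector(b)
  r_manual <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(fit$r, r_manual)
  expect_equal(fit$rmsd, sqrt(mean((va - vb)^2)))
  expect_equal(fit$n, 6)
  # identity and uniform offset
  expect_equal(fit_statistics(a, a)$r, 1)
  expect_equal(fit_statistics(a, a)$rmsd, 0)
  off <- fit_statistics(a, a + 0.1)
  expect_equal(off$r, 1)
  expect_equal(off$rmsd, 0.1)
  # symmetry
  rev <- fit_statistics(b, a)
  expect_equal(rev$r, fit$r)
  expect_equal(rev$rmsd, fit$rmsd)
  # pooling lists of per-condition profiles equals concatenation
  pooled <- fit_statistics(list(a, b), list(b, a))
  byhand <- fit_statistics(rbind(cbind(a), cbind(b)), rbind(cbind(b), cbind(a)))
  expect_equal(pooled$rmsd, byhand$rmsd)
  expect_warning(fit_statistics(matrix(1, 2, 2), a[1:2, 1:2]), "constant")
  expect_error(fit_statistics(a, b[, 1:2]), "matching")
})

test_that("paired transfer test matches the t-test oracle", {
  set.seed(10)
  for (i in 1:5) {
    first <- runif(50, 0, 0.6)
    second <- first + rnorm(50, 0.05, 0.05)
    res <- transfer_test(first, second)
    oracle <- t.test(first, second, paired = TRUE)
    expect_equal(res$t, unname(oracle$statistic))
    expect_equal(res$df, unname(oracle$parameter))
    expect_equal(res$p, oracle$p.value)
    expect_equal(res$df, 49)
  }
  # hand-checked 5-pair example
  f <- c(0.2, 0.3, 0.25, 0.4, 0.35)
  s <- c(0.1, 0.25, 0.3, 0.3, 0.2)
  res <- transfer_test(f, s)
  d <- f - s
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(res$mean_first, 100 * mean(f))
  expect_equal(res$sd_second, 100 * sd(s))
  # identical series: no difference at all
  expect_equal(transfer_test(f, f)$t, 0)
  # uniformly larger second series gives a negative t
  expect_lt(transfer_test(f, f + 0.1)$t, 0)
  # pairing is by index: permuting pairs together changes nothing
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(transfer_test(f[perm], s[perm])$t, res$t)
  expect_error(transfer_test(f, s[1:3]), "equal length")
  expect_error(transfer_test(1, 2), "2 pairs")
})

test_that("Steiger's Z behaves as the dependent-correlation test", {
  expect_equal(steiger_z(0.4, 0.4, 0.3, 50), 0)
  # frozen from an independent step-by-step transcription of the
  # pooled-estimate formula (Fisher z, covariance of dependent rs)
  expect_equal(steiger_z(0.5, 0.3, 0.2, 100), 1.7803242299, tolerance = 1e-9)
  expect_equal(steiger_z(0.5, 0.3, 0.2, 400), 3.6017079030, tolerance = 1e-9)
  # |Z| grows with n at fixed correlations
  zs <- vapply(c(10, 50, 200, 1000),
               function(n) steiger_z(0.6, 0.4, 0.3, n), numeric(1))
  expect_true(all(diff(zs) > 0))
  # antisymmetry in the two compared correlations
  expect_equal(steiger_z(0.3, 0.5, 0.2, 100),
               -steiger_z(0.5, 0.3, 0.2, 100))
  expect_error(steiger_z(1, 0.3, 0.2, 100), "require")
  expect_error(steiger_z(0.5, 0.3, 0.2, 3), "require")
})

test_that("the smoother preserves simple signals and reduces noise", {
  expect_equal(smooth_series(rep(0.4, 50)), rep(0.4, 50), tolerance = 1e-8)
  lin <- seq(0, 1, length.out = 50)
  expect_equal(smooth_series(lin), lin, tolerance = 1e-6)
  set.seed(5)
  clean <- sin(seq(0, 2 * pi, length.out = 100)) / 4 + 0.5
  noisy <- clean + rnorm(100, 0, 0.1)
  sm <- smooth_series(noisy, span = 0.2)
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
  # NA gaps survive in place
  gap <- noisy
  gap[c(10, 40)] <- NA
  sg <- smooth_series(gap)
  expect_true(all(is.na(sg[c(10, 40)])))
  expect_false(anyNA(sg[-c(10, 40)]))
  expect_error(smooth_series(noisy, span = 0), "span")
})

test_that("round logs round-trip through the CSV schema", {
  runs <- run_condition(condition_table()[1, ],
                        experiment_config(n_runs = 2, master_seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_round_log(runs, path)
  back <- read_round_log(path)
  expect_equal(back$focal_move, runs$focal_move)
  expect_equal(back$agent_move, runs$agent_move)
  expect_equal(back$global_round, runs$global_round)
  expect_equal(unique(back$player_type), "model")
  # outcome classes written match a recomputation
  x <- back[back$run_id == 1 & back$game_index == 1, ]
  x <- x[order(x$round), ]
  expect_equal(x$outcome_class,
               trustgames:::classify_trajectory(x$focal_move, x$agent_move))
  # schema validation
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(condition_id = 1, run_id = 1), bad,
                   row.names = FALSE)
  expect_error(read_round_log(bad), "lacks columns")
})

test_that("synthetic logs realize their requested outcome mix", {
  mix <- c(CC = 0.5, CD = 0.2, DC = 0.2, DD = 0.1)
  runs <- synthetic_round_log(200, 10, mix = mix, game = "CG", seed = 9)
  pair <- paste0(runs$focal_move, runs$agent_move)
  freq <- table(factor(pair, levels = c("BB", "BA", "AB", "AA"))) / nrow(runs)
  expect_true(all(abs(as.vector(freq) - unname(mix)) < 0.03))
  # payoffs follow the declared game
  for (i in sample(nrow(runs), 50)) {
    expect_equal(unname(payoff("CG", runs$focal_move[i], runs$agent_move[i])),
                 c(runs$focal_payoff[i], runs$agent_payoff[i]))
  }
  expect_identical(synthetic_round_log(5, 6, seed = 3),
                   synthetic_round_log(5, 6, seed = 3))
})

test_that("per-class averaged correlation is the mean of column correlations", {
  set.seed(12)
  a <- matrix(runif(50), 10, 5)
  b <- a + matrix(rnorm(50, 0, 0.2), 10, 5)
  fit <- fit_statistics(a, b, by_class = TRUE)
  expect_equal(fit$r, mean(vapply(1:5, function(j) cor(a[, j], b[, j]),
                                  numeric(1))))
  expect_equal(fit$rmsd, fit_statistics(a, b)$rmsd)
  expect_error(fit_statistics(a, b[1:4, ], by_class = TRUE), "congruent")
})
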