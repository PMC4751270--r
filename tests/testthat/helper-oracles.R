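# Independent oracles used across the suite.  These re-derive expected
# values by direct arithmetic or brute force, separately from the
# package's implementation paths.

# Base-level activation by direct power-term summation.
oracle_activation <- function(times, now, d = 0.5) {
  log(sum((now - times)^(-d)))
}

# Brute-force zero-noise prediction: enumerate both candidate
# instances, compute raw activations, take the argmax above tau.
oracle_predict <- function(memory, own_prev, other_prev, d = 0.5,
                           tau = -10) {
  best <- "unknown"
  best_a <- -Inf
  for (cand in c("A", "B")) {
    times <- memory$instances[[paste0(own_prev, other_prev, cand)]]
    if (is.null(times)) next
    a <- log(sum((memory$clock - times)^(-d)))
    if (a >= tau && a > best_a) {
      best <- cand
      best_a <- a
    }
  }
  best
}

# Build an instance memory by encoding (triple, tick) rows.
make_memory <- function(triples, ticks, clock) {
  mem <- instance_memory()
  for (i in seq_along(ticks)) {
    mem$clock <- ticks[i]
    mem <- encode_instance(mem, triples[[i]][1], triples[[i]][2],
                           triples[[i]][3])
  }
  mem$clock <- clock
  mem
}

# A memory with random presentation histories over the 8 possible keys.
random_memory <- function(max_ticks = 12) {
  mem <- instance_memory()
  keys <- expand.grid(o = c("A", "B"), p = c("A", "B"), c = c("A", "B"),
                      stringsAsFactors = FALSE)
  tick <- 0L
  for (t in seq_len(max_ticks)) {
    tick <- tick + 1L
    mem$clock <- tick
    k <- keys[sample.int(8, 1), ]
    mem <- encode_instance(mem, k$o, k$p, k$c)
  }
  mem$clock <- tick + sample.int(3, 1)
  mem
}

# Rows of the three strategy truth tables: game, own previous move,
# other's previous move, own previous payoff, expected move on round N.
strategy_truth_table <- function() {
  rows <- rbind(
    # Tit-for-Tat
    c("T4T", "PD", "A", "A", -1, "A"), c("T4T", "PD", "A", "B", 4, "B"),
    c("T4T", "PD", "B", "A", -4, "A"), c("T4T", "PD", "B", "B", 1, "B"),
    c("T4T", "CG", "A", "A", -4, "A"), c("T4T", "CG", "A", "B", 4, "B"),
    c("T4T", "CG", "B", "A", -1, "A"), c("T4T", "CG", "B", "B", 1, "B"),
    # Pavlov (win-stay / lose-shift)
    c("PAVLOV", "PD", "A", "A", -1, "B"), c("PAVLOV", "PD", "A", "B", 4, "A"),
    c("PAVLOV", "PD", "B", "A", -4, "A"), c("PAVLOV", "PD", "B", "B", 1, "B"),
    c("PAVLOV", "CG", "A", "A", -4, "B"), c("PAVLOV", "CG", "A", "B", 4, "A"),
    c("PAVLOV", "CG", "B", "A", -1, "A"), c("PAVLOV", "CG", "B", "B", 1, "B"),
    # Pavlov-Tit-for-Tat (T4T with win-stay after winning defection)
    c("PT4T", "PD", "A", "A", -1, "A"), c("PT4T", "PD", "A", "B", 4, "A"),
    c("PT4T", "PD", "B", "A", -4, "A"), c("PT4T", "PD", "B", "B", 1, "B"),
    c("PT4T", "CG", "A", "A", -4, "A"), c("PT4T", "CG", "A", "B", 4, "A"),
    c("PT4T", "CG", "B", "A", -1, "A"), c("PT4T", "CG", "B", "B", 1, "B"))
  data.frame(strategy = rows[, 1], game = rows[, 2], own = rows[, 3],
             other = rows[, 4], payoff = as.integer(rows[, 5]),
             expected = rows[, 6], stringsAsFactors = FALSE)
}

# Independent re-implementation of the round pipeline (used to check
# play_round/run_condition against a from-scratch trace under the same
# seed).  Written directly from the round description, not sharing code
# with the package internals.
oracle_run <- function(script, game_name, rounds, params, variant,
                       start_global = 0L) {
  g <- game_spec(game_name)
  util <- c("?|0|0:B" = params$coop_prior)
  mem <- list()
  tr <- 0; iv <- 0
  own_prev <- NULL; oth_prev <- NULL; p2_prev <- 0
  ag_own <- NULL; ag_oth <- NULL; ag_pay <- NULL
  moves <- character(rounds); agents <- character(rounds)
  rewards <- numeric(rounds); trusts <- numeric(rounds)
  for (r in seq_len(rounds)) {
    now <- start_global + r
    # prediction
    pred <- "unknown"
    if (!is.null(own_prev)) {
      best <- -Inf
      for (cand in c("A", "B")) {
        times <- mem[[paste0(own_prev, oth_prev, cand)]]
        if (is.null(times)) next
        noise <- if (params$s_act > 0) rlogis(1, 0, params$s_act) else 0
        a <- log(sum((now - times)^(-params$d))) + noise
        if (a >= params$tau && a > best) { best <- a; pred <- cand }
      }
    }
    ctx <- paste(if (pred == "unknown") "?" else pred,
                 if (is.null(own_prev)) "0" else own_prev,
                 if (is.null(oth_prev)) "0" else oth_prev, sep = "|")
    u <- c(A = 0, B = 0)
    for (m in c("A", "B")) {
      v <- util[paste(ctx, m, sep = ":")]
      if (!is.na(v)) u[m] <- v
    }
    if (params$s_util > 0) u <- u + rlogis(2, 0, params$s_util)
    mv <- if (u[["A"]] == u[["B"]]) c("A", "B")[sample.int(2, 1)]
          else names(u)[which.max(u)]
    ag <- agent_move(script, r, ag_own, ag_oth, ag_pay)
    p <- g$payoff[[paste0(mv, ag)]]
    if (!is.null(own_prev)) {
      key <- paste0(own_prev, oth_prev, ag)
      mem[[key]] <- c(mem[[key]], now)
    }
    tr <- max(-variant$trust_bound, min(variant$trust_bound,
      tr + if (ag == "B") variant$step_trust else -variant$step_trust))
    if (variant$label == "TRUST") {
      if (mv == "A" && ag == "A") iv <- iv + variant$step_invest
      else if (mv == "B" && ag == "A")
        iv <- iv - variant$invest_loss * variant$step_invest
      iv <- max(variant$invest_floor, min(variant$invest_bound, iv))
    }
    fn <- if (variant$label == "FIXED") variant$fixed_reward
          else if (tr > 0) "JOINT_MINUS_PREV"
          else if (variant$label == "TRUST" && iv > 0) "OTHER"
          else "SELFISH"
    rew <- switch(fn, JOINT_MINUS_PREV = p[1] + p[2] - p2_prev,
                  OTHER = p[2], SELFISH = p[1] - p[2],
                  OWN = p[1], JOINT = p[1] + p[2])
    key <- paste(ctx, mv, sep = ":")
    u0 <- util[key]
    if (is.na(u0)) u0 <- 0
    util[key] <- u0 + params$alpha * (rew - u0)
    own_prev <- mv; oth_prev <- ag; p2_prev <- p[2]
    ag_own <- ag; ag_oth <- mv; ag_pay <- p[2]
    moves[r] <- mv; agents[r] <- ag; rewards[r] <- rew; trusts[r] <- tr
  }
  list(moves = moves, agents = agents, rewards = rewards, trusts = trusts)
}

# An always-cooperating scripted agent (every round forced to B).
always_b_script <- function(rounds = 50L) {
  structure(list(strategy = "T4T", trust = "HT", rounds = as.integer(rounds),
                 forced_rounds = seq_len(rounds), forced_move = "B",
                 version_id = 1L, seed = 0L),
            class = "agent_script")
}
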