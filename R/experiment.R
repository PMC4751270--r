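# The 16-condition prediction experiment: 50 model runs per condition,
# two 50-round games with persistent model state, random assignment to
# one of 10 scripted agent versions per game.

#' The 16 experimental conditions
#'
#' Crosses game order (PDPD, PDCG, CGPD, CGCG) with confederate
#' strategy (T4T, PT4T) and trustworthiness (HT, LT).  Shipped as a
#' config file under `inst/extdata/conditions.csv`.
#'
#' @return A data.frame with columns `condition_id`, `game1`, `game2`,
#'   `strategy`, `trust`.
#' @export
condition_table <- function() {
  path <- system.file("extdata", "conditions.csv", package = "trustgames",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Experiment configuration
#'
#' @param n_runs Model runs per condition (default 50).
#' @param rounds_per_game Rounds per game (default 50).
#' @param n_versions Scripted agent versions per strategy x
#'   trustworthiness cell (default 10).
#' @param variant A [model_variant()] or variant token.
#' @param cognitive A [cognitive_params()].
#' @param master_seed Integer master seed; every random draw in the
#'   experiment derives from it.
#' @param strategy_switch If `TRUE`, the confederate agent swaps
#'   strategy (T4T <-> PT4T) for the second game at the same
#'   trustworthiness.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_runs = 50L, rounds_per_game = 50L,
                              n_versions = 10L,
                              variant = model_variant("trust"),
                              cognitive = cognitive_params(),
                              master_seed = 1L,
                              strategy_switch = FALSE) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(n_runs >= 1, rounds_per_game >= 1, n_versions >= 1,
            inherits(variant, "model_variant"),
            inherits(cognitive, "cognitive_params"))
  structure(list(n_runs = as.integer(n_runs),
                 rounds_per_game = as.integer(rounds_per_game),
                 n_versions = as.integer(n_versions),
                 variant = variant, cognitive = cognitive,
                 master_seed = as.integer(master_seed),
                 strategy_switch = isTRUE(strategy_switch)),
            class = "experiment_config")
}

# Deterministic sub-seed derivation.  Streams are split so that the
# agent-version assignment of (condition, run) is identical across
# model variants, enabling paired variant comparisons.  All derived
# seeds stay below 2^31 - 1.
derive_seed <- function(master_seed, condition_id = 0L, run_id = 0L,
                        stream = c("assign", "model", "versions"),
                        cell = 0L) {
  stream <- match.arg(stream)
  base <- (abs(as.integer(master_seed)) %% 100000L) * 16384L
  offset <- switch(stream,
    assign = (condition_id - 1L) * 128L + run_id * 2L,
    model = (condition_id - 1L) * 128L + run_id * 2L + 1L,
    versions = 8192L + cell
  )
  base + offset
}

# Versions are generated once per (strategy, trust) cell so all
# conditions sharing a cell reuse the same 10 scripts, as participants
# were assigned to one of the same 10 versions.
version_cell_seed <- function(master_seed, strategy, trust) {
  cell <- (match(strategy, STRATEGIES) - 1L) * 2L +
    (match(trust, TRUST_LEVELS) - 1L)
  derive_seed(master_seed, stream = "versions", cell = cell)
}

other_strategy <- function(strategy) {
  switch(strategy, T4T = "PT4T", PT4T = "T4T",
         stop("strategy switch is defined for T4T and PT4T only",
              call. = FALSE))
}

# Fresh model state at the start of a condition run.
new_model_state <- function(params = cognitive_params()) {
  list(mem = instance_memory(), util = utility_table(params$coop_prior),
       trust = trust_state(),
       own_prev = NULL, other_prev = NULL,   # model's last moves (continuous)
       p2_prev = 0L,                          # other's last payoff
       agent_prev_own = NULL, agent_prev_other = NULL,
       agent_prev_payoff = NULL)              # agent-side history (per game)
}

#' Play one round of the model-vs-agent pipeline
#'
#' Executes the full round pipeline: memory retrieval predicts the
#' agent's move, noisy utility maximization picks the model's move, the
#' scripted agent moves, payoffs resolve, the round is encoded into
#' declarative memory, the trust accumulators update, the active reward
#' function is selected and its reward reinforces the model's choice.
#'
#' @param state Model state from [new_model_state()] or a previous
#'   round (an opaque list).
#' @param script The agent's script for the current game.
#' @param game A [game_spec()] or game name.
#' @param round_index Round within the game (1-based).
#' @param global_round Round on the continuous clock across both games.
#' @param config An [experiment_config()].
#' @return A list with `record` (one-row data.frame) and `state`.
#' @export
play_round <- function(state, script, game, round_index, global_round,
                       config = experiment_config()) {
  out <- play_round_core(state, script, as_game(game), round_index,
                         global_round, config)
  out$record <- as.data.frame(out$record, stringsAsFactors = FALSE)
  out
}

# Fast path used by the run loop: identical pipeline, record as a
# plain named list.
play_round_core <- function(state, script, game, round_index, global_round,
                            config) {
  params <- config$cognitive
  variant <- config$variant

  state$mem$clock <- as.integer(global_round)
  predicted <- predict_other_move(state$mem, state$own_prev,
                                  state$other_prev, params)
  ctx <- context_key(predicted, state$own_prev, state$other_prev)
  move <- choose_move(state$util, ctx, params)
  agent <- agent_move(script, round_index, state$agent_prev_own,
                      state$agent_prev_other, state$agent_prev_payoff)
  p <- game$payoff[[paste0(move, agent)]]

  if (!is.null(state$own_prev)) {
    state$mem <- encode_instance(state$mem, state$own_prev,
                                 state$other_prev, agent)
  }
  state$trust <- update_trust(state$trust, move, agent, variant)
  fn <- select_reward_function(state$trust, variant)
  reward <- compute_reward(fn, p[1], p[2], state$p2_prev)
  state$util <- update_utility(state$util, ctx, move, reward, params)

  state$own_prev <- move
  state$other_prev <- agent
  state$p2_prev <- p[2]
  state$agent_prev_own <- agent
  state$agent_prev_other <- move
  state$agent_prev_payoff <- p[2]

  record <- list(
    game = game$name, round = round_index, global_round = global_round,
    focal_move = move, agent_move = agent,
    focal_payoff = p[1], agent_payoff = p[2],
    predicted = predicted, reward_fn = fn, reward = reward,
    trust = state$trust$trust, invest = state$trust$invest)
  list(record = record, state = state)
}

# One full run of a condition: two games, persistent model state,
# per-game agent scripts.  Returns a data.frame of 2 * rounds_per_game
# rows.  `versions` is a list(game1 = list of scripts, game2 = ...).
run_one <- function(condition, config, versions, run_id) {
  rpg <- config$rounds_per_game
  n <- 2L * rpg
  with_seed(derive_seed(config$master_seed, condition$condition_id, run_id,
                        "assign"), {
    v <- sample.int(config$n_versions, 2L, replace = TRUE)
  })
  games <- list(as_game(condition$game1), as_game(condition$game2))
  state <- new_model_state(config$cognitive)
  col <- list(game = character(n), round = integer(n),
              global_round = integer(n), focal_move = character(n),
              agent_move = character(n), focal_payoff = integer(n),
              agent_payoff = integer(n), predicted = character(n),
              reward_fn = character(n), reward = numeric(n),
              trust = numeric(n), invest = numeric(n),
              game_index = integer(n), version_id = integer(n))

  with_seed(derive_seed(config$master_seed, condition$condition_id, run_id,
                        "model"), {
    for (g in 1:2) {
      script <- versions[[g]][[v[g]]]
      # agent history resets at each game's round 1
      state$agent_prev_own <- NULL
      state$agent_prev_other <- NULL
      state$agent_prev_payoff <- NULL
      for (r in seq_len(rpg)) {
        i <- (g - 1L) * rpg + r
        out <- play_round_core(state, script, games[[g]], r, i, config)
        state <- out$state
        rec <- out$record
        for (nm in names(rec)) col[[nm]][i] <- rec[[nm]]
        col$game_index[i] <- g
        col$version_id[i] <- script$version_id
      }
    }
  })
  run <- as.data.frame(col, stringsAsFactors = FALSE)
  run$condition_id <- condition$condition_id
  run$run_id <- run_id
  run
}

#' Run all model runs of one experimental condition
#'
#' Each of the `n_runs` runs plays the condition's two games against an
#' agent version drawn uniformly per game from the condition's
#' strategy x trustworthiness cell; the model's memory, utilities and
#' trust accumulators persist from game 1 into game 2.  Fully
#' reproducible from the config's master seed.
#'
#' @param condition One row of [condition_table()] (as a list or
#'   one-row data.frame).
#' @param config An [experiment_config()].
#' @return A data.frame of round records (`n_runs * 2 *
#'   rounds_per_game` rows) with columns `condition_id`, `run_id`,
#'   `game_index`, `game`, `round`, `global_round`, `focal_move`,
#'   `agent_move`, `focal_payoff`, `agent_payoff`, `predicted`,
#'   `reward_fn`, `reward`, `trust`, `invest`, `version_id`.
#' @export
run_condition <- function(condition, config = experiment_config()) {
  condition <- as.list(condition)
  strat2 <- if (config$strategy_switch) other_strategy(condition$strategy)
            else condition$strategy
  versions <- list(
    generate_agent_versions(condition$strategy, condition$trust,
                            config$n_versions, config$rounds_per_game,
                            version_cell_seed(config$master_seed,
                                              condition$strategy,
                                              condition$trust)),
    generate_agent_versions(strat2, condition$trust,
                            config$n_versions, config$rounds_per_game,
                            version_cell_seed(config$master_seed, strat2,
                                              condition$trust)))
  out <- do.call(rbind, lapply(seq_len(config$n_runs), function(i) {
    run_one(condition, config, versions, i)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full 16-condition experiment
#'
#' @param config An [experiment_config()].
#' @param conditions Condition table (default [condition_table()]).
#' @return A data.frame concatenating [run_condition()] over all
#'   conditions.
#' @examples
#' \donttest{
#' runs <- run_experiment(experiment_config(n_runs = 2, master_seed = 1))
#' }
#' @export
run_experiment <- function(config = experiment_config(),
                           conditions = condition_table()) {
  out <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    run_condition(conditions[i, ], config)
  }))
  rownames(out) <- NULL
  out
}
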