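# Round-log CSV schema (read/write) and a synthetic round-log
# generator with controllable outcome mixes for testing the metrics
# layer and ingesting third-party play records.

ROUND_LOG_COLUMNS <- c("condition_id", "run_id", "player_type",
                       "game_index", "round", "focal_move", "agent_move",
                       "focal_payoff", "agent_payoff", "outcome_class")

#' Write and read round logs in the package's CSV schema
#'
#' The schema has columns `condition_id`, `run_id`, `player_type`
#' (`model` or `human`), `game_index` (1 or 2), `round` (1-based within
#' the game), `focal_move`, `agent_move` (`A`/`B`), `focal_payoff`,
#' `agent_payoff`, and `outcome_class`.  `write_round_log()` derives
#' missing `outcome_class` / `player_type` columns; `read_round_log()`
#' validates the schema and reconstructs `global_round`.
#'
#' @param runs A round-log data.frame (e.g. from [run_experiment()]).
#' @param path CSV file path.
#' @param player_type Value for the `player_type` column if absent.
#' @return `read_round_log()` returns the validated data.frame;
#'   `write_round_log()` returns `path` invisibly.
#' @export
write_round_log <- function(runs, path, player_type = "model") {
  if (is.null(runs$player_type)) runs$player_type <- player_type
  if (is.null(runs$outcome_class)) {
    runs$outcome_class <- NA_character_
    key <- interaction(runs$condition_id, runs$run_id, runs$game_index,
                       drop = TRUE)
    for (idx in split(seq_len(nrow(runs)), key)) {
      idx <- idx[order(runs$round[idx])]
      runs$outcome_class[idx] <-
        classify_trajectory(runs$focal_move[idx], runs$agent_move[idx])
    }
  }
  utils::write.csv(runs[, ROUND_LOG_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_round_log
#' @export
read_round_log <- function(path) {
  runs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ROUND_LOG_COLUMNS, names(runs))
  if (length(missing) > 0) {
    stop("round log lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_move(c(runs$focal_move, runs$agent_move))
  rpg <- max(runs$round)
  runs$global_round <- (runs$game_index - 1L) * rpg + runs$round
  runs
}

#' Generate synthetic round logs with a controlled outcome mix
#'
#' Draws each round's move pair independently from a given
#' distribution over the four move-pair outcomes (focal perspective),
#' either one distribution for all rounds or a per-round schedule.
#' Useful as ground truth for the metrics layer: the expected
#' proportion profile is the mix itself.
#'
#' @param n_runs Number of runs.
#' @param rounds Rounds per game.
#' @param mix Named probability vector over `c("CC","CD","DC","DD")`,
#'   or a `rounds x 4` matrix of per-round probabilities.
#' @param n_games Number of games (default 1).
#' @param game Game name used for payoffs (default `"PD"`).
#' @param condition_id Condition id stamped on the log.
#' @param seed Integer seed.
#' @return A round-log data.frame (with `global_round`).
#' @export
synthetic_round_log <- function(n_runs, rounds,
                                mix = c(CC = 0.25, CD = 0.25,
                                        DC = 0.25, DD = 0.25),
                                n_games = 1L, game = "PD",
                                condition_id = 0L, seed = 1L) {
  pairs <- c(CC = "BB", CD = "BA", DC = "AB", DD = "AA")
  if (is.matrix(mix)) {
    stopifnot(nrow(mix) == rounds, ncol(mix) == 4)
    colnames(mix) <- names(pairs)
  } else {
    stopifnot(length(mix) == 4, abs(sum(mix) - 1) < 1e-9)
    mix <- matrix(rep(mix, each = rounds), rounds, 4,
                  dimnames = list(NULL, names(pairs)))
  }
  g <- as_game(game)
  rows <- with_seed(as.integer(seed), {
    lapply(seq_len(n_runs * n_games), function(k) {
      run <- (k - 1L) %/% n_games + 1L
      gi <- (k - 1L) %% n_games + 1L
      outc <- vapply(seq_len(rounds), function(r) {
        sample(names(pairs), 1L, prob = mix[r, ])
      }, character(1))
      mv <- pairs[outc]
      focal <- substr(mv, 1, 1)
      other <- substr(mv, 2, 2)
      pay <- t(vapply(seq_len(rounds),
                      function(r) g$payoff[[mv[r]]], integer(2)))
      data.frame(condition_id = condition_id, run_id = run,
                 player_type = "synthetic", game_index = gi,
                 game = g$name, round = seq_len(rounds),
                 global_round = (gi - 1L) * rounds + seq_len(rounds),
                 focal_move = focal, agent_move = other,
                 focal_payoff = pay[, 1], agent_payoff = pay[, 2],
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
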