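# Moves, payoff structures, round resolution and outcome classification.

MOVES <- c("A", "B")

OUTCOME_CLASSES <- c("CC", "CD", "DC", "DD", "ALT")

#' Moves and payoff structures
#'
#' Both games use two moves: `"A"` (defect) and `"B"` (cooperate).
#' `complement_move()` maps each move to the other one.
#'
#' @param move A move, `"A"` or `"B"`.
#' @return `complement_move()` returns the opposite move.
#' @examples
#' complement_move("A")
#' @export
complement_move <- function(move) {
  check_move(move)
  ifelse(move == "A", "B", "A")
}

check_move <- function(move) {
  if (!all(move %in% MOVES)) {
    stop("moves must be \"A\" (defect) or \"B\" (cooperate)", call. = FALSE)
  }
  invisible(move)
}

# Payoff tables indexed by "<focal><other>"; values are c(focal, other).
# PD: mutual cooperation pays 1 each, mutual defection costs 1 each,
# unilateral defection pays 4 to the defector and -4 to the cooperator.
# CG: mutual defection is the catastrophic cell (-4 each); the unilateral
# cooperator loses only 1 while the defector earns 4.
.PAYOFFS <- list(
  PD = list(BB = c(1L, 1L), AA = c(-1L, -1L), AB = c(4L, -4L), BA = c(-4L, 4L)),
  CG = list(BB = c(1L, 1L), AA = c(-4L, -4L), AB = c(4L, -1L), BA = c(-1L, 4L))
)

#' Game specification for Prisoner's Dilemma or Chicken
#'
#' Returns the 2x2 payoff structure of one of the two supported games.
#' Both games are symmetric under player exchange.
#'
#' @param name `"PD"` (Prisoner's Dilemma) or `"CG"` (Chicken Game).
#' @return An object of class `game_spec` with elements `name` and
#'   `payoff` (a list keyed by the focal/other move pair).
#' @examples
#' game_spec("PD")
#' @export
game_spec <- function(name) {
  name <- toupper(as.character(name))
  if (length(name) != 1L || !name %in% names(.PAYOFFS)) {
    stop("unknown game name; use \"PD\" or \"CG\"", call. = FALSE)
  }
  structure(list(name = name, payoff = .PAYOFFS[[name]]), class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat("<game_spec>", x$name, "\n")
  for (k in names(x$payoff)) {
    cat(sprintf("  (%s,%s) -> (%d, %d)\n", substr(k, 1, 1), substr(k, 2, 2),
                x$payoff[[k]][1], x$payoff[[k]][2]))
  }
  invisible(x)
}

as_game <- function(game) {
  if (inherits(game, "game_spec")) game else game_spec(game)
}

#' Resolve the payoffs of a single round
#'
#' @param game A [game_spec()] or a game name.
#' @param focal,other Moves of the focal and other player.
#' @return Integer vector `c(focal = ..., other = ...)`.
#' @examples
#' payoff("PD", "A", "B")  # defector earns 4, cooperator loses 4
#' @export
payoff <- function(game, focal, other) {
  game <- as_game(game)
  check_move(c(focal, other))
  p <- game$payoff[[paste0(focal, other)]]
  c(focal = p[1], other = p[2])
}

#' Classify a round into one of five outcome classes
#'
#' Classes are `CC` (mutual cooperation), `CD` (focal cooperates, other
#' defects), `DC` (focal defects, other cooperates), `DD` (mutual
#' defection) and `ALT` (asymmetric alternation).  A round with opposite
#' moves is `ALT` when the previous round also had opposite moves and each
#' player switched move between the rounds; `ALT` takes precedence over
#' `CD`/`DC` so the five classes partition the rounds.  Round 1 (no
#' previous round) can never be `ALT`.
#'
#' @param cur_focal,cur_other Moves of the current round.
#' @param prev_focal,prev_other Moves of the previous round, or `NULL`
#'   for the first round.
#' @return One of `"CC" "CD" "DC" "DD" "ALT"`.
#' @examples
#' classify_round("A", "B", prev_focal = "B", prev_other = "A")  # "ALT"
#' @export
classify_round <- function(cur_focal, cur_other,
                           prev_focal = NULL, prev_other = NULL) {
  check_move(c(cur_focal, cur_other))
  if (cur_focal == cur_other) {
    return(if (cur_focal == "B") "CC" else "DD")
  }
  if (!is.null(prev_focal) && !is.null(prev_other)) {
    check_move(c(prev_focal, prev_other))
    if (prev_focal != prev_other &&
        cur_focal != prev_focal && cur_other != prev_other) {
      return("ALT")
    }
  }
  if (cur_focal == "B") "CD" else "DC"
}

# Vectorised 5-way classification of a trajectory of move pairs,
# restarting (no ALT) at position 1.
classify_trajectory <- function(focal, other) {
  n <- length(focal)
  stopifnot(length(other) == n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (i == 1L) {
      classify_round(focal[i], other[i])
    } else {
      classify_round(focal[i], other[i], focal[i - 1L], other[i - 1L])
    }
  }
  out
}

#' Mean per-round payoff of a sustained optimal pattern
#'
#' Under repeated mutual cooperation each player earns 1 point per round
#' in both games.  Under perfect asymmetric alternation in Chicken the
#' players trade the 4 and -1 payoffs, averaging 1.5 points per round.
#'
#' @param game A [game_spec()] or game name.
#' @param pattern `"mutual_cooperation"` or `"alternation"`.
#' @param rounds Number of rounds; must be even for alternation.
#' @return Mean per-round payoff of either player.
#' @examples
#' optimal_stream_payoff("CG", "alternation", 50)  # 1.5
#' @export
optimal_stream_payoff <- function(game, pattern = c("mutual_cooperation",
                                                    "alternation"),
                                  rounds) {
  game <- as_game(game)
  pattern <- match.arg(pattern)
  stopifnot(rounds >= 1)
  if (pattern == "mutual_cooperation") {
    return(payoff(game, "B", "B")[["focal"]])
  }
  if (rounds %% 2 != 0) {
    stop("alternation requires an even number of rounds", call. = FALSE)
  }
  (payoff(game, "A", "B")[["focal"]] + payoff(game, "B", "A")[["focal"]]) / 2
}
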