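# Scripted confederate strategies (T4T, Pavlov, PT4T) and the
# trustworthiness-manipulated agent versions.

STRATEGIES <- c("T4T", "PAVLOV", "PT4T")
TRUST_LEVELS <- c("HT", "LT")

# Forced (random cooperation/defection) round counts per strategy over a
# 50-round game: T4T plays its strategy on 90% of rounds (5 forced),
# PT4T on 65% (17 forced).
forced_round_count <- function(strategy, rounds = 50L) {
  frac <- switch(strategy, T4T = 0.10, PT4T = 0.35,
                 PAVLOV = 0.10)  # Pavlov scripts mirror the T4T rate
  as.integer(frac * rounds)      # 50 rounds: 5 for T4T, 17 for PT4T
}

#' Deterministic move of a confederate strategy
#'
#' Implements the strategy truth tables for Tit-for-Tat (`"T4T"`),
#' Pavlov (`"PAVLOV"`, win-stay/lose-shift) and Pavlov-Tit-for-Tat
#' (`"PT4T"`).  T4T copies the other player's previous move.  Pavlov
#' repeats its own previous move iff its previous payoff was positive.
#' PT4T behaves as T4T except after its own winning defection (it chose
#' A, the other chose B), where it stays with A; equivalently it
#' cooperates only after mutual cooperation.  On round 1 (no history)
#' every strategy opens with `"B"`.
#'
#' @param strategy `"T4T"`, `"PAVLOV"` or `"PT4T"`.
#' @param own_prev,other_prev The strategy's and the other player's
#'   moves on the previous round, or `NULL` on round 1.
#' @param own_prev_payoff The strategy's payoff on the previous round
#'   (needed by Pavlov), or `NULL` on round 1.
#' @param opening Move played on round 1 (default `"B"`).
#' @return A move.
#' @examples
#' strategy_move("T4T", own_prev = "B", other_prev = "A",
#'               own_prev_payoff = -4)   # reciprocates the defection
#' @export
strategy_move <- function(strategy, own_prev = NULL, other_prev = NULL,
                          own_prev_payoff = NULL, opening = "B") {
  strategy <- match.arg(strategy, STRATEGIES)
  args_null <- c(is.null(own_prev), is.null(other_prev),
                 is.null(own_prev_payoff))
  if (any(args_null) && !all(args_null)) {
    stop("previous-round arguments must be all NULL (round 1) or all given",
         call. = FALSE)
  }
  if (all(args_null)) {
    check_move(opening)
    return(opening)
  }
  check_move(c(own_prev, other_prev))
  switch(strategy,
    T4T = other_prev,
    PAVLOV = if (own_prev_payoff > 0) own_prev else complement_move(own_prev),
    PT4T = if (own_prev == "B" && other_prev == "B") "B" else "A"
  )
}

#' Generate scripted confederate agent versions
#'
#' Each version is a 50-round plan: the strategy governs most rounds,
#' while a fixed set of forced rounds implements the trustworthiness
#' manipulation — forced cooperation (`B`) under high trustworthiness
#' (`"HT"`), forced defection (`A`) under low (`"LT"`).  T4T scripts
#' force 5 of 50 rounds (10%), PT4T scripts 17 (35%).  Forced-round
#' positions are sampled uniformly without replacement, independently
#' per version, and are fixed thereafter so the same versions can be
#' reused across runs.
#'
#' @param strategy `"T4T"`, `"PAVLOV"` or `"PT4T"`.
#' @param trust `"HT"` or `"LT"`.
#' @param n_versions Number of versions to generate (default 10).
#' @param rounds Rounds per game (default 50).
#' @param seed Integer seed; the same arguments always produce the same
#'   scripts.
#' @return A list of `agent_script` objects with fields `strategy`,
#'   `trust`, `rounds`, `forced_rounds`, `forced_move`, `version_id`,
#'   `seed`.
#' @examples
#' scripts <- generate_agent_versions("T4T", "HT", seed = 1)
#' length(scripts[[1]]$forced_rounds)  # 5
#' @export
generate_agent_versions <- function(strategy, trust, n_versions = 10L,
                                    rounds = 50L, seed) {
  strategy <- match.arg(strategy, STRATEGIES)
  trust <- match.arg(trust, TRUST_LEVELS)
  stopifnot(n_versions >= 1, !missing(seed))
  n_forced <- forced_round_count(strategy, rounds)
  if (rounds < n_forced) {
    stop("rounds is smaller than the required forced-round count",
         call. = FALSE)
  }
  forced_move <- if (trust == "HT") "B" else "A"
  out <- vector("list", n_versions)
  with_seed(as.integer(seed), {
    for (v in seq_len(n_versions)) {
      out[[v]] <- structure(
        list(strategy = strategy, trust = trust, rounds = as.integer(rounds),
             forced_rounds = sort(sample.int(rounds, n_forced)),
             forced_move = forced_move, version_id = v,
             seed = as.integer(seed)),
        class = "agent_script")
    }
  })
  out
}

#' @export
print.agent_script <- function(x, ...) {
  cat(sprintf("<agent_script> %s %s v%d: %d rounds, forced %s on {%s}\n",
              x$strategy, x$trust, x$version_id, x$rounds, x$forced_move,
              paste(x$forced_rounds, collapse = ",")))
  invisible(x)
}

#' Move of a scripted confederate agent on a given round
#'
#' Returns the script's forced move if the round is a forced round,
#' otherwise delegates to [strategy_move()] using the actual previous
#' moves (including any previous forced move).
#'
#' @param script An `agent_script` from [generate_agent_versions()].
#' @param round_index Round number within the game (1-based).
#' @param own_prev,other_prev,own_prev_payoff Previous-round history
#'   from the agent's perspective; all `NULL` on round 1.
#' @return A move.
#' @export
agent_move <- function(script, round_index, own_prev = NULL,
                       other_prev = NULL, own_prev_payoff = NULL) {
  stopifnot(inherits(script, "agent_script"))
  if (round_index < 1L || round_index > script$rounds) {
    stop("round_index out of the script's range", call. = FALSE)
  }
  if (round_index %in% script$forced_rounds) {
    return(script$forced_move)
  }
  strategy_move(script$strategy, own_prev, other_prev, own_prev_payoff)
}

#' Serialize agent scripts to and from YAML
#'
#' @param scripts A list of `agent_script` objects (or a single one).
#' @param path File path.
#' @return `read_agent_scripts()` returns a list of `agent_script`
#'   objects; `write_agent_scripts()` returns `path` invisibly.
#' @export
write_agent_scripts <- function(scripts, path) {
  if (inherits(scripts, "agent_script")) scripts <- list(scripts)
  docs <- lapply(scripts, function(s) {
    list(strategy = s$strategy, trust = s$trust, rounds = s$rounds,
         forced_rounds = as.integer(s$forced_rounds),
         forced_move = s$forced_move, version_id = s$version_id,
         seed = s$seed)
  })
  yaml::write_yaml(docs, path)
  invisible(path)
}

#' @rdname write_agent_scripts
#' @export
read_agent_scripts <- function(path) {
  docs <- yaml::read_yaml(path)
  lapply(docs, function(d) {
    structure(list(strategy = d$strategy, trust = d$trust,
                   rounds = as.integer(d$rounds),
                   forced_rounds = sort(as.integer(d$forced_rounds)),
                   forced_move = d$forced_move,
                   version_id = as.integer(d$version_id),
                   seed = as.integer(d$seed)),
              class = "agent_script")
  })
}

# Evaluate an expression with a temporary RNG seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
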