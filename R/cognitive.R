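# Declarative instance memory with activation-based retrieval and the
# utility-learning action selector.

#' Cognitive parameters of the learning model
#'
#' Bundles the ACT-R-style parameters governing memory and choice:
#' base-level decay `d`, logistic activation-noise scale `s_act`,
#' retrieval threshold `tau` (default -10, effectively disabled),
#' utility learning rate `alpha`, logistic utility-noise scale
#' `s_util`, and the cooperative opening prior `coop_prior` (the
#' initial utility of cooperating in the no-history opening context,
#' reflecting that players tend to open cooperatively).  Defaults are
#' the package's calibrated values; all are config-exposed.
#'
#' @param d Base-level decay rate (> 0).
#' @param s_act Activation noise scale (>= 0).
#' @param tau Retrieval threshold.
#' @param alpha Utility learning rate in (0, 1].
#' @param s_util Utility noise scale (>= 0).
#' @param coop_prior Initial utility of move `B` in the opening
#'   context (>= 0).
#' @return A list of class `cognitive_params`.
#' @export
cognitive_params <- function(d = 0.5, s_act = 0.5, tau = -10,
                             alpha = 0.3, s_util = 0.3, coop_prior = 1) {
  stopifnot(d > 0, s_act >= 0, alpha > 0, alpha <= 1, s_util >= 0,
            coop_prior >= 0)
  structure(list(d = d, s_act = s_act, tau = tau,
                 alpha = alpha, s_util = s_util, coop_prior = coop_prior),
            class = "cognitive_params")
}

#' Declarative instance memory
#'
#' Stores time-stamped instances keyed by the triple (own previous
#' move, other's previous move, other's current move) — at most
#' 2 x 2 x 2 = 8 distinct keys.  Re-encoding an existing triple appends
#' a presentation time, strengthening it.  `clock` is the current
#' round-clock tick (one tick per round, continuous across games).
#'
#' @return An `instance_memory` list with elements `instances` (a named
#'   list of presentation-time vectors) and `clock`.
#' @export
instance_memory <- function() {
  structure(list(instances = list(), clock = 0L), class = "instance_memory")
}

instance_key <- function(own_prev, other_prev, other_cur) {
  paste0(own_prev, other_prev, other_cur)
}

#' Encode one instance into declarative memory
#'
#' Appends the memory's current clock tick to the presentation times of
#' the matching instance, creating the instance if absent.
#'
#' @param memory An [instance_memory()].
#' @param own_prev,other_prev,other_cur The instance triple.
#' @return The updated memory.
#' @export
encode_instance <- function(memory, own_prev, other_prev, other_cur) {
  check_move(c(own_prev, other_prev, other_cur))
  key <- instance_key(own_prev, other_prev, other_cur)
  memory$instances[[key]] <- c(memory$instances[[key]], memory$clock)
  memory
}

#' Base-level activation of an instance
#'
#' Computes `ln(sum_j (now - t_j)^(-d)) + noise` over the instance's
#' presentation times `t_j` — more presentations and more recent
#' presentations both raise activation; time passing lowers it.
#'
#' @param times Presentation-time ticks (all `< now`).
#' @param now Current clock tick.
#' @param params A [cognitive_params()].
#' @param noise Noise term added by the caller (drawn from a logistic
#'   distribution of scale `s_act` during simulation).
#' @return Activation value.
#' @examples
#' activation(c(1, 2), now = 3)  # log(2^-0.5 + 1^-0.5)
#' @export
activation <- function(times, now, params = cognitive_params(), noise = 0) {
  if (length(times) == 0L) return(-Inf)
  if (now <= max(times)) {
    stop("now must exceed every presentation time", call. = FALSE)
  }
  log(sum((now - times)^(-params$d))) + noise
}

#' Predict the other player's next move by memory retrieval
#'
#' Using the previous own and other moves as exact-match retrieval
#' cues, returns the `other_cur` slot of the most active matching
#' instance (noisy activation above the threshold `tau`), i.e. the move
#' the other player most memorably chose in this situation before.
#' Returns `"unknown"` when a cue is missing (round 1), no instance
#' matches, or all matches fall below threshold.
#'
#' @param memory An [instance_memory()]; retrieval happens at its
#'   current `clock` tick.
#' @param own_prev,other_prev Retrieval cues, or `NULL` on round 1.
#' @param params A [cognitive_params()].
#' @return `"A"`, `"B"` or `"unknown"`.
#' @export
predict_other_move <- function(memory, own_prev = NULL, other_prev = NULL,
                               params = cognitive_params()) {
  if (is.null(own_prev) || is.null(other_prev)) return("unknown")
  check_move(c(own_prev, other_prev))
  best <- "unknown"
  best_a <- -Inf
  for (cand in MOVES) {
    times <- memory$instances[[instance_key(own_prev, other_prev, cand)]]
    if (is.null(times)) next
    noise <- if (params$s_act > 0) stats::rlogis(1, 0, params$s_act) else 0
    a <- activation(times, memory$clock, params, noise)
    if (a >= params$tau && a > best_a) {
      best <- cand
      best_a <- a
    }
  }
  best
}

# Utility-table context key: predicted other move ("A"/"B"/"?") x own
# previous move ("A"/"B"/"0") x other previous move.
context_key <- function(predicted, own_prev = NULL, other_prev = NULL) {
  paste(if (identical(predicted, "unknown")) "?" else predicted,
        if (is.null(own_prev)) "0" else own_prev,
        if (is.null(other_prev)) "0" else other_prev,
        sep = "|")
}

#' Utility table for action selection
#'
#' A mapping from (context, action) to a learned utility, initialized
#' at 0 for unseen pairs.  Contexts pair the predicted other move with
#' the previous moves of both players.  `coop_prior` seeds the utility
#' of cooperating in the no-history opening context, so a fresh model
#' leans cooperative on round 1 and then learns from rewards.
#'
#' @param coop_prior Initial utility of `B` in the opening context.
#' @return A named numeric vector of class `utility_table`.
#' @export
utility_table <- function(coop_prior = 0) {
  u <- structure(stats::setNames(numeric(0), character(0)),
                 class = "utility_table")
  if (coop_prior != 0) {
    u[[paste(context_key("unknown"), "B", sep = ":")]] <- coop_prior
  }
  u
}

utility_of <- function(table, context, action) {
  i <- match(paste(context, action, sep = ":"), names(table))
  if (is.na(i)) 0 else table[[i]]
}

#' Choose a move by noisy utility maximization
#'
#' Adds logistic noise of scale `s_util` to each action's utility in
#' the given context and returns the argmax; exact ties (the zero-noise
#' case with equal utilities) are broken uniformly at random.
#'
#' @param table A [utility_table()].
#' @param context A context key from the round pipeline.
#' @param params A [cognitive_params()].
#' @return A move.
#' @export
choose_move <- function(table, context, params = cognitive_params()) {
  u <- vapply(MOVES, function(m) utility_of(table, context, m), numeric(1))
  if (params$s_util > 0) {
    u <- u + stats::rlogis(length(u), 0, params$s_util)
  }
  if (u[1] == u[2]) return(MOVES[sample.int(2L, 1L)])
  MOVES[which.max(u)]
}

#' Reinforce the action just taken
#'
#' Difference-learning update `U <- U + alpha * (reward - U)` applied
#' to the (context, action) pair of the completed round; every other
#' entry is unchanged.
#'
#' @param table A [utility_table()].
#' @param context Context key of the round.
#' @param action The move that was taken.
#' @param reward Reward delivered by the selected reward function.
#' @param params A [cognitive_params()].
#' @return The updated table.
#' @export
update_utility <- function(table, context, action, reward,
                           params = cognitive_params()) {
  stopifnot(is.finite(reward))
  key <- paste(context, action, sep = ":")
  u <- utility_of(table, context, action)
  table[[key]] <- u + params$alpha * (reward - u)
  table
}

#' Serialize memory or utility state to JSON (debugging snapshots)
#'
#' @param x An `instance_memory` or `utility_table`.
#' @return A JSON string.
#' @export
state_json <- function(x) {
  if (inherits(x, "instance_memory")) {
    jsonlite::toJSON(list(clock = x$clock, instances = x$instances),
                     auto_unbox = TRUE)
  } else if (inherits(x, "utility_table")) {
    jsonlite::toJSON(as.list(unclass(x)), auto_unbox = TRUE)
  } else {
    stop("unsupported object", call. = FALSE)
  }
}
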