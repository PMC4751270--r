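# The trust mechanism: two accumulators (trust, trust-invest) whose
# signs select among three reward functions, plus the fixed-reward and
# reactive model variants used for comparison.

REWARD_FUNCTIONS <- c("JOINT_MINUS_PREV", "OTHER", "SELFISH", "OWN", "JOINT")

#' Trust state
#'
#' The two accumulators of the trust mechanism.  `trust` tracks the
#' other player's demonstrated trustworthiness (the reactive component);
#' `invest` tracks trust necessity — the need to establish trust (the
#' proactive component).  Both start at zero at the start of the first
#' game and persist across a condition's two games.
#'
#' @param trust,invest Initial accumulator values.
#' @return A list of class `trust_state`.
#' @export
trust_state <- function(trust = 0, invest = 0) {
  structure(list(trust = trust, invest = invest), class = "trust_state")
}

#' Model variant specification
#'
#' `"trust"` is the full two-accumulator model; `"reactive"` uses only
#' the trust accumulator (switching between the joint-minus-previous
#' and selfish rewards); `"fixed:<fn>"` disables the mechanism and
#' reinforces with a single fixed reward function, one of `fixed:P1`,
#' `fixed:P2`, `fixed:P1+P2`, `fixed:P1-P2`, `fixed:P1+P2-P2prev`.
#'
#' Both accumulators are bounded, leaky-free evidence counters.  Trust
#' saturates at `c(-trust_bound, trust_bound)`: a small bound keeps the
#' mechanism responsive, so a handful of defections can flip the regime
#' even after a long cooperative history.  Trust-invest saturates at
#' `invest_bound` above and `invest_floor` below, and a failed
#' investment (own unilateral cooperation that the other exploits)
#' costs `invest_loss` steps rather than one: after a repair attempt
#' fails, proactive investment stays silenced for a long stretch of
#' mutual defection rather than re-triggering every few rounds.
#'
#' @param token Variant token (see Details).
#' @param step_trust,step_invest Accumulator step sizes per event.
#' @param trust_bound Saturation bound of the trust accumulator.
#' @param invest_bound Upper saturation bound of trust-invest.
#' @param invest_loss Trust-invest decrement (in steps) after a failed
#'   investment.
#' @param invest_floor Lower saturation bound of trust-invest.
#' @return A list of class `model_variant`.
#' @examples
#' model_variant("trust")
#' model_variant("fixed:P1-P2")
#' @export
model_variant <- function(token = "trust", step_trust = 1, step_invest = 1,
                          trust_bound = 2, invest_bound = 2,
                          invest_loss = 25, invest_floor = -50) {
  token <- tolower(token)
  fixed_map <- c("fixed:p1" = "OWN", "fixed:p2" = "OTHER",
                 "fixed:p1+p2" = "JOINT", "fixed:p1-p2" = "SELFISH",
                 "fixed:p1+p2-p2prev" = "JOINT_MINUS_PREV")
  if (token %in% c("trust", "reactive")) {
    label <- toupper(token)
    fixed <- NA_character_
  } else if (token %in% names(fixed_map)) {
    label <- "FIXED"
    fixed <- fixed_map[[token]]
  } else {
    stop("unknown variant token: ", token, call. = FALSE)
  }
  stopifnot(step_trust > 0, step_invest > 0, trust_bound > 0,
            invest_bound > 0, invest_loss > 0, invest_floor < 0)
  structure(list(label = label, fixed_reward = fixed, token = token,
                 step_trust = step_trust, step_invest = step_invest,
                 trust_bound = trust_bound, invest_bound = invest_bound,
                 invest_loss = invest_loss, invest_floor = invest_floor),
            class = "model_variant")
}

#' All seven variant tokens used in the model comparison
#'
#' @return Character vector: the trust model, the reactive model, and
#'   the five fixed-reward variants.
#' @export
variant_tokens <- function() {
  c("trust", "reactive", "fixed:P1", "fixed:P2", "fixed:P1+P2",
    "fixed:P1-P2", "fixed:P1+P2-P2prev")
}

#' Update the trust accumulators after a round
#'
#' The trust accumulator rises when the other player cooperated (mutual
#' cooperation, or the focal player's unilateral defection) and falls
#' when the other defected (mutual defection, unilateral cooperation),
#' saturating at `trust_bound`.  The trust-invest accumulator rises
#' after mutual defection and falls -- by `invest_loss` steps -- after
#' the focal player's own exploited unilateral cooperation; it is
#' unchanged otherwise and saturates at `invest_bound` /
#' `invest_floor`.  The reactive variant updates trust only; fixed
#' variants leave the state untouched.
#'
#' @param state A [trust_state()].
#' @param focal_move,other_move The round's moves.
#' @param variant A [model_variant()].
#' @return The updated state.
#' @export
update_trust <- function(state, focal_move, other_move,
                         variant = model_variant("trust")) {
  check_move(c(focal_move, other_move))
  if (variant$label == "FIXED") return(state)
  delta <- if (other_move == "B") variant$step_trust else -variant$step_trust
  state$trust <- clamp(state$trust + delta,
                       -variant$trust_bound, variant$trust_bound)
  if (variant$label == "TRUST") {
    iv <- state$invest
    if (focal_move == "A" && other_move == "A") {
      iv <- iv + variant$step_invest
    } else if (focal_move == "B" && other_move == "A") {
      iv <- iv - variant$invest_loss * variant$step_invest
    }
    state$invest <- clamp(iv, variant$invest_floor, variant$invest_bound)
  }
  state
}

clamp <- function(x, lo, hi) max(lo, min(hi, x))

#' Select the active reward function from the trust state
#'
#' For the trust model: a positive trust accumulator (regardless of
#' trust-invest) selects the joint-payoff-minus-previous reward; when
#' only trust-invest is positive the model is rewarded by the other
#' player's payoff (investing in trust); when both are at or below zero
#' it is rewarded selfishly (own minus other payoff).  The reactive
#' variant has no invest branch; fixed variants always return their
#' fixed function.
#'
#' @param state A [trust_state()].
#' @param variant A [model_variant()].
#' @return A reward-function id.
#' @export
select_reward_function <- function(state, variant = model_variant("trust")) {
  switch(variant$label,
    FIXED = variant$fixed_reward,
    REACTIVE = if (state$trust > 0) "JOINT_MINUS_PREV" else "SELFISH",
    TRUST = if (state$trust > 0) "JOINT_MINUS_PREV"
            else if (state$invest > 0) "OTHER"
            else "SELFISH"
  )
}

#' Evaluate a reward function
#'
#' @param fn A reward-function id: `"JOINT_MINUS_PREV"` (P1n + P2n -
#'   P2n-1), `"OTHER"` (P2n), `"SELFISH"` (P1n - P2n), `"OWN"` (P1n),
#'   `"JOINT"` (P1n + P2n).
#' @param p1_n,p2_n This round's focal and other payoffs.
#' @param p2_prev The other player's previous-round payoff; 0 on the
#'   first round of the first game, and carried continuously across the
#'   two games.
#' @return The reward value.
#' @examples
#' compute_reward("JOINT_MINUS_PREV", 1, 1, -4)  # 6
#' @export
compute_reward <- function(fn, p1_n, p2_n, p2_prev = 0) {
  fn <- match.arg(fn, REWARD_FUNCTIONS)
  switch(fn,
    JOINT_MINUS_PREV = p1_n + p2_n - p2_prev,
    OTHER = p2_n,
    SELFISH = p1_n - p2_n,
    OWN = p1_n,
    JOINT = p1_n + p2_n
  )
}
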