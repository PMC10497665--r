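# Synthetic sessions: agent policies calibrated to the behavioural
# regularities reported for the lab sessions, so that every downstream metric
# can be exercised without the deposited data. The policy layer is a
# stand-in for human subjects, not a fitted behavioural model.

#' Agent policy
#'
#' Behavioural parameters of one synthetic player.
#'
#' @param mean_inquiries Expected inquiries per round; the realised count is
#'   drawn from a Poisson truncated to `[0, N-1]`.
#' @param reply_rate Probability of sending each available non-redundant
#'   informed reply.
#' @param uninformed_reply_rate Probability of sending an available
#'   uninformed reply (only available when no informative option exists).
#' @param redundant_reply_rate Probability of sending an available
#'   self-expert reply whose content the reciprocal inquiry already revealed.
#' @param reciprocity_weight Multiplicative preference (>= 1) for inquiry
#'   targets who contacted this agent in earlier rounds; the sampling weight
#'   of a target is `reciprocity_weight ^ (messages received from them)`,
#'   counting both replies and inquiries. Received inquiries count because
#'   subjects read them as relationship signals, and it is the attention to
#'   them that makes mutual (bi-directional) links form and persist.
#' @param suggestion_adherence While the nudge is displayed, the probability
#'   that each inquiry is aimed at a starred (suggested) partner.
#' @param adherence_after Same probability after the nudge is removed.
#' @param comply_fully If `TRUE`, the agent ignores the count model and sends
#'   exactly one inquiry along every suggested link each round (the full
#'   compliance benchmark).
#'
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(mean_inquiries = 2.65, reply_rate = 0.85,
                         uninformed_reply_rate = 0.03,
                         redundant_reply_rate = 0.75,
                         reciprocity_weight = 2,
                         suggestion_adherence = 0, adherence_after = 0,
                         comply_fully = FALSE) {
  probs <- c(reply_rate, uninformed_reply_rate, redundant_reply_rate,
             suggestion_adherence, adherence_after)
  if (any(probs < 0 | probs > 1))
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (mean_inquiries < 0) stop("mean_inquiries must be >= 0", call. = FALSE)
  if (reciprocity_weight < 1)
    stop("reciprocity_weight must be >= 1", call. = FALSE)
  structure(
    list(mean_inquiries = mean_inquiries, reply_rate = reply_rate,
         uninformed_reply_rate = uninformed_reply_rate,
         redundant_reply_rate = redundant_reply_rate,
         reciprocity_weight = reciprocity_weight,
         suggestion_adherence = suggestion_adherence,
         adherence_after = adherence_after,
         comply_fully = isTRUE(comply_fully)),
    class = "agent_policy"
  )
}

#' Calibrated policy presets
#'
#' `baseline_policy()` targets the regularities of the no-nudge sessions
#' (about 2.65 inquiries/round, reply share 0.85, 3% of possible uninformative
#' replies, 75% of redundant opportunities taken). `nudged_policy()` raises
#' the inquiry volume to about 3.53/round and aims 93.5% of inquiries at
#' starred partners while the nudge shows, dropping to 48.5% after removal.
#' `compliance_policy()` is the idealised benchmark: all six suggested
#' inquiries every round and every informed reply sent.
#'
#' @return An [agent_policy()].
#' @export
baseline_policy <- function() {
  agent_policy(mean_inquiries = 2.65, reply_rate = 0.85,
               uninformed_reply_rate = 0.03, redundant_reply_rate = 0.75,
               reciprocity_weight = 2)
}

#' @rdname baseline_policy
#' @export
nudged_policy <- function() {
  agent_policy(mean_inquiries = 3.53, reply_rate = 0.85,
               uninformed_reply_rate = 0.03, redundant_reply_rate = 0.75,
               reciprocity_weight = 2,
               suggestion_adherence = 0.935, adherence_after = 0.485)
}

#' @rdname baseline_policy
#' @export
compliance_policy <- function() {
  agent_policy(mean_inquiries = 6, reply_rate = 1,
               uninformed_reply_rate = 0, redundant_reply_rate = 1,
               reciprocity_weight = 1,
               suggestion_adherence = 1, adherence_after = 1,
               comply_fully = TRUE)
}

# Truncated Poisson draw on 0..max_k (renormalised mass).
rtrunc_pois <- function(lambda, max_k) {
  if (lambda == 0) return(0L)
  k <- 0:max_k
  sample(k, 1L, prob = stats::dpois(k, lambda))
}

#' Draw one player's stage-1 inquiries
#'
#' The inquiry count is truncated-Poisson; targets are drawn sequentially
#' without replacement. When a suggestion is in force, each inquiry first
#' chooses its pool -- starred partners with the adherence probability,
#' everyone else otherwise (falling back when a pool is exhausted) -- and
#' then picks within the pool with reciprocity weights
#' `reciprocity_weight ^ (messages previously received from that target)`.
#'
#' @param player Player id.
#' @param contacts_received Integer vector: messages (inquiries and replies)
#'   received by `player` from each other player over previous rounds
#'   (length N).
#' @param policy An [agent_policy()].
#' @param suggested Integer vector of the player's suggested partners, or
#'   `NULL` when the session has no suggestion graph.
#' @param adherence Pool probability currently in force (the policy's
#'   `suggestion_adherence` while the stars show, `adherence_after` later).
#'
#' @return Data frame of inquiries (`sender`, `receiver`).
#' @export
choose_inquiries <- function(player, contacts_received, policy,
                             suggested = NULL, adherence = 0) {
  n <- length(contacts_received)
  if (policy$comply_fully) {
    if (is.null(suggested)) stop("comply_fully requires a suggestion graph",
                                 call. = FALSE)
    return(data.frame(sender = player, receiver = sort(suggested)))
  }
  k <- rtrunc_pois(policy$mean_inquiries, n - 1L)
  if (k == 0L) return(empty_inquiries())
  candidates <- setdiff(seq_len(n), player)
  w <- policy$reciprocity_weight^contacts_received[candidates]
  targets <- integer(k)
  use_pools <- !is.null(suggested) && adherence > 0
  for (s in seq_len(k)) {
    pool <- candidates
    if (use_pools) {
      starred <- candidates %in% suggested
      prefer <- stats::runif(1) < adherence
      sel <- if (prefer) starred else !starred
      if (!any(sel)) sel <- !sel   # pool exhausted: fall back
      pool <- candidates[sel]
    }
    wp <- w[match(pool, candidates)]
    pick <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = wp)
    targets[s] <- pick
    keep <- candidates != pick
    candidates <- candidates[keep]
    w <- w[keep]
  }
  data.frame(sender = player, receiver = targets)
}

#' Draw one player's stage-2 replies
#'
#' Each legal informed reply is sent independently with the policy's
#' `reply_rate` (`redundant_reply_rate` when its content is already known to
#' the inquirer through the reciprocal inquiry); each legal uninformed reply
#' with `uninformed_reply_rate`.
#'
#' @param player Player id.
#' @param round A `round_record` with stage 1 closed.
#' @param policy An [agent_policy()].
#'
#' @return Data frame of replies (possibly zero rows).
#' @export
choose_replies <- function(player, round, policy) {
  opts <- legal_replies(player, round)
  if (!nrow(opts)) return(empty_replies())
  redundant <- flag_redundant(opts, round)
  p <- ifelse(opts$kind == "uninformed", policy$uninformed_reply_rate,
              ifelse(redundant, policy$redundant_reply_rate,
                     policy$reply_rate))
  opts[stats::runif(nrow(opts)) < p, , drop = FALSE]
}

#' Session specification
#'
#' @param n_rounds Number of rounds (>= 1).
#' @param nudged If `TRUE`, the suggestion graph is displayed during the
#'   first `suggestion_rounds` rounds.
#' @param suggestion_rounds Rounds with the nudge on screen (default 5).
#' @param policies A single [agent_policy()] applied to every player, or a
#'   list of N policies.
#' @param seed Integer seed; the whole session is reproducible from it.
#' @param config A [game_config()].
#' @param label Optional session label (e.g. `"B1"`).
#'
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_rounds, nudged = FALSE,
                         suggestion_rounds = if (nudged) min(5L, n_rounds) else 0L,
                         policies = baseline_policy(), seed = 1,
                         config = game_config(), label = NULL) {
  if (n_rounds < 1) stop("n_rounds must be >= 1", call. = FALSE)
  if (suggestion_rounds > n_rounds)
    stop("suggestion_rounds cannot exceed n_rounds", call. = FALSE)
  if (inherits(policies, "agent_policy"))
    policies <- rep(list(policies), config$n_players)
  if (length(policies) != config$n_players)
    stop("need one policy, or one per player", call. = FALSE)
  structure(
    list(n_rounds = as.integer(n_rounds), nudged = isTRUE(nudged),
         suggestion_rounds = as.integer(suggestion_rounds),
         policies = policies, seed = as.integer(seed), config = config,
         label = label),
    class = "session_spec"
  )
}

#' Simulate a full session
#'
#' Plays `n_rounds` rounds: a fresh random assignment, stage-1 inquiries from
#' every player's policy, stage-2 replies, and round resolution. Reciprocity
#' state (messages received per ordered pair) carries across rounds. Nudged
#' sessions use the suggestion graph of [build_suggested_network()] (for
#' other player counts no suggestion is available). Identical spec and seed
#' give an identical log.
#'
#' @param spec A [session_spec()].
#'
#' @return An object of class `session_log`: the session header, the suggestion
#'   adjacency (nudged sessions), and one record per round (`assignment`,
#'   `inquiries`, `replies`, `outcome`).
#' @export
#'
#' @examples
#' log <- simulate_session(session_spec(3, seed = 7,
#'   config = game_config(n_players = 5)))
#' length(log$rounds)
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  config <- spec$config
  n <- config$n_players
  set.seed(spec$seed)
  suggestion <- NULL
  if (spec$nudged) {
    if (n != 25L)
      stop("the suggestion graph is defined for 25 players", call. = FALSE)
    suggestion <- build_suggested_network()
  }
  sugg_nbrs <- if (!is.null(suggestion))
    apply(suggestion$adjacency > 0, 1, which, simplify = FALSE)
  contacts_received <- matrix(0L, n, n)  # [player, sender], inquiries + replies
  rounds <- vector("list", spec$n_rounds)
  for (t in seq_len(spec$n_rounds)) {
    assignment <- draw_assignment(n)
    active <- spec$nudged && t <= spec$suggestion_rounds
    inquiries <- do.call(rbind, lapply(seq_len(n), function(i) {
      pol <- spec$policies[[i]]
      adh <- if (!spec$nudged) 0 else
        if (active) pol$suggestion_adherence else pol$adherence_after
      choose_inquiries(i, contacts_received[i, ], pol,
                       suggested = if (!is.null(suggestion)) sugg_nbrs[[i]],
                       adherence = adh)
    }))
    rr <- round_record(t, assignment, inquiries)
    replies <- do.call(rbind, lapply(seq_len(n), function(i)
      choose_replies(i, rr, spec$policies[[i]])))
    if (is.null(replies)) replies <- empty_replies()
    rr <- round_record(t, assignment, inquiries, replies)
    outcome <- resolve_round(rr, config)
    for (msgs in list(rr$inquiries, rr$replies))
      if (nrow(msgs))
        for (j in seq_len(nrow(msgs)))
          contacts_received[msgs$receiver[j], msgs$sender[j]] <-
            contacts_received[msgs$receiver[j], msgs$sender[j]] + 1L
    rounds[[t]] <- list(round_index = t, assignment = assignment,
                        inquiries = rr$inquiries, replies = rr$replies,
                        outcome = outcome)
  }
  structure(
    list(config = config, label = spec$label, nudged = spec$nudged,
         suggestion_rounds = spec$suggestion_rounds, seed = spec$seed,
         n_rounds = spec$n_rounds,
         suggested_network = if (!is.null(suggestion)) suggestion$adjacency,
         rounds = rounds),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s%d players, %d rounds%s\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$config$n_players, x$n_rounds,
              if (x$nudged) sprintf(", nudged (rounds 1-%d)",
                                    x$suggestion_rounds) else ""))
  invisible(x)
}

#' Regenerate the shipped deterministic fixture sessions
#'
#' Two small reference logs used by the metric tests: a 5-player, 3-round
#' baseline-style session and a 25-player, 6-round nudged session. Both are
#' fully determined by their fixed seeds, so the shipped files can always be
#' re-derived.
#'
#' @param dir Directory to write `fixture_small.json` and
#'   `fixture_nudged.json` into.
#'
#' @return Invisibly, the two file paths.
#' @export
make_fixtures <- function(dir = tempdir()) {
  small <- simulate_session(session_spec(
    3, policies = agent_policy(mean_inquiries = 2, reciprocity_weight = 2),
    seed = 101, config = game_config(n_players = 5), label = "F5"))
  nudged <- simulate_session(session_spec(
    6, nudged = TRUE, policies = nudged_policy(), seed = 202,
    label = "FN25"))
  paths <- file.path(dir, c("fixture_small.json", "fixture_nudged.json"))
  write_session(small, paths[1], format = "json")
  write_session(nudged, paths[2], format = "json")
  invisible(paths)
}
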