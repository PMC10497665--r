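# Core mechanics of one round of the question/expert game.
#
# Each round every player holds a unique question and a unique expertise
# (letters), arranged so that the "expert-of" relation is a single N-cycle.
# Stage 1: costly inquiries reveal the sender's question and expertise to one
# receiver. Stage 2: costly replies answer inquiries; no false content is
# possible, so a reply is either uninformed ("I don't know an expert in X"),
# self-expert ("I am the expert"), or a referral naming a third player whose
# own inquiry revealed the matching expertise. A player is rewarded when some
# message identifies their expert.

#' Game configuration
#'
#' Costs, reward and player count for the question/expert game. The endowment
#' is the show-up stock of currency and never enters reported profit.
#'
#' @param n_players Number of players (at least 3).
#' @param inquiry_cost Cost in ECU of sending one inquiry.
#' @param reply_cost Cost in ECU of sending one reply.
#' @param reward Reward in ECU for learning one's expert in a round.
#' @param endowment Initial endowment in ECU (bookkeeping only).
#'
#' @return An object of class `game_config`.
#' @export
#'
#' @examples
#' game_config()
game_config <- function(n_players = 25, inquiry_cost = 1, reply_cost = 1,
                        reward = 10, endowment = 100) {
  if (!is.numeric(n_players) || length(n_players) != 1L || n_players < 3)
    stop("n_players must be a single integer >= 3 (a 2-player game would ",
         "force each player to be the other's expert)", call. = FALSE)
  n_players <- as.integer(n_players)
  if (inquiry_cost < 0 || reply_cost < 0) stop("costs must be >= 0", call. = FALSE)
  if (reward <= 0) stop("reward must be > 0", call. = FALSE)
  structure(
    list(n_players = n_players, inquiry_cost = inquiry_cost,
         reply_cost = reply_cost, reward = reward, endowment = endowment),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat(sprintf(
    "<game_config> %d players | inquiry %g ECU, reply %g ECU, reward %g ECU\n",
    x$n_players, x$inquiry_cost, x$reply_cost, x$reward))
  invisible(x)
}

# Letter labels used for questions/expertise: A..Z for N <= 26, "L<k>" above.
letter_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else paste0("L", seq_len(n))
}

#' Draw a round's question/expertise assignment
#'
#' Draws a uniform random permutation `p` of the players and a uniform random
#' permutation `q` of the first N letters, then gives player `p[i]` question
#' `q[i]` and expertise `q[i+1 mod N]`. Every question matches exactly one
#' other player's expertise, and the induced expert-of relation is a single
#' N-cycle with no fixed point: the expert of `p[i]` is `p[i-1]`.
#'
#' @param n_players Number of players (>= 3).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#'
#' @return An object of class `expertise_assignment` with elements
#'   `player_order`, `letter_order`, `question`, `expertise` (integer letter
#'   indices per player) and `expert_of` (player index per player).
#' @export
#'
#' @examples
#' a <- draw_assignment(25, seed = 1)
#' all(a$expertise[a$expert_of] == a$question)
draw_assignment <- function(n_players = 25, seed = NULL) {
  if (n_players < 3) stop("n_players must be >= 3", call. = FALSE)
  n <- as.integer(n_players)
  if (!is.null(seed)) set.seed(seed)
  p <- sample.int(n)
  q <- sample.int(n)
  question <- expertise <- integer(n)
  question[p] <- q
  expertise[p] <- q[c(2:n, 1L)]
  # expert_of[x]: the player whose expertise equals x's question
  expert_of <- match(question, expertise)
  structure(
    list(n_players = n, player_order = p, letter_order = q,
         question = question, expertise = expertise, expert_of = expert_of),
    class = "expertise_assignment"
  )
}

#' @export
print.expertise_assignment <- function(x, ...) {
  lab <- letter_labels(x$n_players)
  cat(sprintf("<expertise_assignment> %d players, expert-of is a %d-cycle\n",
              x$n_players, x$n_players))
  cat(" question: ", paste(lab[x$question], collapse = ""), "\n", sep = "")
  cat(" expertise:", paste(lab[x$expertise], collapse = ""), "\n", sep = "")
  invisible(x)
}

empty_inquiries <- function() {
  data.frame(sender = integer(), receiver = integer())
}

empty_replies <- function() {
  data.frame(sender = integer(), receiver = integer(),
             kind = character(), named_player = integer())
}

#' Assemble and validate one round record
#'
#' @param round_index Positive integer round number.
#' @param assignment An `expertise_assignment` for the round.
#' @param inquiries Data frame with columns `sender`, `receiver` (stage 1).
#'   At most one inquiry per ordered pair; no self-inquiries.
#' @param replies Data frame with columns `sender`, `receiver`, `kind`
#'   (`"uninformed"`, `"self_expert"` or `"referral"`) and `named_player`
#'   (player id for referrals, `NA` otherwise). Each reply must answer a
#'   same-round inquiry from its receiver to its sender.
#'
#' @return An object of class `round_record`.
#' @export
round_record <- function(round_index, assignment, inquiries = empty_inquiries(),
                         replies = empty_replies()) {
  stopifnot(inherits(assignment, "expertise_assignment"))
  if (round_index < 1) stop("round_index must be >= 1", call. = FALSE)
  n <- assignment$n_players
  inquiries <- as.data.frame(inquiries)[, c("sender", "receiver")]
  if (nrow(inquiries)) {
    if (any(inquiries$sender == inquiries$receiver))
      stop("self-inquiry is not allowed", call. = FALSE)
    if (any(inquiries$sender < 1 | inquiries$sender > n |
            inquiries$receiver < 1 | inquiries$receiver > n))
      stop("inquiry endpoints out of range", call. = FALSE)
    if (anyDuplicated(inquiries[, c("sender", "receiver")]))
      stop("duplicate inquiry for an ordered pair within one round", call. = FALSE)
  }
  replies <- as.data.frame(replies)
  if (nrow(replies)) {
    replies <- replies[, c("sender", "receiver", "kind", "named_player")]
    bad <- !replies$kind %in% c("uninformed", "self_expert", "referral")
    if (any(bad)) stop("unknown reply kind: ", replies$kind[which(bad)[1]],
                       call. = FALSE)
    has_inq <- paste(replies$receiver, replies$sender) %in%
      paste(inquiries$sender, inquiries$receiver)
    if (!all(has_inq))
      stop("reply without a matching same-round inquiry (reply #",
           which(!has_inq)[1], ")", call. = FALSE)
    if (anyDuplicated(replies[, c("sender", "receiver")]))
      stop("duplicate reply for an ordered pair within one round", call. = FALSE)
  } else {
    replies <- empty_replies()
  }
  structure(
    list(round_index = as.integer(round_index), assignment = assignment,
         inquiries = inquiries, replies = replies),
    class = "round_record"
  )
}

#' Enumerate the legal reply options of one player
#'
#' For each inquiry received by `responder`, lists the reply the rules allow:
#' `self_expert` when the responder's own expertise answers the inquirer's
#' question; `referral` naming the third player whose same-round inquiry to the
#' responder revealed the matching expertise; and `uninformed` only when no
#' informative option exists (players cannot send false information, and the
#' "I don't know" message is only truthful in that case).
#'
#' @param responder Player id.
#' @param round A `round_record` with stage 1 closed.
#'
#' @return Data frame of reply options with columns `sender`, `receiver`,
#'   `kind`, `named_player` (zero rows if the responder received no inquiries).
#' @export
legal_replies <- function(responder, round) {
  stopifnot(inherits(round, "round_record"))
  a <- round$assignment
  inq <- round$inquiries
  inquirers <- inq$sender[inq$receiver == responder]
  if (!length(inquirers)) return(empty_replies())
  out <- vector("list", length(inquirers))
  for (k in seq_along(inquirers)) {
    x <- inquirers[k]
    if (a$expertise[responder] == a$question[x]) {
      out[[k]] <- data.frame(sender = responder, receiver = x,
                             kind = "self_expert", named_player = NA_integer_)
    } else {
      y <- inquirers[inquirers != x & a$expertise[inquirers] == a$question[x]]
      if (length(y)) {
        out[[k]] <- data.frame(sender = responder, receiver = x,
                               kind = "referral", named_player = y[1])
      } else {
        out[[k]] <- data.frame(sender = responder, receiver = x,
                               kind = "uninformed", named_player = NA_integer_)
      }
    }
  }
  do.call(rbind, out)
}

#' Messages that identify a player's expert
#'
#' Scans a completed round for every message whose content tells `player` who
#' their expert is: the expert's own stage-1 inquiry (it reveals the expert's
#' expertise), a self-expert reply from the expert, or a referral naming the
#' expert.
#'
#' @param player Player id.
#' @param round A completed `round_record`.
#'
#' @return Data frame with columns `type` and `sender`, one row per informing
#'   message (zero rows when the player is not informed).
#' @export
informing_messages <- function(player, round) {
  stopifnot(inherits(round, "round_record"))
  expert <- round$assignment$expert_of[player]
  inq <- round$inquiries
  rep <- round$replies
  out <- list()
  if (any(inq$sender == expert & inq$receiver == player))
    out[[length(out) + 1L]] <- data.frame(type = "inquiry", sender = expert)
  if (nrow(rep)) {
    se <- rep$receiver == player & rep$kind == "self_expert" & rep$sender == expert
    if (any(se))
      out[[length(out) + 1L]] <- data.frame(type = "reply_self_expert",
                                            sender = expert)
    rf <- rep$receiver == player & rep$kind == "referral" &
      !is.na(rep$named_player) & rep$named_player == expert
    if (any(rf))
      out[[length(out) + 1L]] <- data.frame(type = "reply_referral",
                                            sender = rep$sender[rf])
  }
  if (!length(out)) return(data.frame(type = character(), sender = integer()))
  do.call(rbind, out)
}

#' Is a self-expert reply redundant?
#'
#' A self-expert reply is redundant when the responder also inquired the
#' inquirer in stage 1 of the same round: that inquiry already revealed the
#' responder's expertise, so the inquirer learns nothing new from the reply.
#'
#' @param reply A one-row data frame or list with `sender`, `receiver`, `kind`.
#' @param round The `round_record` the reply belongs to.
#'
#' @return `TRUE` or `FALSE`. Referral and uninformed replies are never
#'   flagged.
#' @export
is_redundant <- function(reply, round) {
  stopifnot(inherits(round, "round_record"))
  if (reply$kind != "self_expert") return(FALSE)
  any(round$inquiries$sender == reply$sender &
        round$inquiries$receiver == reply$receiver)
}

# Vectorised redundancy flag over a reply table.
flag_redundant <- function(replies, round) {
  if (!nrow(replies)) return(logical(0))
  key <- paste(round$inquiries$sender, round$inquiries$receiver)
  replies$kind == "self_expert" &
    paste(replies$sender, replies$receiver) %in% key
}

#' Resolve a round: rewards, costs and reward attribution
#'
#' Checks every reply against [legal_replies()], determines which players were
#' informed of their expert, and settles the round ledger:
#' `profit_delta(i) = reward * informed(i) - inquiry_cost * inquiries sent -
#' reply_cost * replies sent`. The informed player always receives the full
#' reward; when several distinct senders informed the same player in one
#' round, the reward is additionally *attributed* to those senders in equal
#' fractions, as link-level bookkeeping for return-on-investment metrics.
#'
#' @param round A `round_record`.
#' @param config A `game_config`.
#' @param strict If `TRUE` (default) an illegal reply aborts with an error
#'   naming the offending message; if `FALSE` violations are collected into
#'   the `violations` element instead (for tolerant ingestion of lab data).
#'
#' @return An object of class `round_outcome`: logical vector `informed`,
#'   numeric vector `profit_delta`, data frame `attribution` with columns
#'   `sender`, `informed_player`, `n_senders`, `share` (ECU), and per-player
#'   message counts.
#' @export
resolve_round <- function(round, config = game_config(), strict = TRUE) {
  stopifnot(inherits(round, "round_record"), inherits(config, "game_config"))
  n <- round$assignment$n_players
  if (n != config$n_players)
    stop("assignment and config disagree on the number of players", call. = FALSE)
  rep <- round$replies
  violations <- character(0)
  if (nrow(rep)) {
    legal <- do.call(rbind, lapply(seq_len(n), legal_replies, round = round))
    legal_key <- paste(legal$sender, legal$receiver, legal$kind,
                       ifelse(is.na(legal$named_player), 0L, legal$named_player))
    rep_key <- paste(rep$sender, rep$receiver, rep$kind,
                     ifelse(is.na(rep$named_player), 0L, rep$named_player))
    bad <- !(rep_key %in% legal_key)
    if (any(bad)) {
      msg <- sprintf("illegal reply: %d -> %d (%s)",
                     rep$sender[bad], rep$receiver[bad], rep$kind[bad])
      if (strict) stop(msg[1], call. = FALSE)
      violations <- msg
    }
  }
  informed <- logical(n)
  attribution <- list()
  for (i in seq_len(n)) {
    msgs <- informing_messages(i, round)
    if (nrow(msgs)) {
      informed[i] <- TRUE
      senders <- unique(msgs$sender)
      attribution[[length(attribution) + 1L]] <- data.frame(
        sender = senders, informed_player = i,
        n_senders = length(senders),
        share = config$reward / length(senders))
    }
  }
  attribution <- if (length(attribution)) do.call(rbind, attribution) else
    data.frame(sender = integer(), informed_player = integer(),
               n_senders = integer(), share = numeric())
  inq_sent <- tabulate(round$inquiries$sender, nbins = n)
  rep_sent <- tabulate(rep$sender, nbins = n)
  profit_delta <- config$reward * as.numeric(informed) -
    config$inquiry_cost * inq_sent - config$reply_cost * rep_sent
  structure(
    list(informed = informed, profit_delta = profit_delta,
         attribution = attribution, inquiries_sent = inq_sent,
         replies_sent = rep_sent,
         inquiries_received = tabulate(round$inquiries$receiver, nbins = n),
         replies_received = tabulate(rep$receiver, nbins = n),
         violations = violations),
    class = "round_outcome"
  )
}
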