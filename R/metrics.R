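# Session-level behavioural metrics: profit summaries, reply share, RRI
# (reward attributed along a set of links per message sent on them), the
# suggested x bi-directional inquiry decomposition, the reciprocity null
# model, and rank-based session comparisons.

default_window <- function(log, round_window = NULL) {
  if (is.null(round_window))
    round_window <- seq_len(min(51L, log$n_rounds))
  round_window <- as.integer(round_window)
  if (!length(round_window) || any(round_window < 1 | round_window > log$n_rounds))
    stop("round window outside the session", call. = FALSE)
  round_window
}

#' Summarise a session
#'
#' Per-round mean inquiries and mean profit, the cumulative mean-profit
#' trajectory, per-player totals, and the share of players ending the window
#' with positive profit. The default window is rounds 1-51 so that sessions
#' of different lengths are compared over a common span.
#'
#' @param log A `session_log`.
#' @param round_window Integer vector of rounds (default `1:min(51, n)`).
#'
#' @return List with `per_round` (data frame `round`, `mean_inquiries`,
#'   `mean_profit`, `cum_mean_profit`), `per_player` (totals), and
#'   `share_positive_profit`.
#' @export
session_summary <- function(log, round_window = NULL) {
  w <- default_window(log, round_window)
  n <- log$config$n_players
  profit <- matrix(0, length(w), n)
  inq <- rep_s <- inq_r <- rep_r <- matrix(0L, length(w), n)
  for (k in seq_along(w)) {
    o <- log$rounds[[w[k]]]$outcome
    profit[k, ] <- o$profit_delta
    inq[k, ] <- o$inquiries_sent
    rep_s[k, ] <- o$replies_sent
    inq_r[k, ] <- o$inquiries_received
    rep_r[k, ] <- o$replies_received
  }
  per_round <- data.frame(
    round = w,
    mean_inquiries = rowMeans(inq),
    mean_profit = rowMeans(profit),
    cum_mean_profit = cumsum(rowMeans(profit)))
  per_player <- data.frame(
    player = seq_len(n),
    profit = colSums(profit),
    inquiries_sent = colSums(inq), inquiries_received = colSums(inq_r),
    replies_sent = colSums(rep_s), replies_received = colSums(rep_r),
    messages_sent = colSums(inq) + colSums(rep_s),
    messages_received = colSums(inq_r) + colSums(rep_r))
  list(per_round = per_round, per_player = per_player,
       share_positive_profit = mean(per_player$profit > 0),
       window = w)
}

# Informed-reply opportunities and realisations per round.
reply_opportunities <- function(round) {
  n <- round$assignment$n_players
  opts <- do.call(rbind, lapply(seq_len(n), legal_replies, round = round))
  if (is.null(opts) || !nrow(opts))
    return(list(available = empty_replies(), redundant = logical(0)))
  informative <- opts[opts$kind != "uninformed", , drop = FALSE]
  list(available = informative,
       redundant = flag_redundant(informative, round))
}

#' Share of informed replies sent
#'
#' Informed replies sent divided by informed replies that could have been
#' sent, pooled over players and rounds in the window.
#'
#' @inheritParams session_summary
#' @param include_redundant Count redundant self-expert opportunities and
#'   replies (default `TRUE`, matching pooled session reporting). Set to
#'   `FALSE` to score only non-redundant opportunities.
#'
#' @return List with `share`, `sent`, `available`.
#' @export
reply_share <- function(log, round_window = NULL, include_redundant = TRUE) {
  w <- default_window(log, round_window)
  sent <- avail <- 0L
  for (t in w) {
    rd <- log$rounds[[t]]
    rr <- round_record(rd$round_index, rd$assignment, rd$inquiries, rd$replies)
    opp <- reply_opportunities(rr)
    keep <- if (include_redundant) rep(TRUE, nrow(opp$available)) else
      !opp$redundant
    avail <- avail + sum(keep)
    rep_inf <- rd$replies[rd$replies$kind != "uninformed", , drop = FALSE]
    if (!include_redundant && nrow(rep_inf))
      rep_inf <- rep_inf[!flag_redundant(rep_inf, rr), , drop = FALSE]
    sent <- sent + nrow(rep_inf)
  }
  if (avail == 0L)
    stop("no informed-reply opportunity in the window", call. = FALSE)
  list(share = sent / avail, sent = sent, available = avail)
}

#' Share of possible uninformative replies sent
#'
#' @inheritParams session_summary
#' @return List with `share`, `sent`, `available` (zero opportunities give
#'   share `NA`).
#' @export
uninformed_share <- function(log, round_window = NULL) {
  w <- default_window(log, round_window)
  sent <- avail <- 0L
  for (t in w) {
    rd <- log$rounds[[t]]
    rr <- round_record(rd$round_index, rd$assignment, rd$inquiries, rd$replies)
    n <- rr$assignment$n_players
    opts <- do.call(rbind, lapply(seq_len(n), legal_replies, round = rr))
    if (!is.null(opts) && nrow(opts))
      avail <- avail + sum(opts$kind == "uninformed")
    sent <- sent + sum(rd$replies$kind == "uninformed")
  }
  list(share = if (avail > 0) sent / avail else NA_real_,
       sent = sent, available = avail)
}

#' Share of redundant self-expert opportunities taken
#'
#' @inheritParams session_summary
#' @return List with `share`, `sent`, `available`.
#' @export
redundant_share <- function(log, round_window = NULL) {
  w <- default_window(log, round_window)
  sent <- avail <- 0L
  for (t in w) {
    rd <- log$rounds[[t]]
    rr <- round_record(rd$round_index, rd$assignment, rd$inquiries, rd$replies)
    opp <- reply_opportunities(rr)
    avail <- avail + sum(opp$redundant)
    if (nrow(rd$replies))
      sent <- sent + sum(flag_redundant(rd$replies, rr))
  }
  list(share = if (avail > 0) sent / avail else NA_real_,
       sent = sent, available = avail)
}

link_in_filter <- function(a, b, adj, link_filter) {
  switch(link_filter,
         all = rep(TRUE, length(a)),
         suggested = adj[cbind(a, b)] > 0,
         other = adj[cbind(a, b)] == 0,
         stop("unknown link filter", call. = FALSE))
}

#' Relative return on investment along a set of links
#'
#' Sums the equal-split reward attribution flowing along the filtered links
#' and divides by the number of inquiries (or all messages: inquiries plus
#' replies) sent along them, over the window. Message costs do not enter; the
#' RRI is reward per message, not net profit.
#'
#' @inheritParams session_summary
#' @param net A `suggested_network` or symmetric adjacency matrix defining
#'   which links count as "suggested" (required unless `link_filter = "all"`).
#' @param link_filter `"suggested"`, `"other"` or `"all"`.
#' @param denominator `"inquiries"` or `"messages"`.
#' @param count_redundant Count redundant replies in a `"messages"`
#'   denominator (default `TRUE`).
#'
#' @return List with `rri`, `reward_attributed`, `n_messages`.
#' @export
rri <- function(log, net = NULL, link_filter = c("suggested", "other", "all"),
                denominator = c("inquiries", "messages"),
                round_window = NULL, count_redundant = TRUE) {
  link_filter <- match.arg(link_filter)
  denominator <- match.arg(denominator)
  w <- default_window(log, round_window)
  if (link_filter != "all" && is.null(net))
    stop("a suggestion network is needed for this link filter", call. = FALSE)
  adj <- if (!is.null(net)) as_adjacency(net)
  reward_sum <- 0
  n_msg <- 0L
  for (t in w) {
    rd <- log$rounds[[t]]
    att <- rd$outcome$attribution
    if (nrow(att)) {
      keep <- link_in_filter(att$sender, att$informed_player, adj, link_filter)
      reward_sum <- reward_sum + sum(att$share[keep])
    }
    inq <- rd$inquiries
    if (nrow(inq))
      n_msg <- n_msg + sum(link_in_filter(inq$sender, inq$receiver, adj,
                                          link_filter))
    if (denominator == "messages" && nrow(rd$replies)) {
      reps <- rd$replies
      if (!count_redundant) {
        rr <- round_record(rd$round_index, rd$assignment, inq, reps)
        reps <- reps[!flag_redundant(reps, rr), , drop = FALSE]
      }
      if (nrow(reps))
        n_msg <- n_msg + sum(link_in_filter(reps$sender, reps$receiver, adj,
                                            link_filter))
    }
  }
  if (n_msg == 0L)
    stop("no messages on the filtered links in the window", call. = FALSE)
  list(rri = reward_sum / n_msg, reward_attributed = reward_sum,
       n_messages = n_msg)
}

#' Decompose inquiries by suggested and bi-directional status
#'
#' Classifies every inquiry of every round into four classes: on a suggested
#' link or not, and bi-directional (the reverse inquiry occurs in the same
#' round) or not. For baseline sessions the same reference graph provides the
#' counterfactual "suggested" split.
#'
#' @param log A `session_log`.
#' @param net A `suggested_network` or symmetric adjacency matrix.
#'
#' @return Data frame of class `link_decomposition`, one row per round:
#'   `round`, `suggested_bi`, `suggested_uni`, `other_bi`, `other_uni`,
#'   `total`.
#' @export
link_decomposition <- function(log, net = build_suggested_network()) {
  adj <- as_adjacency(net)
  out <- lapply(log$rounds, function(rd) {
    inq <- rd$inquiries
    if (!nrow(inq))
      return(data.frame(round = rd$round_index, suggested_bi = 0L,
                        suggested_uni = 0L, other_bi = 0L, other_uni = 0L,
                        total = 0L))
    sugg <- adj[cbind(inq$sender, inq$receiver)] > 0
    bi <- paste(inq$receiver, inq$sender) %in% paste(inq$sender, inq$receiver)
    data.frame(round = rd$round_index,
               suggested_bi = sum(sugg & bi), suggested_uni = sum(sugg & !bi),
               other_bi = sum(!sugg & bi), other_uni = sum(!sugg & !bi),
               total = nrow(inq))
  })
  out <- do.call(rbind, out)
  class(out) <- c("link_decomposition", "data.frame")
  out
}

#' Bi-directional inquiry pairs observed per round
#'
#' @param log A `session_log`.
#' @return Data frame `round`, `bidirectional_pairs`, `total_inquiries`.
#' @export
observed_bidirectional <- function(log) {
  do.call(rbind, lapply(log$rounds, function(rd) {
    inq <- rd$inquiries
    bi <- if (nrow(inq))
      sum(paste(inq$receiver, inq$sender) %in%
            paste(inq$sender, inq$receiver)) / 2 else 0
    data.frame(round = rd$round_index, bidirectional_pairs = bi,
               total_inquiries = nrow(inq))
  }))
}

#' Expected bi-directional pairs under random targeting
#'
#' Null model for reciprocity: each player a sends their observed number of
#' inquiries `k_a` to targets drawn uniformly without replacement among the
#' other N-1 players, independently across players. The expected number of
#' mutual pairs is `sum_{a<b} k_a k_b / (N-1)^2`. Optionally also returns a
#' Monte Carlo sample of the null distribution.
#'
#' @param out_degrees Integer vector of per-player inquiry counts.
#' @param n_players Number of players.
#' @param n_mc Monte Carlo draws of the null (0 for none).
#' @param seed Optional integer seed for the Monte Carlo part.
#'
#' @return List with `expected` and `mc` (numeric vector or `NULL`).
#' @export
bidirectional_null <- function(out_degrees, n_players, n_mc = 0, seed = NULL) {
  k <- as.numeric(out_degrees)
  if (length(k) != n_players)
    stop("need one out-degree per player", call. = FALSE)
  if (any(k < 0 | k > n_players - 1))
    stop("out-degrees must lie in [0, N-1]", call. = FALSE)
  expected <- (sum(k)^2 - sum(k^2)) / (2 * (n_players - 1)^2)
  mc <- NULL
  if (n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    mc <- vapply(seq_len(n_mc), function(d) {
      adj <- matrix(0L, n_players, n_players)
      for (a in seq_len(n_players))
        if (k[a] > 0)
          adj[a, sample(setdiff(seq_len(n_players), a), k[a])] <- 1L
      sum(adj * t(adj)) / 2
    }, numeric(1))
  }
  list(expected = expected, mc = mc)
}

session_statistic <- function(log, statistic, round_window = NULL) {
  switch(statistic,
         inquiries_round1 = log$rounds[[1]]$outcome$inquiries_sent,
         inquiries_per_round = {
           w <- default_window(log, round_window)
           vapply(w, function(t)
             mean(log$rounds[[t]]$outcome$inquiries_sent), numeric(1))
         },
         stop("unknown statistic", call. = FALSE))
}

#' Compare sessions with rank-sum tests
#'
#' Two-sided Wilcoxon rank-sum tests on a per-session statistic, pairwise
#' across sessions (or across pooled groups), with optional Bonferroni
#' correction. `inquiries_round1` uses per-player round-1 inquiry counts;
#' `inquiries_per_round` uses the per-round mean inquiry counts over the
#' window.
#'
#' @param logs Named list of `session_log`s (>= 2 sessions).
#' @param statistic `"inquiries_round1"` or `"inquiries_per_round"`.
#' @param test Only `"ranksum"` is implemented.
#' @param correction `"bonferroni"` or `"none"`.
#' @param groups Optional named character vector mapping session names to
#'   group labels; observations are pooled by group before testing.
#' @param round_window Window for `inquiries_per_round`.
#'
#' @return Data frame: `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`, `n1`, `n2`.
#' @export
compare_sessions <- function(logs,
                             statistic = c("inquiries_round1",
                                           "inquiries_per_round"),
                             test = "ranksum",
                             correction = c("bonferroni", "none"),
                             groups = NULL, round_window = NULL) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  if (test != "ranksum") stop("only the rank-sum test is implemented",
                              call. = FALSE)
  if (length(logs) < 2) stop("need at least two sessions", call. = FALSE)
  if (is.null(names(logs)))
    names(logs) <- paste0("S", seq_along(logs))
  values <- lapply(logs, session_statistic, statistic = statistic,
                   round_window = round_window)
  if (!is.null(groups)) {
    glab <- groups[names(values)]
    values <- lapply(split(values, glab), function(v) unlist(v, use.names = FALSE))
  }
  nm <- names(values)
  pairs <- utils::combn(nm, 2)
  out <- apply(pairs, 2, function(pr) {
    x <- values[[pr[1]]]; y <- values[[pr[2]]]
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               n1 = length(x), n2 = length(y))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- if (correction == "bonferroni")
    stats::p.adjust(out$p_value, "bonferroni") else out$p_value
  out
}

#' Pearson correlations between messages sent and received
#'
#' Per-player session totals: correlation of inquiries sent with inquiries
#' received, and of all messages sent with all messages received.
#'
#' @inheritParams session_summary
#' @return List with `inquiries` and `messages` correlation coefficients.
#' @export
message_correlations <- function(log, round_window = NULL) {
  pp <- session_summary(log, round_window)$per_player
  list(inquiries = stats::cor(pp$inquiries_sent, pp$inquiries_received),
       messages = stats::cor(pp$messages_sent, pp$messages_received))
}
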