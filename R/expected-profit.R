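# Expected-profit model on a fixed directed inquiry network.
#
# The behavioural model has a single parameter, the reply rate r: every
# *informed* reply a player could send is sent independently with probability
# r (uninformed replies are never sent). The question/expertise assignment is
# a uniform random cyclic permutation, whose pair marginal is
# P(expert(x) = y) = 1/(N-1) for every y != x. Because every quantity below
# involves only one (x, expert(x)) pair at a time, all expectations reduce to
# that marginal and the model is exact, not a simulation.
#
# For a directed 0/1 adjacency A (A[i,j] = 1 iff i inquires j):
#   P(i informed | expert = j) =
#     1 - (1 - A[j,i]) (1 - r A[i,j]) prod_{m != i,j} (1 - r A[i,m] A[j,m])
#   (the expert's own inquiry always informs; the expert's self-expert reply
#    and each third-party referral succeed independently with probability r)
#   E[replies by m] = r/(N-1) * sum_{x: A[x,m]=1} (indeg(m) - excl * A[m,x])
#   (for each received inquiry, m holds an informative option iff m is the
#    expert, probability 1/(N-1), or the expert is one of m's other
#    inquirers, probability (indeg(m)-1)/(N-1); with the exclude-redundant
#    variant the self-expert reply is dropped when the reciprocal inquiry
#    already revealed it)
# Group profit = sum_i [ reward * P(i informed) - inquiry_cost * outdeg(i)
#                        - reply_cost * E[replies by i] ].

#' Reply-rate model
#'
#' @param reply_rate Probability in `[0, 1]` that each available informed
#'   reply is sent.
#' @param exclude_redundant If `TRUE`, self-expert replies are not sent when
#'   the reciprocal inquiry already revealed the responder's expertise
#'   (saving their cost; informedness is unchanged because the inquiry itself
#'   informs).
#'
#' @return An object of class `reply_model`.
#' @export
reply_model <- function(reply_rate = 1, exclude_redundant = FALSE) {
  if (reply_rate < 0 || reply_rate > 1)
    stop("reply_rate must be in [0, 1]", call. = FALSE)
  structure(list(reply_rate = reply_rate,
                 exclude_redundant = isTRUE(exclude_redundant)),
            class = "reply_model")
}

check_inquiry_network <- function(adj) {
  adj <- as_adjacency(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square", call. = FALSE)
  if (any(diag(adj) != 0)) stop("self-loop in inquiry network", call. = FALSE)
  storage.mode(adj) <- "double"
  adj
}

# Network-dependent precomputations shared across reply rates.
profit_components <- function(adj) {
  adj <- check_inquiry_network(adj)
  list(A = adj, tA = t(adj),
       common = adj %*% t(adj),       # common[i,j] = # m with i->m and j->m
       indeg = colSums(adj), outdeg = rowSums(adj),
       recip_in = colSums(adj * t(adj)),  # of m's inquirers, how many m inquired back
       n = nrow(adj))
}

profit_from_components <- function(comp, model, config) {
  n <- comp$n
  r <- model$reply_rate
  excl <- as.numeric(model$exclude_redundant)
  M <- (1 - comp$tA) * (1 - r * comp$A) * (1 - r)^comp$common
  diag(M) <- 0
  p_informed <- 1 - rowSums(M) / (n - 1)
  e_replies <- r / (n - 1) * (comp$indeg^2 - excl * comp$recip_in)
  group <- config$reward * sum(p_informed) -
    config$inquiry_cost * sum(comp$outdeg) -
    config$reply_cost * sum(e_replies)
  list(group = group, per_player = group / n,
       p_informed = p_informed, expected_replies = e_replies)
}

#' Exact expected profit on a fixed inquiry network
#'
#' Expected single-round profit under a uniform random cyclic
#' question/expertise assignment and independent Bernoulli informed replies
#' at the model's reply rate. The computation is exact (closed form over the
#' assignment's pair marginal), O(N^3).
#'
#' @param inquiry_network Directed 0/1 adjacency matrix (`A[i, j] = 1` iff
#'   player i sends an inquiry to j); no self-loops.
#' @param model A [reply_model()].
#' @param config A [game_config()].
#'
#' @return List with `group` (expected group profit in ECU), `per_player`
#'   (`group / N`), `p_informed` (per-player probability of learning the
#'   expert) and `expected_replies` (per-player expected replies sent).
#' @export
#'
#' @examples
#' net <- build_suggested_network()
#' expected_profit_fixed_network(net$adjacency, reply_model(1))$per_player
expected_profit_fixed_network <- function(inquiry_network, model = reply_model(),
                                          config = game_config()) {
  comp <- profit_components(inquiry_network)
  if (comp$n != config$n_players)
    stop("network size and config n_players disagree", call. = FALSE)
  profit_from_components(comp, model, config)
}

#' Sample a uniform random inquiry network
#'
#' Draws a directed graph with exactly `n_edges` distinct directed edges,
#' uniform over the `N(N-1)` ordered pairs; the random-network model behind
#' [ensemble_curve()]. Uses the current RNG stream.
#'
#' @param n_players Number of players.
#' @param n_edges Total number of directed inquiries.
#' @return A 0/1 adjacency matrix.
#' @export
sample_inquiry_network <- function(n_players, n_edges) {
  n <- n_players
  if (n_edges > n * (n - 1)) stop("too many edges requested", call. = FALSE)
  m <- matrix(0, n, n)
  off <- which(row(m) != col(m))
  adj <- m
  if (n_edges > 0) adj[sample(off, n_edges)] <- 1
  adj
}

# Ensemble mean/sd of expected group profit on a grid of total inquiry
# volumes, evaluated at several reply rates over the *same* sampled networks.
ensemble_profit_grid <- function(T_grid, r_values, n_networks, seed = NULL,
                                 config = game_config(),
                                 exclude_redundant = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_players
  if (max(T_grid) > n * (n - 1))
    stop("inquiry volume exceeds the ", n * (n - 1),
         " ordered pairs", call. = FALSE)
  if (n_networks < 1) stop("n_networks must be >= 1", call. = FALSE)
  models <- lapply(r_values, reply_model, exclude_redundant = exclude_redundant)
  mean_mat <- sd_mat <- matrix(NA_real_, length(T_grid), length(r_values),
                               dimnames = list(NULL, paste0("r", r_values)))
  for (ti in seq_along(T_grid)) {
    vals <- matrix(NA_real_, n_networks, length(r_values))
    for (b in seq_len(n_networks)) {
      comp <- profit_components(sample_inquiry_network(n, T_grid[ti]))
      for (ri in seq_along(r_values))
        vals[b, ri] <- profit_from_components(comp, models[[ri]], config)$group
    }
    mean_mat[ti, ] <- colMeans(vals)
    sd_mat[ti, ] <- apply(vals, 2, stats::sd)
  }
  if (n_networks == 1L) sd_mat[] <- 0
  list(T_grid = T_grid, r_values = r_values,
       mean = mean_mat, sd = sd_mat)
}

#' Ensemble expected-profit curve over random inquiry networks
#'
#' For each total inquiry volume T on the grid, samples `n_networks` directed
#' graphs with exactly T distinct directed edges uniform over the N(N-1)
#' ordered pairs, computes the exact expected group profit of each, and
#' returns the ensemble mean and standard deviation.
#'
#' @param T_grid Increasing grid of total inquiry counts (default 0 to 192,
#'   i.e. 0 to 8 x 24 on 25 players).
#' @param model A [reply_model()].
#' @param n_networks Ensemble size per grid point (default 100).
#' @param seed Optional integer seed.
#' @param config A [game_config()].
#'
#' @return A data frame of class `expected_profit_curve` with columns
#'   `per_player_inquiries`, `total_inquiries`, `mean_profit`, `sd_profit`
#'   (group profit in ECU), and attributes `reply_rate` and `n_networks`.
#' @export
ensemble_curve <- function(T_grid = 0:192, model = reply_model(),
                           n_networks = 100, seed = NULL,
                           config = game_config()) {
  if (is.unsorted(T_grid, strictly = TRUE))
    stop("T_grid must be strictly increasing", call. = FALSE)
  g <- ensemble_profit_grid(T_grid, model$reply_rate, n_networks, seed,
                            config, model$exclude_redundant)
  out <- data.frame(per_player_inquiries = T_grid / config$n_players,
                    total_inquiries = T_grid,
                    mean_profit = g$mean[, 1], sd_profit = g$sd[, 1])
  attr(out, "reply_rate") <- model$reply_rate
  attr(out, "n_networks") <- n_networks
  class(out) <- c("expected_profit_curve", "data.frame")
  out
}

#' Profit-maximising inquiry volume
#'
#' Per-player inquiry volume at which the ensemble mean expected group profit
#' is highest; ties are broken toward the smaller volume.
#'
#' @param curve An [ensemble_curve()] result, or `NULL` to compute one from
#'   the remaining arguments.
#' @inheritParams ensemble_curve
#'
#' @return List with `per_player` (inquiries per player at the maximum),
#'   `total` and `max_mean_profit`.
#' @export
optimal_inquiries <- function(curve = NULL, model = reply_model(),
                              T_grid = 0:192, n_networks = 100, seed = NULL,
                              config = game_config()) {
  if (is.null(curve))
    curve <- ensemble_curve(T_grid, model, n_networks, seed, config)
  if (!nrow(curve)) stop("empty grid", call. = FALSE)
  k <- which.max(curve$mean_profit)  # first max = smaller volume on sorted grid
  list(per_player = curve$per_player_inquiries[k],
       total = curve$total_inquiries[k],
       max_mean_profit = curve$mean_profit[k])
}

#' Smallest reply rate with positive achievable expected profit
#'
#' Scans reply rates 0, step, ..., 1 and returns the first rate at which the
#' maximum over the inquiry-volume grid of the ensemble mean expected group
#' profit is positive. The same network ensemble (fixed seed) is reused
#' across rates so the scan is monotone in r by construction of the model.
#'
#' @param step Scan increment in `(0, 0.1]` (default 0.05).
#' @inheritParams ensemble_curve
#'
#' @return List with `threshold` (reply rate, or `NA` if never positive) and
#'   `max_profit_by_r` (named vector of grid maxima per rate).
#' @export
reply_rate_threshold <- function(step = 0.05, T_grid = 0:192,
                                 n_networks = 100, seed = NULL,
                                 config = game_config(),
                                 exclude_redundant = FALSE) {
  if (step <= 0 || step > 0.1)
    stop("step must be in (0, 0.1]", call. = FALSE)
  r_values <- seq(0, 1, by = step)
  g <- ensemble_profit_grid(T_grid, r_values, n_networks, seed, config,
                            exclude_redundant)
  max_by_r <- apply(g$mean, 2, max)
  names(max_by_r) <- format(r_values)
  hit <- which(max_by_r > 0)
  list(threshold = if (length(hit)) r_values[hit[1]] else NA_real_,
       max_profit_by_r = max_by_r)
}

#' Expected profit under full compliance with the suggestion
#'
#' Expected per-player per-round profit when every player sends an inquiry
#' along each suggested link (the benchmark drawn as a dashed line against
#' realised session profits). At reply rate 1 every player is informed every
#' round: the suggestion graph is bi-directional with diameter two, so each
#' player's expert is either a direct inquirer or shares an inquiry target.
#'
#' @param net A `suggested_network` (or symmetric adjacency matrix).
#' @param model A [reply_model()].
#' @param config A [game_config()].
#'
#' @return Expected ECU per player per round (scalar).
#' @export
compliance_expected_profit <- function(net = build_suggested_network(),
                                       model = reply_model(),
                                       config = game_config()) {
  expected_profit_fixed_network(suggested_inquiry_pattern(net), model,
                                config)$per_player
}

#' Monte Carlo expected profit on a fixed network
#'
#' Stochastic cross-check of [expected_profit_fixed_network()]: draws random
#' cyclic assignments, flips an independent coin with the model's reply rate
#' for every informed-reply opportunity the round actually presents, and
#' averages the realised group profit.
#'
#' @inheritParams expected_profit_fixed_network
#' @param n_draws Number of simulated assignments.
#' @param seed Optional integer seed.
#'
#' @return List with `group_mean`, `group_se` (standard error),
#'   `per_player_mean`, `per_player_se` and `n_draws`.
#' @export
simulate_expected_profit <- function(inquiry_network, model = reply_model(),
                                     config = game_config(), n_draws = 1e5,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- check_inquiry_network(inquiry_network)
  n <- nrow(A)
  r <- model$reply_rate
  excl <- model$exclude_redundant
  common <- A %*% t(A)
  total_inq <- sum(A)
  profits <- vapply(seq_len(n_draws), function(d) {
    p <- sample.int(n)
    sigma <- integer(n)
    sigma[p] <- p[c(n, seq_len(n - 1))]        # expert of p[i] is p[i-1]
    base <- A[cbind(sigma, seq_len(n))] > 0     # expert's inquiry informs x
    self_opp <- A[cbind(seq_len(n), sigma)] > 0 # x inquired the expert
    if (excl) self_opp <- self_opp & !base      # redundant self-reply dropped
    ref_opp <- common[cbind(seq_len(n), sigma)] # third parties able to refer
    self_sent <- self_opp & stats::runif(n) < r
    ref_sent <- stats::rbinom(n, ref_opp, r)
    informed <- base | self_sent | ref_sent > 0
    config$reward * sum(informed) - config$inquiry_cost * total_inq -
      config$reply_cost * (sum(self_sent) + sum(ref_sent))
  }, numeric(1))
  list(group_mean = mean(profits),
       group_se = stats::sd(profits) / sqrt(n_draws),
       per_player_mean = mean(profits) / n,
       per_player_se = stats::sd(profits) / sqrt(n_draws) / n,
       n_draws = n_draws)
}
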