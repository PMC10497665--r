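test_that("session summaries are exact bookkeeping", {
  log <- tiny_session()
  s <- session_summary(log, 1:3)
  # recompute per-round means by hand from the stored outcomes
  for (k in 1:3) {
    o <- log$rounds[[k]]$outcome
    expect_equal(s$per_round$mean_inquiries[k], mean(o$inquiries_sent))
    expect_equal(s$per_round$mean_profit[k], mean(o$profit_delta))
  }
  expect_equal(s$per_round$cum_mean_profit,
               cumsum(s$per_round$mean_profit))
  expect_equal(s$share_positive_profit, mean(s$per_player$profit > 0))
  expect_error(session_summary(log, 4:6), "window")
})

test_that("reply share is sent over available informed replies", {
  # reply rate 1 -> share exactly 1
  log1 <- simulate_session(session_spec(
    6, policies = agent_policy(mean_inquiries = 3, reply_rate = 1,
                               uninformed_reply_rate = 0,
                               redundant_reply_rate = 1),
    seed = 23))
  expect_equal(reply_share(log1, 1:6)$share, 1)

  # a session with no messages has no opportunities
  mute <- simulate_session(session_spec(
    2, policies = agent_policy(mean_inquiries = 0), seed = 1))
  expect_error(reply_share(mute, 1:2), "opportunity")

  # empirical share at rate 0.85 stays within 3 binomial SEs
  log85 <- simulate_session(session_spec(
    51, policies = agent_policy(mean_inquiries = 3, reply_rate = 0.85,
                                uninformed_reply_rate = 0,
                                redundant_reply_rate = 0.85),
    seed = 29))
  rs <- reply_share(log85, 1:51)
  expect_gt(rs$available, 500)
  expect_lt(abs(rs$share - 0.85), 3 * sqrt(0.85 * 0.15 / rs$available))
})

test_that("RRI is attributed reward per message on the filtered links", {
  # one round, one inquiry from a player to their expert, self-expert reply:
  # 10 ECU attributed along the only used link, one inquiry -> RRI 10
  cfg <- game_config(n_players = 5)
  a <- assignment_from_sigma(c(2L, 3L, 4L, 5L, 1L))
  inq <- data.frame(sender = 1L, receiver = 2L)
  reps <- data.frame(sender = 2L, receiver = 1L, kind = "self_expert",
                     named_player = NA_integer_)
  rr <- round_record(1, a, inq, reps)
  log <- make_log(list(list(round_index = 1L, assignment = a,
                            inquiries = inq, replies = reps,
                            outcome = resolve_round(rr, cfg))), cfg)
  expect_equal(rri(log, link_filter = "all")$rri, 10)
  expect_equal(rri(log, link_filter = "all", denominator = "messages")$rri, 5)
  # an empty filter errors explicitly
  no_link <- matrix(0, 5, 5)
  expect_error(rri(log, net = no_link, link_filter = "suggested"),
               "no messages")

  # numerator conservation: total attribution equals reward x informed events
  nlog <- read_session(system.file("extdata", "fixture_nudged.json",
                                   package = "nudgenet"))
  informed_events <- sum(vapply(nlog$rounds, function(rd)
    sum(rd$outcome$informed), numeric(1)))
  r_all <- rri(nlog, link_filter = "all")
  expect_equal(r_all$reward_attributed, 10 * informed_events)
})

test_that("the four link classes partition the inquiries of every round", {
  net <- build_suggested_network()
  nlog <- read_session(system.file("extdata", "fixture_nudged.json",
                                   package = "nudgenet"))
  dec <- link_decomposition(nlog, net)
  expect_equal(dec$suggested_bi + dec$suggested_uni + dec$other_bi +
                 dec$other_uni, dec$total)
  expect_true(all(dec$suggested_bi %% 2 == 0))  # bi-directional counts pair up
  expect_true(all(dec$other_bi %% 2 == 0))

  # full compliance: every inquiry suggested and reciprocated
  clog <- simulate_session(session_spec(2, nudged = TRUE,
                                        suggestion_rounds = 2,
                                        policies = compliance_policy(),
                                        seed = 2))
  cdec <- link_decomposition(clog, net)
  expect_equal(cdec$suggested_bi, cdec$total)
  expect_equal(cdec$other_bi + cdec$other_uni + cdec$suggested_uni,
               rep(0L, 2))

  # a single reciprocal non-suggested pair lands in other x bi-directional
  cfg <- game_config(n_players = 25)
  a <- draw_assignment(25, seed = 8)
  non_edge <- which(net$adjacency == 0 & row(net$adjacency) != col(net$adjacency),
                    arr.ind = TRUE)[1, ]
  inq <- data.frame(sender = c(non_edge[1], non_edge[2]),
                    receiver = c(non_edge[2], non_edge[1]))
  rr <- round_record(1, a, inq)
  log1 <- make_log(list(list(round_index = 1L, assignment = a,
                             inquiries = rr$inquiries, replies = rr$replies,
                             outcome = resolve_round(rr, cfg))), cfg)
  d1 <- link_decomposition(log1, net)
  expect_equal(d1$other_bi, 2L)
  expect_equal(d1$total, 2L)
})

test_that("the reciprocity null matches enumeration and the closed form", {
  # N=3, everyone sends one inquiry: 3 pairs x (1/2)^2 = 0.75
  expect_equal(bidirectional_null(c(1, 1, 1), 3)$expected, 0.75)
  expect_equal(enum_bidirectional(c(1, 1, 1), 3), 0.75)
  # exhaustive agreement across degree vectors for N <= 4
  for (k in list(c(0, 1, 2), c(2, 2, 2), c(1, 0, 1), c(1, 1, 1, 1),
                 c(2, 1, 0, 3), c(3, 3, 3, 3))) {
    n <- length(k)
    expect_equal(bidirectional_null(k, n)$expected, enum_bidirectional(k, n),
                 tolerance = 1e-12, info = paste(k, collapse = ","))
  }
  # degenerate and invalid degree vectors
  expect_equal(bidirectional_null(c(0, 2, 2), 3)$expected,
               enum_bidirectional(c(0, 2, 2), 3))
  expect_error(bidirectional_null(c(5, 0, 0), 3), "out-degrees")
  # N = 25, all k = 6: closed form 300 (6/24)^2
  expect_equal(bidirectional_null(rep(6, 25), 25)$expected, 18.75)
})

test_that("reciprocity in sessions exceeds the null when policies reciprocate", {
  # strong reciprocity weight builds mutual links above the random-target null
  log <- simulate_session(session_spec(
    40, policies = agent_policy(mean_inquiries = 3, reciprocity_weight = 3),
    seed = 41))
  obs <- observed_bidirectional(log)
  late <- obs[obs$round > 20, ]
  null_exp <- vapply(late$round, function(t)
    bidirectional_null(log$rounds[[t]]$outcome$inquiries_sent, 25)$expected,
    numeric(1))
  expect_gt(mean(late$bidirectional_pairs), mean(null_exp))
})

test_that("rank-sum session comparisons report sensible p-values", {
  logA <- simulate_session(session_spec(12, policies = baseline_policy(),
                                        seed = 51, label = "A"))
  logB <- simulate_session(session_spec(12, policies = baseline_policy(),
                                        seed = 52, label = "B"))
  # a session compared with itself is maximally non-significant
  self <- compare_sessions(list(A = logA, B = logA),
                           statistic = "inquiries_round1",
                           correction = "none")
  expect_gt(self$p_value, 0.95)  # exactly 1 up to the continuity correction
  res <- compare_sessions(list(A = logA, B = logB),
                          statistic = "inquiries_per_round",
                          round_window = 1:12)
  expect_identical(res$n1, 12L)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_gte(res$p_adjusted, res$p_value)
  # pooled groups: four sessions, two arms
  logs <- list(A = logA, B = logB, C = logA, D = logB)
  pooled <- compare_sessions(logs, statistic = "inquiries_round1",
                             groups = c(A = "g1", B = "g1", C = "g2", D = "g2"))
  expect_identical(pooled$n1, 50L)
  expect_error(compare_sessions(list(logA)), "two sessions")
})

test_that("the rank-sum test holds its nominal size on equal-policy arms", {
  set.seed(61)
  pol <- agent_policy(mean_inquiries = 3, reciprocity_weight = 1)
  rejections <- 0L
  n_rep <- 120L
  for (b in seq_len(n_rep)) {
    la <- simulate_session(session_spec(1, policies = pol,
                                        seed = sample.int(2^30, 1)))
    lb <- simulate_session(session_spec(1, policies = pol,
                                        seed = sample.int(2^30, 1)))
    p <- compare_sessions(list(a = la, b = lb),
                          statistic = "inquiries_round1",
                          correction = "none")$p_value
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("sent and received message totals correlate within a session", {
  log <- simulate_session(session_spec(30, policies = baseline_policy(),
                                       seed = 71))
  cors <- message_correlations(log, 1:30)
  expect_true(abs(cors$inquiries) <= 1)
  expect_true(abs(cors$messages) <= 1)
  # replies can only go to inquirers, so messages sent/received track each other
  expect_gt(cors$messages, 0)
})
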