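test_that("the closed form matches exhaustive enumeration on small digraphs", {
  cfg3 <- game_config(n_players = 3)
  for (A in all_digraphs(3, 5)) {
    for (r in c(0, 0.5, 1)) {
      for (excl in c(FALSE, TRUE)) {
        expect_equal(
          expected_profit_fixed_network(A, reply_model(r, excl), cfg3)$group,
          enum_expected_profit(A, r, cfg3, excl),
          tolerance = 1e-12)
      }
    }
  }
  # spot-check N = 4 and N = 5 on random digraphs, including fractional rates
  set.seed(77)
  for (trial in 1:10) {
    n <- sample(4:5, 1)
    A <- sample_inquiry_network(n, sample(0:6, 1))
    cfg <- game_config(n_players = n)
    r <- sample(c(0.25, 0.5, 0.8, 1), 1)
    expect_equal(expected_profit_fixed_network(A, reply_model(r), cfg)$group,
                 enum_expected_profit(A, r, cfg), tolerance = 1e-12)
  }
})

test_that("the worked single-inquiry case averages the two 3-cycles", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  ep <- expected_profit_fixed_network(A, reply_model(1),
                                      game_config(n_players = 3))
  expect_equal(ep$group, 8.5)  # (8 + 9) / 2 over the two cyclic assignments
})

test_that("degenerate networks are handled explicitly", {
  cfg <- game_config(n_players = 4)
  empty <- matrix(0, 4, 4)
  ep <- expected_profit_fixed_network(empty, reply_model(0.7), cfg)
  expect_equal(ep$group, 0)
  expect_equal(ep$p_informed, rep(0, 4))
  loop <- empty; loop[2, 2] <- 1
  expect_error(expected_profit_fixed_network(loop, reply_model(1), cfg),
               "self-loop")
  expect_error(ensemble_curve(c(0, 700), reply_model(1), n_networks = 2,
                              config = game_config()),
               "ordered pairs")
})

test_that("at reply rate zero profit is the exact linear closed form", {
  # per-player profit k (reward/(N-1) - inquiry_cost) for any placement with
  # k inquiries per player; structure does not matter at r = 0
  set.seed(5)
  cfg <- game_config()
  for (k in c(1, 3, 6)) {
    A <- matrix(0, 25, 25)
    for (i in 1:25) A[i, sample(setdiff(1:25, i), k)] <- 1
    ep <- expected_profit_fixed_network(A, reply_model(0), cfg)
    expect_equal(ep$per_player, k * (10 / 24 - 1), tolerance = 1e-12)
    expect_lt(ep$per_player, 0)
  }
})

test_that("expected profit is monotone in reply rate and costs", {
  set.seed(21)
  A <- sample_inquiry_network(25, 80)
  prof_r <- vapply(seq(0, 1, 0.25), function(r)
    expected_profit_fixed_network(A, reply_model(r))$group, numeric(1))
  expect_true(all(diff(prof_r) >= 0))
  base <- expected_profit_fixed_network(A, reply_model(0.8))$group
  dearer_inq <- expected_profit_fixed_network(
    A, reply_model(0.8), game_config(inquiry_cost = 2))$group
  dearer_rep <- expected_profit_fixed_network(
    A, reply_model(0.8), game_config(reply_cost = 2))$group
  expect_lt(dearer_inq, base)
  expect_lt(dearer_rep, base)
})

test_that("ensemble curves are reproducible and degenerate sanely at T = 0", {
  cur1 <- ensemble_curve(c(0, 24, 48), reply_model(1), n_networks = 20,
                         seed = 31)
  cur2 <- ensemble_curve(c(0, 24, 48), reply_model(1), n_networks = 20,
                         seed = 31)
  expect_equal(cur1, cur2)
  expect_equal(cur1$mean_profit[1], 0)
  expect_equal(cur1$sd_profit[1], 0)
  expect_true(all(cur1$sd_profit >= 0))
  expect_equal(cur1$per_player_inquiries, c(0, 24, 48) / 25)
})

test_that("the optimal volume is zero at r = 0 and nondecreasing in r", {
  grid <- seq(0, 192, by = 8)
  opts <- vapply(c(0, 0.5, 0.75, 1), function(r)
    optimal_inquiries(ensemble_curve(grid, reply_model(r), n_networks = 30,
                                     seed = 13))$per_player,
    numeric(1))
  expect_equal(opts[1], 0)                  # never profitable to send
  expect_true(all(diff(opts) >= 0))         # more replies support more inquiries
  expect_gte(opts[3], opts[1])
  expect_lte(opts[3], opts[4])
})

test_that("the reply-rate scan is deterministic under a fixed seed", {
  grid <- seq(0, 192, by = 16)
  th1 <- reply_rate_threshold(0.1, grid, n_networks = 20, seed = 3)
  th2 <- reply_rate_threshold(0.1, grid, n_networks = 20, seed = 3)
  expect_identical(th1, th2)
  expect_true(th1$threshold > 0 && th1$threshold <= 1)
  # raising the reward can only lower the threshold
  th_rich <- reply_rate_threshold(0.1, grid, n_networks = 20, seed = 3,
                                  config = game_config(reward = 100))
  expect_lte(th_rich$threshold, th1$threshold)
})

test_that("full compliance informs everyone at r = 1 and prices replies", {
  net <- build_suggested_network()
  ep <- expected_profit_fixed_network(net$adjacency, reply_model(1))
  expect_equal(ep$p_informed, rep(1, 25))
  # E[replies per player] = 6 r (1/24 + 5/24) = 1.5 at r = 1
  expect_equal(ep$expected_replies, rep(1.5, 25))
  expect_equal(compliance_expected_profit(net, reply_model(1)), 10 - 6 - 1.5)
  # dropping redundant replies saves their cost but informs no one less
  expect_equal(compliance_expected_profit(net, reply_model(1, TRUE)),
               10 - 6 - 1.25)
  # at r = 0 only the six expert inquiries can inform: 10 * 6/24 - 6
  expect_equal(compliance_expected_profit(net, reply_model(0)),
               6 * (10 / 24 - 1))
})

test_that("Monte Carlo simulation agrees with the exact expectation", {
  set.seed(19)
  A <- sample_inquiry_network(10, 30)
  cfg <- game_config(n_players = 10)
  for (r in c(0.5, 1)) {
    exact <- expected_profit_fixed_network(A, reply_model(r), cfg)$group
    mc <- simulate_expected_profit(A, reply_model(r), cfg, n_draws = 2e4,
                                   seed = 91)
    expect_lt(abs(mc$group_mean - exact), 3 * mc$group_se + 1e-9)
  }
})
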