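test_that("assignment drawing yields a uniform single cycle with no fixed point", {
  for (n in c(3, 5, 25)) {
    a <- draw_assignment(n, seed = 42)
    expect_true(all(sort(a$question) == 1:n))
    expect_true(all(sort(a$expertise) == 1:n))
    expect_true(all(a$expert_of != seq_len(n)))
    # expert_of^n = identity and expert_of^k != identity for 0 < k < n
    x <- seq_len(n)
    for (k in seq_len(n - 1)) {
      x <- a$expert_of[x]
      expect_false(identical(x, seq_len(n)), info = sprintf("n=%d k=%d", n, k))
    }
    expect_identical(a$expert_of[x], seq_len(n))
    # construction: the expert of p[i] is p[i-1]
    p <- a$player_order
    expect_identical(a$expert_of[p], p[c(n, seq_len(n - 1))])
  }
  expect_identical(draw_assignment(25, seed = 7), draw_assignment(25, seed = 7))
  expect_error(draw_assignment(2), "n_players")
})

test_that("the pair marginal of the cyclic assignment is 1/(N-1)", {
  # For N=3 there are two 3-cycles and each maps player 1 to either of the
  # other two players, so P(expert_of(1) = 2) = 1/2 across seeds.
  set.seed(301)
  hits <- mean(replicate(4000, draw_assignment(3)$expert_of[1] == 2))
  expect_lt(abs(hits - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("reply legality follows the three truthful reply types", {
  # players 1..4; expert-of cycle 1->2->3->4->1 (expert of x is x+1)
  sigma <- c(2L, 3L, 4L, 1L)
  a <- assignment_from_sigma(sigma)
  # inquiries: 1->2 (2 is 1's expert), 3->2, 4->3
  inq <- data.frame(sender = c(1L, 3L, 4L), receiver = c(2L, 2L, 3L))
  rr <- round_record(1, a, inq)
  opts2 <- legal_replies(2, rr)
  # to 1: self-expert; to 3: 2 is not 3's expert (that is 4) and no inquirer
  # of 2 is 3's expert, so only the uninformed reply is legal
  expect_identical(opts2$kind[opts2$receiver == 1], "self_expert")
  expect_identical(opts2$kind[opts2$receiver == 3], "uninformed")
  # 3 received 4's inquiry; 3 is not 4's expert (that is 1); no referral
  opts3 <- legal_replies(3, rr)
  expect_identical(opts3$kind, "uninformed")
  # referral case: add inquiry 2->3 so 3 heard from 2, and 4 asks 3 about
  # expertise held by... expert of 4 is 1; make 1 inquire 3 as well
  inq2 <- rbind(inq, data.frame(sender = 1L, receiver = 3L))
  rr2 <- round_record(1, a, inq2)
  opts3b <- legal_replies(3, rr2)
  ref <- opts3b[opts3b$receiver == 4, ]
  expect_identical(ref$kind, "referral")
  expect_identical(ref$named_player, 1L)
  # empty inbox
  expect_identical(nrow(legal_replies(4, rr)), 0L)
})

test_that("informing messages pool expert inquiries, self-expert replies and referrals", {
  sigma <- c(2L, 3L, 4L, 1L)
  a <- assignment_from_sigma(sigma)
  # expert of 1 is 2. 2 inquires 1 (informing inquiry); 1 inquires 2 and 3;
  # 3 also heard from 2 so 3 can refer 1 to 2.
  inq <- data.frame(sender = c(2L, 1L, 1L, 2L), receiver = c(1L, 2L, 3L, 3L))
  reps <- data.frame(sender = c(2L, 3L), receiver = c(1L, 1L),
                     kind = c("self_expert", "referral"),
                     named_player = c(NA_integer_, 2L))
  rr <- round_record(1, a, inq, reps)
  m <- informing_messages(1, rr)
  expect_setequal(m$type, c("inquiry", "reply_self_expert", "reply_referral"))
  expect_identical(nrow(informing_messages(4, rr)), 0L)
})

test_that("round resolution settles the ledger and splits attribution equally", {
  # worked 3-player case: single inquiry 1->2, expert of 1 is 2, all legal
  # replies sent -> player 1 informed, profits (9, -1, 0)
  a <- assignment_from_sigma(c(2L, 3L, 1L))
  inq <- data.frame(sender = 1L, receiver = 2L)
  reps <- legal_replies(2, round_record(1, a, inq))
  rr <- round_record(1, a, inq, reps)
  out <- resolve_round(rr, game_config(n_players = 3))
  expect_identical(out$informed, c(TRUE, FALSE, FALSE))
  expect_equal(out$profit_delta, c(9, -1, 0))

  # two informing messages (expert inquiry + referral) -> 5/5 split,
  # full reward still reaches the informed player
  sigma <- c(2L, 3L, 4L, 1L)
  a4 <- assignment_from_sigma(sigma)
  inq4 <- data.frame(sender = c(2L, 1L, 2L), receiver = c(1L, 3L, 3L))
  reps4 <- data.frame(sender = 3L, receiver = 1L, kind = "referral",
                      named_player = 2L)
  rr4 <- round_record(1, a4, inq4, reps4)
  out4 <- resolve_round(rr4, game_config(n_players = 4))
  att <- out4$attribution[out4$attribution$informed_player == 1, ]
  expect_setequal(att$sender, c(2L, 3L))
  expect_equal(att$share, c(5, 5))
  expect_equal(out4$profit_delta[1], 10 - 1)  # 10 reward, one inquiry sent

  # forged reply (self-expert claim by a non-expert) is rejected
  bad <- data.frame(sender = 3L, receiver = 1L, kind = "self_expert",
                    named_player = NA_integer_)
  rr_bad <- round_record(1, a4, inq4, bad)
  expect_error(resolve_round(rr_bad, game_config(n_players = 4)),
               "illegal reply")
})

test_that("redundancy is the self-expert reply to a reciprocal inquirer", {
  a <- assignment_from_sigma(c(2L, 3L, 1L))
  inq <- data.frame(sender = c(1L, 2L), receiver = c(2L, 1L))
  rr <- round_record(1, a, inq)
  self_rep <- list(sender = 2L, receiver = 1L, kind = "self_expert")
  expect_true(is_redundant(self_rep, rr))
  # without the reciprocal inquiry the same reply is informative
  rr1 <- round_record(1, a, inq[1, , drop = FALSE])
  expect_false(is_redundant(self_rep, rr1))
  expect_false(is_redundant(list(sender = 2L, receiver = 1L,
                                 kind = "referral"), rr))
})

test_that("session ledgers conserve currency and attribution", {
  log <- tiny_session()
  cfg <- log$config
  for (rd in log$rounds) {
    o <- rd$outcome
    expect_equal(sum(o$attribution$share), cfg$reward * sum(o$informed))
    expect_equal(o$profit_delta,
                 cfg$reward * o$informed - cfg$inquiry_cost * o$inquiries_sent -
                   cfg$reply_cost * o$replies_sent)
  }
  # final profit equals the sum of round deltas (endowment never enters)
  totals <- Reduce(`+`, lapply(log$rounds, function(rd) rd$outcome$profit_delta))
  expect_equal(session_summary(log)$per_player$profit, totals)
})

test_that("round records reject malformed input", {
  a <- assignment_from_sigma(c(2L, 3L, 1L))
  expect_error(round_record(1, a, data.frame(sender = 1L, receiver = 1L)),
               "self-inquiry")
  expect_error(round_record(1, a, data.frame(sender = c(1L, 1L),
                                             receiver = c(2L, 2L))),
               "duplicate")
  expect_error(
    round_record(1, a, data.frame(sender = 1L, receiver = 2L),
                 data.frame(sender = 3L, receiver = 1L, kind = "uninformed",
                            named_player = NA_integer_)),
    "matching")
})
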