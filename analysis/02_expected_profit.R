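#!/usr/bin/env Rscript
# Step 2: the expected-profit model. For each total inquiry volume we draw
# 100 random directed inquiry networks and compute each network's exact
# expected group profit under a uniform cyclic question/expertise assignment
# and a Bernoulli reply rate; the mean curves locate the profitable regime.
# We then ask two questions the curves answer: what inquiry volume maximises
# group profit when everyone replies (r = 1), and how much replying the
# network needs before communication pays at all. Finally we price the
# full-compliance benchmark on the suggestion graph.

library(nudgenet)

dir.create("results", showWarnings = FALSE)
seed <- 20260901

T_grid <- seq(0, 192, by = 2)
rates <- c(0, 0.25, 0.5, 0.75, 1)

curves <- lapply(rates, function(r) {
  cur <- ensemble_curve(T_grid, reply_model(r), n_networks = 100,
                        seed = seed, config = game_config())
  cur$reply_rate <- r
  cur
})
all_curves <- do.call(rbind, lapply(curves, as.data.frame))
utils::write.csv(all_curves, "results/expected_profit_curves.csv",
                 row.names = FALSE)

cat("Expected group profit across inquiry volumes (ensemble means):\n")
for (cur in curves) {
  opt <- optimal_inquiries(cur)
  cat(sprintf("  r = %-4s peak %6.2f ECU at %.2f inquiries/player\n",
              format(cur$reply_rate[1]), opt$max_mean_profit,
              opt$per_player))
}

opt1 <- optimal_inquiries(curves[[length(curves)]])
cat(sprintf("\nAt full replying the group does best near %.1f inquiries per player.\n",
            opt1$per_player))

th <- reply_rate_threshold(step = 0.05, T_grid = T_grid, n_networks = 100,
                           seed = seed)
cat(sprintf("Profit first turns positive at a reply rate of %.0f%%.\n",
            100 * th$threshold))

# full-compliance benchmark on the suggestion graph
net <- build_suggested_network()
bench <- data.frame(
  variant = c("include_redundant", "exclude_redundant", "no_replies"),
  per_player_per_round = c(
    compliance_expected_profit(net, reply_model(1)),
    compliance_expected_profit(net, reply_model(1, exclude_redundant = TRUE)),
    compliance_expected_profit(net, reply_model(0))))
cat(sprintf("\nFull compliance with the suggestion yields %.2f ECU/player/round\n",
            bench$per_player_per_round[1]))
cat(sprintf("  (%.2f without redundant replies; %.2f if nobody replied).\n",
            bench$per_player_per_round[2], bench$per_player_per_round[3]))

utils::write.csv(
  rbind(data.frame(quantity = "optimal_inquiries_per_player_r1",
                   value = opt1$per_player),
        data.frame(quantity = "reply_rate_threshold", value = th$threshold),
        data.frame(quantity = paste0("compliance_", bench$variant),
                   value = bench$per_player_per_round)),
  "results/expected_profit_summary.csv", row.names = FALSE)
cat("wrote results/expected_profit_{curves,summary}.csv\n")
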