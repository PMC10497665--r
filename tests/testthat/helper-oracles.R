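# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive quantities by exhaustive enumeration and never
# call the closed-form code paths they are used to check.

# All cyclic permutations of 1..n (single n-cycles), as expert-of vectors:
# sigma[x] is the expert of x.
all_cyclic_perms <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  lapply(perms(2:n), function(ord) {
    cyc <- c(1L, ord)                 # visiting order of the cycle
    sigma <- integer(n)
    sigma[cyc] <- cyc[c(n, seq_len(n - 1))]  # expert = predecessor in cycle
    sigma
  })
}

# Exhaustive expected group profit: enumerate every cyclic assignment and
# every subset of the informed replies the round makes available, weighting
# reply subsets by independent Bernoulli(r) coins.
enum_expected_profit <- function(A, r, config = game_config(n_players = nrow(A)),
                                 exclude_redundant = FALSE) {
  n <- nrow(A)
  edges <- which(A > 0, arr.ind = TRUE)  # x -> m inquiries
  total_inq <- nrow(edges)
  sigmas <- all_cyclic_perms(n)
  acc <- 0
  for (sigma in sigmas) {
    base <- vapply(seq_len(n), function(x) A[sigma[x], x] > 0, logical(1))
    # potential informed replies: one per inquiry x -> m that m can answer
    targets <- integer(0)
    for (e in seq_len(total_inq)) {
      if (!total_inq) break
      x <- edges[e, 1]; m <- edges[e, 2]
      if (sigma[x] == m) {                      # self-expert reply
        if (exclude_redundant && A[m, x] > 0) next
        targets <- c(targets, x)
      } else if (A[sigma[x], m] > 0) {          # referral naming sigma[x]
        targets <- c(targets, x)
      }
    }
    R <- length(targets)
    subsets <- if (R) as.matrix(expand.grid(rep(list(0:1), R))) else
      matrix(0L, 1, 0)
    for (s in seq_len(nrow(subsets))) {
      bits <- subsets[s, ]
      wgt <- prod(ifelse(bits == 1, r, 1 - r))
      if (wgt == 0) next
      informed <- base
      informed[targets[bits == 1]] <- TRUE
      profit <- config$reward * sum(informed) -
        config$inquiry_cost * total_inq - config$reply_cost * sum(bits)
      acc <- acc + wgt * profit
    }
  }
  acc / length(sigmas)
}

# Exhaustive expected number of mutual inquiry pairs when each player a picks
# k[a] distinct targets uniformly among the other n-1 players.
enum_bidirectional <- function(k, n) {
  choices <- lapply(seq_len(n), function(a) {
    others <- setdiff(seq_len(n), a)
    if (k[a] == 0) return(list(integer(0)))
    cmb <- utils::combn(others, k[a])
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  })
  grid <- expand.grid(lapply(choices, seq_along))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    adj <- matrix(0L, n, n)
    for (a in seq_len(n)) {
      t <- choices[[a]][[grid[g, a]]]
      if (length(t)) adj[a, t] <- 1L
    }
    tot <- tot + sum(adj * t(adj)) / 2
  }
  tot / nrow(grid)
}

# All digraphs on n nodes with up to max_edges directed edges, as adjacency
# matrices (used for the oracle-equivalence sweep).
all_digraphs <- function(n, max_edges) {
  m <- matrix(0L, n, n)
  off <- which(row(m) != col(m))
  out <- list(m)
  for (e in seq_len(max_edges)) {
    cmb <- utils::combn(off, e)
    for (j in seq_len(ncol(cmb))) {
      a <- m
      a[cmb[, j]] <- 1L
      out[[length(out) + 1L]] <- a
    }
  }
  out
}

# Small deterministic session for metric bookkeeping tests.
tiny_session <- function(seed = 101) {
  simulate_session(session_spec(
    3, policies = agent_policy(mean_inquiries = 2, reciprocity_weight = 2),
    seed = seed, config = game_config(n_players = 5), label = "F5"))
}

# Build an expertise_assignment realising a given expert-of vector (sigma
# must be a fixed-point-free single cycle).
assignment_from_sigma <- function(sigma) {
  n <- length(sigma)
  question <- seq_len(n)
  expertise <- integer(n)
  expertise[sigma] <- question          # expert's expertise answers the question
  structure(
    list(n_players = n, player_order = seq_len(n),
         letter_order = question, question = question,
         expertise = expertise, expert_of = sigma),
    class = "expertise_assignment")
}

# Wrap hand-built rounds into a minimal session_log.
make_log <- function(rounds, config, nudged = FALSE, label = NULL) {
  structure(
    list(config = config, label = label, nudged = nudged,
         suggestion_rounds = if (nudged) 5L else 0L, seed = NA_integer_,
         n_rounds = length(rounds),
         suggested_network = if (nudged) build_suggested_network()$adjacency,
         rounds = rounds),
    class = "session_log")
}
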