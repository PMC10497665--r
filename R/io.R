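# Session-log serialization. Canonical on-disk format is JSON (nested
# rounds); a flat CSV event table is provided for spreadsheet use. Player ids
# are serialized 1..N and question/expertise as letters A.. . Round outcomes
# are recomputed on read (they are deterministic functions of the messages),
# so files carry only the primary record.

session_format_version <- "1"

assignment_to_list <- function(a) {
  lab <- letter_labels(a$n_players)
  list(player_order = a$player_order, letter_order = lab[a$letter_order],
       question = lab[a$question], expertise = lab[a$expertise])
}

assignment_from_list <- function(x, n) {
  lab <- letter_labels(n)
  question <- match(unlist(x$question), lab)
  expertise <- match(unlist(x$expertise), lab)
  if (anyNA(question) || anyNA(expertise) ||
      anyDuplicated(question) || anyDuplicated(expertise))
    stop("question/expertise letters do not form bijections", call. = FALSE)
  structure(
    list(n_players = n, player_order = as.integer(unlist(x$player_order)),
         letter_order = match(unlist(x$letter_order), lab),
         question = question, expertise = expertise,
         expert_of = match(question, expertise)),
    class = "expertise_assignment")
}

#' Write a session log to disk
#'
#' JSON is the canonical nested format; `"csv"` writes a flat event table
#' (one row per assignment entry, inquiry or reply) preceded by `#`-prefixed
#' header lines. Both round-trip through [read_session()].
#'
#' @param log A `session_log`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#'
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(log, "session_log"))
  if (format == "json") {
    body <- list(
      format = "nudgenet-session", version = session_format_version,
      header = list(
        n_players = log$config$n_players,
        inquiry_cost = log$config$inquiry_cost,
        reply_cost = log$config$reply_cost, reward = log$config$reward,
        endowment = log$config$endowment, label = log$label,
        nudged = log$nudged, suggestion_rounds = log$suggestion_rounds,
        seed = log$seed, n_rounds = log$n_rounds),
      rounds = lapply(log$rounds, function(rd) list(
        round = rd$round_index,
        assignment = assignment_to_list(rd$assignment),
        inquiries = rd$inquiries,
        replies = rd$replies)))
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", na = "null")
  } else {
    events <- session_events(log)
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- c(n_players = log$config$n_players,
             inquiry_cost = log$config$inquiry_cost,
             reply_cost = log$config$reply_cost, reward = log$config$reward,
             endowment = log$config$endowment,
             label = if (is.null(log$label)) "" else log$label,
             nudged = as.integer(log$nudged),
             suggestion_rounds = log$suggestion_rounds, seed = log$seed,
             n_rounds = log$n_rounds, version = session_format_version)
    writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
    utils::write.csv(events, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Flatten a session log to its event table
#'
#' One row per event: stage 0 rows carry the round's assignment (one per
#' player, with question/expertise letters), stage 1 rows the inquiries,
#' stage 2 rows the typed replies.
#'
#' @param log A `session_log`.
#' @return Data frame with columns `round`, `stage`, `sender`, `receiver`,
#'   `message_type`, `named_player`, `question`, `expertise`.
#' @export
session_events <- function(log) {
  lab <- letter_labels(log$config$n_players)
  do.call(rbind, lapply(log$rounds, function(rd) {
    a <- rd$assignment
    assign_rows <- data.frame(
      round = rd$round_index, stage = 0L, sender = seq_len(a$n_players),
      receiver = NA_integer_, message_type = "assignment",
      named_player = NA_integer_, question = lab[a$question],
      expertise = lab[a$expertise])
    inq_rows <- if (nrow(rd$inquiries)) data.frame(
      round = rd$round_index, stage = 1L, sender = rd$inquiries$sender,
      receiver = rd$inquiries$receiver, message_type = "inquiry",
      named_player = NA_integer_, question = NA_character_,
      expertise = NA_character_)
    rep_rows <- if (nrow(rd$replies)) data.frame(
      round = rd$round_index, stage = 2L, sender = rd$replies$sender,
      receiver = rd$replies$receiver,
      message_type = paste0("reply_", rd$replies$kind),
      named_player = rd$replies$named_player, question = NA_character_,
      expertise = NA_character_)
    rbind(assign_rows, inq_rows, rep_rows)
  }))
}

# Rebuild a session_log from a flat event table plus header fields.
session_from_events <- function(events, header, strict = TRUE) {
  config <- game_config(header$n_players, header$inquiry_cost,
                        header$reply_cost, header$reward, header$endowment)
  n <- config$n_players
  lab <- letter_labels(n)
  req <- c("round", "stage", "sender", "message_type")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rounds_idx <- sort(unique(events$round))
  if (!identical(as.integer(rounds_idx), seq_len(header$n_rounds)))
    stop("event rounds do not cover 1..n_rounds", call. = FALSE)
  violations <- character(0)
  rounds <- lapply(rounds_idx, function(t) {
    ev <- events[events$round == t, , drop = FALSE]
    arow <- ev[ev$message_type == "assignment", , drop = FALSE]
    if (nrow(arow) != n)
      stop("round ", t, ": expected ", n, " assignment rows", call. = FALSE)
    arow <- arow[order(arow$sender), ]
    question <- match(arow$question, lab)
    expertise <- match(arow$expertise, lab)
    if (anyNA(question) || anyDuplicated(question) ||
        anyNA(expertise) || anyDuplicated(expertise))
      stop("round ", t, ": letters do not form bijections", call. = FALSE)
    assignment <- structure(
      list(n_players = n, player_order = order(question),
           letter_order = question[order(question)],
           question = question, expertise = expertise,
           expert_of = match(question, expertise)),
      class = "expertise_assignment")
    inq <- ev[ev$message_type == "inquiry", c("sender", "receiver")]
    reps <- ev[startsWith(ev$message_type, "reply_"), , drop = FALSE]
    replies <- if (nrow(reps)) data.frame(
      sender = reps$sender, receiver = reps$receiver,
      kind = sub("^reply_", "", reps$message_type),
      named_player = as.integer(reps$named_player)) else empty_replies()
    rr <- round_record(t, assignment, inq, replies)
    outcome <- resolve_round(rr, config, strict = strict)
    if (length(outcome$violations))
      violations <<- c(violations,
                       sprintf("round %d: %s", t, outcome$violations))
    list(round_index = as.integer(t), assignment = assignment,
         inquiries = rr$inquiries, replies = rr$replies, outcome = outcome)
  })
  log <- structure(
    list(config = config,
         label = if (is.null(header$label) || identical(header$label, ""))
           NULL else header$label,
         nudged = isTRUE(as.logical(header$nudged)),
         suggestion_rounds = as.integer(header$suggestion_rounds %||% 0L),
         seed = if (is.null(header$seed)) NA_integer_ else
           as.integer(header$seed),
         n_rounds = length(rounds),
         suggested_network = if (isTRUE(as.logical(header$nudged)))
           build_suggested_network()$adjacency,
         rounds = rounds),
    class = "session_log")
  attr(log, "validation") <- violations
  log
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a session log
#'
#' @param path File written by [write_session()].
#' @param format `"json"`, `"csv"`, or `NULL` to infer from the extension.
#'
#' @return A `session_log`; round outcomes are recomputed from the messages.
#' @export
read_session <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    body <- jsonlite::read_json(path, simplifyVector = FALSE)
    header <- body$header
    n <- header$n_players
    config <- game_config(n, header$inquiry_cost, header$reply_cost,
                          header$reward, header$endowment)
    col <- function(x, field, mode) {
      v <- unlist(x[[field]])
      if (is.null(v)) vector(mode, 0L) else as.vector(v, mode)
    }
    log_rounds <- lapply(body$rounds, function(rd) {
      assignment <- assignment_from_list(rd$assignment, n)
      inq <- data.frame(sender = col(rd$inquiries, "sender", "integer"),
                        receiver = col(rd$inquiries, "receiver", "integer"))
      kind <- col(rd$replies, "kind", "character")
      reps <- if (length(kind)) {
        np <- rd$replies$named_player
        np <- vapply(np, function(v)
          if (is.null(v)) NA_integer_ else as.integer(v), integer(1))
        data.frame(sender = col(rd$replies, "sender", "integer"),
                   receiver = col(rd$replies, "receiver", "integer"),
                   kind = kind, named_player = np)
      } else empty_replies()
      rr <- round_record(rd$round, assignment, inq, reps)
      list(round_index = as.integer(rd$round), assignment = assignment,
           inquiries = rr$inquiries, replies = rr$replies,
           outcome = resolve_round(rr, config))
    })
    structure(
      list(config = config, label = header$label,
           nudged = isTRUE(header$nudged),
           suggestion_rounds = as.integer(header$suggestion_rounds),
           seed = as.integer(header$seed), n_rounds = length(log_rounds),
           suggested_network = if (isTRUE(header$nudged))
             build_suggested_network()$adjacency,
           rounds = log_rounds),
      class = "session_log")
  } else {
    lines <- readLines(path)
    hdr_lines <- grep("^#", lines, value = TRUE)
    kv <- regmatches(hdr_lines, regexec("^# ([^:]+): (.*)$", hdr_lines))
    header <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
    for (f in c("n_players", "inquiry_cost", "reply_cost", "reward",
                "endowment", "nudged", "suggestion_rounds", "seed",
                "n_rounds"))
      header[[f]] <- as.numeric(header[[f]])
    events <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                              stringsAsFactors = FALSE)
    session_from_events(events, header)
  }
}

#' Load an externally deposited session through a schema map
#'
#' Ingests a flat CSV event table whose column names, message-type codes and
#' header metadata differ from the package's native format. The schema map
#' declares the correspondence; validation can be tolerant (violations are
#' flagged on the returned log rather than rejected), since lab software can
#' produce technically illegal rows.
#'
#' @param path CSV file with one row per event.
#' @param schema_map A list (or path to a YAML file encoding one) with
#'   elements: `columns`, a named character vector mapping native names
#'   (`round`, `stage`, `sender`, `receiver`, `message_type`, `named_player`,
#'   `question`, `expertise`) to the file's column names; `values`, an
#'   optional list with a `message_type` named vector mapping native codes to
#'   the file's codes; and `header`, a list with at least `n_players` and
#'   `n_rounds` (costs default to the standard game).
#' @param strict If `FALSE` (default), legality violations are collected into
#'   `attr(log, "validation")` instead of aborting.
#'
#' @return A `session_log`.
#' @export
load_deposited <- function(path, schema_map, strict = FALSE) {
  if (is.character(schema_map) && length(schema_map) == 1L)
    schema_map <- yaml::read_yaml(schema_map)
  cols <- unlist(schema_map$columns)
  req <- c("round", "stage", "sender", "receiver", "message_type")
  miss <- setdiff(req, names(cols))
  if (length(miss))
    stop("schema map does not declare required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  absent <- setdiff(unname(cols), names(raw))
  if (length(absent))
    stop("mapped column(s) not present in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  events <- raw[, unname(cols), drop = FALSE]
  names(events) <- names(cols)
  vm <- schema_map$values$message_type
  if (!is.null(vm)) {
    vm <- unlist(vm)
    hit <- match(events$message_type, unname(vm))
    events$message_type <- ifelse(is.na(hit), events$message_type,
                                  names(vm)[hit])
  }
  header <- schema_map$header
  if (is.null(header$n_players))
    stop("schema map header must give n_players", call. = FALSE)
  if (is.null(header$n_rounds)) header$n_rounds <- max(events$round)
  defaults <- game_config(header$n_players)
  for (f in c("inquiry_cost", "reply_cost", "reward", "endowment"))
    header[[f]] <- header[[f]] %||% defaults[[f]]
  session_from_events(events, header, strict = strict)
}

#' Write an expected-profit curve as CSV
#'
#' @param curve An [ensemble_curve()] result.
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
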