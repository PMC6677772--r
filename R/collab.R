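# Deterministic multi-annotator collaboration engine.
#
# The core is a pure state machine over a server-ordered command stream:
# every edit is converted to a command, assigned a strictly increasing
# sequence number by the session, applied, and appended to a persistent
# log. Replaying the log from the empty state reproduces the final
# annotation exactly, independent of client submission timing. Avatar
# position updates are ephemeral broadcast data and never enter the log.

COMMAND_KINDS <- c("add_segment", "delete_segment", "add_marker",
                   "delete_marker", "set_node_attr")

# fixed 32-entry annotator palette, assigned by join order
COLLAB_PALETTE <- c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
  "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78",
  "#98DF8A", "#FF9896", "#C5B0D5", "#C49C94", "#F7B6D2", "#C7C7C7",
  "#DBDB8D", "#9EDAE5", "#393B79", "#637939", "#8C6D31", "#843C39",
  "#7B4173", "#5254A3", "#8CA252", "#BD9E39", "#AD494A", "#A55194",
  "#6B6ECF", "#B5CF6B")

stop_auth <- function(...) stop_typed("neurotrace_auth_error", ...)
stop_rejected <- function(...) stop_typed("neurotrace_command_rejected", ...)
stop_sequence <- function(...) stop_typed("neurotrace_sequence_error", ...)
stop_log <- function(...) stop_typed("neurotrace_log_integrity_error", ...)

#' Create an empty collaboration session
#'
#' @return An object of class `collab_session` holding the shared
#'   annotation (a node forest plus markers, every element tagged with the
#'   originating client), the client registry, id counters, the last
#'   applied sequence number and the persistent command log.
#' @export
collab_session <- function() {
  structure(list(
    nodes = data.frame(id = integer(), type = integer(), x = numeric(),
                       y = numeric(), z = numeric(), radius = numeric(),
                       parent = integer(), client_id = character(),
                       stringsAsFactors = FALSE),
    markers = data.frame(id = integer(), x = numeric(), y = numeric(),
                         z = numeric(), name = character(),
                         client_id = character(), stringsAsFactors = FALSE),
    clients = data.frame(client_id = character(), username = character(),
                         color = character(), active = logical(),
                         stringsAsFactors = FALSE),
    next_node_id = 1L, next_marker_id = 1L, last_seq = 0L, log = list()),
    class = "collab_session")
}

#' @export
print.collab_session <- function(x, ...) {
  cat(sprintf("<collab_session> %d node(s), %d marker(s), %d client(s), seq %d\n",
              nrow(x$nodes), nrow(x$markers), nrow(x$clients), x$last_seq))
  invisible(x)
}

#' Connect an annotator to a session
#'
#' Registers a client and assigns a color from a fixed 32-entry palette by
#' join order, so colors are deterministic given the join sequence and
#' pairwise distinct among clients. Reconnecting with a username seen
#' before reactivates the same client id and color.
#'
#' @param state A `collab_session`.
#' @param username Nonempty display name.
#' @return List with the updated `state`, the assigned `client_id` and
#'   `color`.
#' @export
session_connect <- function(state, username) {
  if (!nzchar(username)) stop_auth("username must be nonempty")
  known <- match(username, state$clients$username)
  if (!is.na(known)) {
    state$clients$active[known] <- TRUE
    return(list(state = state, client_id = state$clients$client_id[known],
                color = state$clients$color[known]))
  }
  if (sum(state$clients$active) >= length(COLLAB_PALETTE)) {
    stop_auth("color palette exhausted: more than ",
              length(COLLAB_PALETTE), " active annotators")
  }
  idx <- nrow(state$clients) + 1L
  if (idx > length(COLLAB_PALETTE)) {
    stop_auth("color palette exhausted over the session lifetime")
  }
  client_id <- sprintf("c%02d", idx)
  color <- COLLAB_PALETTE[idx]
  state$clients <- rbind(state$clients,
                         data.frame(client_id = client_id, username = username,
                                    color = color, active = TRUE,
                                    stringsAsFactors = FALSE))
  list(state = state, client_id = client_id, color = color)
}

#' @rdname session_connect
#' @export
session_disconnect <- function(state, client_id) {
  i <- match(client_id, state$clients$client_id)
  if (is.na(i)) stop_auth("unknown client: ", client_id)
  state$clients$active[i] <- FALSE
  state
}

validate_payload <- function(state, client_id, kind, payload) {
  switch(kind,
    add_segment = {
      nn <- payload$nodes
      if (is.null(nn) || !is.data.frame(nn) || nrow(nn) == 0) {
        stop_rejected("add_segment: payload must carry a nonempty node table")
      }
      need <- c("id", "type", "x", "y", "z", "radius", "parent")
      if (!all(need %in% names(nn))) {
        stop_rejected("add_segment: node table needs columns ",
                      paste(need, collapse = ", "))
      }
      if (anyDuplicated(nn$id)) stop_rejected("add_segment: duplicate local id")
      ok_parent <- nn$parent == -1L | nn$parent %in% nn$id
      if (!all(ok_parent)) {
        stop_rejected("add_segment: local parent not in payload: ",
                      nn$parent[!ok_parent][1])
      }
      if (!is.null(payload$attach_id) &&
          !(payload$attach_id %in% state$nodes$id)) {
        stop_rejected("add_segment: attach point ", payload$attach_id,
                      " does not exist")
      }
    },
    delete_segment = {
      ids <- payload$node_ids
      if (length(ids) == 0) stop_rejected("delete_segment: no node ids")
      missing <- setdiff(ids, state$nodes$id)
      if (length(missing) > 0) {
        stop_rejected("delete_segment: node(s) not present: ",
                      paste(utils::head(missing, 10), collapse = ", "))
      }
      child_outside <- state$nodes$id[state$nodes$parent %in% ids &
                                      !(state$nodes$id %in% ids)]
      if (length(child_outside) > 0) {
        stop_rejected("delete_segment: would orphan node(s): ",
                      paste(utils::head(child_outside, 10), collapse = ", "))
      }
    },
    add_marker = {
      if (is.null(payload$x) || is.null(payload$y) || is.null(payload$z)) {
        stop_rejected("add_marker: needs x, y, z")
      }
    },
    delete_marker = {
      if (!(payload$marker_id %in% state$markers$id)) {
        stop_rejected("delete_marker: marker ", payload$marker_id,
                      " does not exist")
      }
    },
    set_node_attr = {
      if (!(payload$node_id %in% state$nodes$id)) {
        stop_rejected("set_node_attr: node ", payload$node_id,
                      " does not exist")
      }
      if (is.null(payload$key) || !nzchar(payload$key)) {
        stop_rejected("set_node_attr: empty attribute key")
      }
    },
    stop_rejected("unknown command kind: ", kind))
  invisible(TRUE)
}

#' Submit an annotation operation to the session
#'
#' Validates the payload against the current state, assigns the next
#' sequence number, applies the command and appends it to the persistent
#' log. Client-local node ids inside `add_segment` payloads are remapped to
#' fresh global ids; the mapping is returned to the submitter. Invalid
#' payloads (for example deleting an id that no longer exists) are rejected
#' with a typed condition and do not consume a sequence number.
#'
#' @param state A `collab_session`.
#' @param client_id Id returned by [session_connect()].
#' @param kind One of `add_segment`, `delete_segment`, `add_marker`,
#'   `delete_marker`, `set_node_attr`.
#' @param payload Kind-specific named list (see the command schema in the
#'   package vignette).
#' @param wall_time Informational timestamp string stored in the command;
#'   never influences the state transition.
#' @return List with updated `state`, the sequenced `command`, and for
#'   `add_segment` an `id_map` (named: local id -> global id).
#' @export
session_submit <- function(state, client_id, kind, payload,
                           wall_time = "") {
  i <- match(client_id, state$clients$client_id)
  if (is.na(i) || !state$clients$active[i]) {
    stop_auth("unknown or disconnected client: ", client_id)
  }
  validate_payload(state, client_id, kind, payload)
  cmd <- list(seq = state$last_seq + 1L, client_id = client_id, kind = kind,
              payload = payload, wall_time = wall_time)
  id_map <- NULL
  if (kind == "add_segment") {
    local <- as.integer(payload$nodes$id)
    id_map <- stats::setNames(seq(state$next_node_id, by = 1L,
                                  length.out = length(local)), local)
  }
  state <- apply_command(state, cmd)
  list(state = state, command = cmd, id_map = id_map)
}

#' Apply one sequenced command to a session state
#'
#' Pure, deterministic state transition: the result depends only on the
#' incoming state and the command, never on wall-clock time or hidden
#' randomness. The command's sequence number must be exactly one past the
#' last applied one.
#'
#' @param state A `collab_session`.
#' @param cmd A command as produced by [session_submit()] or read from a
#'   session log.
#' @return The updated `collab_session`.
#' @export
apply_command <- function(state, cmd) {
  if (cmd$seq != state$last_seq + 1L) {
    stop_sequence("out-of-order command: expected seq ", state$last_seq + 1L,
                  ", got ", cmd$seq)
  }
  validate_payload(state, cmd$client_id, cmd$kind, cmd$payload)
  payload <- cmd$payload
  switch(cmd$kind,
    add_segment = {
      nn <- payload$nodes
      glob <- stats::setNames(seq(state$next_node_id, by = 1L,
                                  length.out = nrow(nn)),
                              as.character(as.integer(nn$id)))
      new_parent <- ifelse(nn$parent == -1L,
                           if (is.null(payload$attach_id)) -1L
                           else as.integer(payload$attach_id),
                           glob[as.character(as.integer(nn$parent))])
      add <- data.frame(id = as.integer(glob), type = as.integer(nn$type),
                        x = as.numeric(nn$x), y = as.numeric(nn$y),
                        z = as.numeric(nn$z), radius = as.numeric(nn$radius),
                        parent = as.integer(new_parent),
                        client_id = cmd$client_id, stringsAsFactors = FALSE)
      for (cc in setdiff(names(state$nodes),
                         c(names(add)))) add[[cc]] <- NA_character_
      if (!is.null(payload$attrs)) {
        for (k in names(payload$attrs)) {
          if (!k %in% names(state$nodes)) state$nodes[[k]] <- NA_character_
          if (!k %in% names(add)) add[[k]] <- NA_character_
          add[[k]] <- as.character(payload$attrs[[k]])
        }
      }
      state$nodes <- rbind(state$nodes, add[, names(state$nodes)])
      state$next_node_id <- state$next_node_id + nrow(nn)
    },
    delete_segment = {
      state$nodes <- state$nodes[!(state$nodes$id %in% payload$node_ids), ,
                                 drop = FALSE]
      rownames(state$nodes) <- NULL
    },
    add_marker = {
      state$markers <- rbind(state$markers, data.frame(
        id = state$next_marker_id, x = as.numeric(payload$x),
        y = as.numeric(payload$y), z = as.numeric(payload$z),
        name = as.character(payload$name %||% ""),
        client_id = cmd$client_id, stringsAsFactors = FALSE))
      state$next_marker_id <- state$next_marker_id + 1L
    },
    delete_marker = {
      state$markers <- state$markers[state$markers$id != payload$marker_id, ,
                                     drop = FALSE]
      rownames(state$markers) <- NULL
    },
    set_node_attr = {
      k <- payload$key
      if (!k %in% names(state$nodes)) state$nodes[[k]] <- NA_character_
      state$nodes[[k]][state$nodes$id == payload$node_id] <-
        as.character(payload$value)
    })
  state$last_seq <- cmd$seq
  state$log[[cmd$seq]] <- cmd
  state
}

#' Replay a session log
#'
#' Folds [apply_command()] over a seq-contiguous command list starting from
#' the empty session, registering the given clients first. Two replays of
#' the same log produce identical states, and the exported SWC is
#' byte-identical across runs and machines.
#'
#' @param commands List of commands ordered (or orderable) by `seq`; seqs
#'   must run 1..n without gaps or duplicates.
#' @param clients Optional data frame (`client_id`, `username`, `color`)
#'   registering the participants; when omitted, clients are registered in
#'   order of first appearance in the log.
#' @return The final `collab_session`.
#' @export
session_replay <- function(commands, clients = NULL) {
  seqs <- vapply(commands, function(cm) as.integer(cm$seq), integer(1))
  o <- order(seqs)
  commands <- commands[o]
  seqs <- seqs[o]
  if (length(seqs) > 0 && !identical(seqs, seq_len(length(seqs)))) {
    if (anyDuplicated(seqs)) stop_log("duplicate seq in log: ",
                                      seqs[duplicated(seqs)][1])
    stop_log("gap in log: expected contiguous seq 1..", length(seqs))
  }
  state <- collab_session()
  if (!is.null(clients)) {
    for (i in seq_len(nrow(clients))) {
      state$clients <- rbind(state$clients, data.frame(
        client_id = clients$client_id[i], username = clients$username[i],
        color = clients$color[i], active = TRUE, stringsAsFactors = FALSE))
    }
  } else {
    for (cm in commands) {
      if (!(cm$client_id %in% state$clients$client_id)) {
        state <- session_connect(state, cm$client_id)$state
        state$clients$client_id[nrow(state$clients)] <- cm$client_id
      }
    }
  }
  for (cm in commands) state <- apply_command(state, cm)
  state
}

#' Read and write session logs as JSONL
#'
#' The persistent log is line-delimited JSON: a header line
#' (`schema`, `version`, client registry) followed by one command per
#' line. Numbers are serialised at full precision so a written log replays
#' to the exact same state.
#'
#' @param state A `collab_session`.
#' @param path Log file path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a list with `clients` and `commands`.
#' @export
write_session_log <- function(state, path) {
  header <- list(schema = "neurotrace-session", version = 1L,
                 clients = state$clients[, c("client_id", "username", "color")])
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             vapply(state$log, function(cm) {
               as.character(jsonlite::toJSON(serialize_command(cm),
                                             auto_unbox = TRUE, digits = NA))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

serialize_command <- function(cm) {
  p <- cm$payload
  if (!is.null(p$nodes)) p$nodes <- as.data.frame(p$nodes)
  list(seq = cm$seq, client_id = cm$client_id, kind = cm$kind,
       payload = p, wall_time = cm$wall_time)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop_parse("session log not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_log("empty session log")
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$schema, "neurotrace-session")) {
    stop_log("unrecognised session log schema")
  }
  commands <- lapply(lines[-1], function(ln) {
    cm <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    cm$seq <- as.integer(cm$seq)
    if (!is.null(cm$payload$nodes)) {
      cm$payload$nodes <- as.data.frame(cm$payload$nodes)
    }
    cm
  })
  list(clients = as.data.frame(header$clients), commands = commands)
}

#' Export the session annotation as an extended SWC tree
#'
#' Builds a `neuron_tree` (forest allowed) from the shared annotation,
#' carrying per-node `annotator` (client id) plus any attribute columns
#' such as `gen_method` as SWC label columns.
#'
#' @param state A `collab_session`.
#' @return A `neuron_tree`.
#' @export
session_export_tree <- function(state) {
  nd <- state$nodes
  out <- nd[, c("id", "type", "x", "y", "z", "radius", "parent"), drop = FALSE]
  out$annotator <- nd$client_id
  for (cc in setdiff(names(nd), c(names(out), "client_id"))) {
    out[[cc]] <- nd[[cc]]
  }
  neuron_tree(out, unit = "voxel", provenance = "collab session export")
}

#' Ephemeral avatar position update
#'
#' Avatar updates broadcast an annotator's current working location; they
#' are transient presence data and never enter the persistent log or the
#' session state.
#'
#' @param client_id Connected client id.
#' @param position Finite 3-D position (x, y, z).
#' @return An `avatar_update` object (for transport framing only).
#' @export
avatar_update <- function(client_id, position) {
  if (length(position) != 3 || any(!is.finite(position))) {
    stop_structural("avatar position must be a finite 3-vector")
  }
  structure(list(client_id = client_id, position = as.numeric(position)),
            class = "avatar_update")
}
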