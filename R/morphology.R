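# SWC reconstruction data model: parsing, validation, critical-point
# classification and decomposition into neurite segments.

SWC_CORE_COLS <- c("id", "type", "x", "y", "z", "radius", "parent")

#' Construct a neuron tree
#'
#' A `neuron_tree` holds one neuron reconstruction (or a forest of
#' disconnected arbors) as a node table in SWC column order. Coordinates are
#' voxel indices by default; a `unit` flag records whether they are voxel or
#' micrometer coordinates, and no conversion is ever applied silently.
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`. Additional columns are kept as per-node string
#'   labels (for example `gen_method` holding `"VR"`/`"nonVR"`, or an
#'   annotator id).
#' @param unit `"voxel"` or `"micrometer"`.
#' @param provenance Free-text metadata carried along with the tree.
#' @param validate Check structural invariants (unique ids, resolvable
#'   parents, acyclicity, non-negative radii).
#' @return An object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes, unit = c("voxel", "micrometer"),
                        provenance = "", validate = TRUE) {
  unit <- match.arg(unit)
  if (!is.data.frame(nodes)) {
    stop_structural("`nodes` must be a data frame")
  }
  missing_cols <- setdiff(SWC_CORE_COLS, names(nodes))
  if (length(missing_cols) > 0) {
    stop_structural("node table is missing columns: ",
                    paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  extra <- setdiff(names(nodes), SWC_CORE_COLS)
  for (cc in extra) nodes[[cc]] <- as.character(nodes[[cc]])
  tree <- structure(
    list(nodes = nodes[, c(SWC_CORE_COLS, extra)], unit = unit,
         provenance = provenance),
    class = "neuron_tree")
  if (validate) validate_neuron_tree(tree)
  tree
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, %d root(s), unit=%s, total length %.4g\n",
              nrow(x$nodes), length(tree_roots(x)), x$unit, total_length(x)))
  extra <- setdiff(names(x$nodes), SWC_CORE_COLS)
  if (length(extra) > 0) cat("  labels:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

# typed conditions ----------------------------------------------------------

stop_typed <- function(class, ...) {
  stop(structure(class = c(class, "neurotrace_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_parse <- function(...) stop_typed("neurotrace_parse_error", ...)
stop_structural <- function(...) stop_typed("neurotrace_structural_error", ...)
stop_degenerate <- function(...) stop_typed("neurotrace_degenerate_error", ...)

#' Validate the structural invariants of a neuron tree
#'
#' Checks id uniqueness, non-negative radii, finite coordinates, resolvable
#' parent references and acyclicity (every node reaches a root by following
#' parents). Multiple roots (a forest) are allowed here; operations that
#' need a single root check that themselves.
#'
#' @param tree A `neuron_tree`.
#' @return The tree, invisibly. Throws a structural error on violation.
#' @export
validate_neuron_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$id)) {
    dup <- nd$id[duplicated(nd$id)][1]
    stop_structural("duplicate node id: ", dup)
  }
  if (any(!is.finite(nd$x) | !is.finite(nd$y) | !is.finite(nd$z))) {
    stop_structural("non-finite node coordinates")
  }
  if (any(!is.finite(nd$radius) | nd$radius < 0)) {
    stop_structural("negative or non-finite radius")
  }
  dangling <- nd$parent != -1L & !(nd$parent %in% nd$id)
  if (any(dangling)) {
    stop_structural("dangling parent reference: node ", nd$id[dangling][1],
                    " refers to missing parent ", nd$parent[dangling][1])
  }
  if (any(nd$parent == nd$id)) {
    stop_structural("node ", nd$id[nd$parent == nd$id][1], " is its own parent")
  }
  # root reachability sweep: anything never marked sits on a cycle
  reached <- nd$parent == -1L
  if (!any(reached)) {
    if (nrow(nd) > 0) stop_structural("tree has no root (cycle)")
  }
  idx_of <- match(nd$parent, nd$id)
  repeat {
    newly <- !reached & reached[idx_of]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    reached <- reached | newly
  }
  if (!all(reached) && nrow(nd) > 0) {
    stop_structural("cycle detected involving node ", nd$id[!reached][1])
  }
  invisible(tree)
}

#' @rdname classify_nodes
#' @export
tree_roots <- function(tree) tree$nodes$id[tree$nodes$parent == -1L]

# children ids per node, in node-table order (deterministic traversal order)
tree_children <- function(tree) {
  nd <- tree$nodes
  split(nd$id[nd$parent != -1L],
        factor(nd$parent[nd$parent != -1L], levels = nd$id))
}

node_xyz <- function(tree, ids = NULL) {
  nd <- tree$nodes
  if (!is.null(ids)) nd <- nd[match(ids, nd$id), , drop = FALSE]
  cbind(x = nd$x, y = nd$y, z = nd$z)
}

#' Read an SWC reconstruction
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments). An extended dialect is supported: a header comment
#' `#columns id,type,x,y,z,radius,parent,<label>,...` declares names for
#' extra columns, which are preserved as string labels; undeclared extra
#' columns are kept under the names `extra1`, `extra2`, .... A header
#' `#units micrometer` (or `voxel`) sets the coordinate unit flag.
#'
#' @param source File path, or a character vector of SWC lines via
#'   `text = `.
#' @param text Optional character vector of lines (used instead of a file).
#' @return A validated [neuron_tree()]. Malformed lines raise a parse error
#'   naming the line number; duplicate ids, dangling parents and cycles
#'   raise structural errors.
#' @export
read_swc <- function(source = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(source)) stop_parse("SWC file not found: ", source)
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  unit <- "voxel"
  col_names <- NULL
  is_comment <- grepl("^\\s*#", lines)
  for (h in lines[is_comment]) {
    body <- sub("^\\s*#\\s*", "", h)
    if (grepl("^columns\\b", body, ignore.case = TRUE)) {
      decl <- sub("^columns\\s*:?\\s*", "", body, ignore.case = TRUE)
      col_names <- trimws(strsplit(decl, ",", fixed = TRUE)[[1]])
      if (length(col_names) < 7 ||
          !identical(tolower(col_names[1:7]), SWC_CORE_COLS)) {
        stop_parse("#columns header must start with: ",
                   paste(SWC_CORE_COLS, collapse = ","))
      }
    } else if (grepl("^units?\\b", body, ignore.case = TRUE)) {
      u <- tolower(trimws(sub("^units?\\s*:?\\s*", "", body, ignore.case = TRUE)))
      if (u %in% c("micrometer", "micron", "um")) unit <- "micrometer"
    }
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) == 0) {
    return(neuron_tree(empty_node_table(), unit = unit))
  }
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(fields)
  want <- if (!is.null(col_names)) length(col_names) else max(7L, max(nf))
  bad <- which(nf < 7L | nf > want)
  if (length(bad) > 0) {
    stop_parse("line ", data_idx[bad[1]], ": expected ",
               if (!is.null(col_names)) want else "at least 7",
               " fields, found ", nf[bad[1]])
  }
  ncol_seen <- max(nf)
  mat <- vapply(fields, function(f) c(f, rep(NA_character_, ncol_seen - length(f))),
                character(ncol_seen))
  mat <- matrix(mat, nrow = ncol_seen)  # columns are lines
  core <- mat[1:7, , drop = FALSE]
  num <- suppressWarnings(matrix(as.numeric(core), nrow = 7))
  bad_num <- which(colSums(is.na(num)) > 0)
  if (length(bad_num) > 0) {
    stop_parse("line ", data_idx[bad_num[1]], ": non-numeric field in '",
               trimws(lines[data_idx[bad_num[1]]]), "'")
  }
  nodes <- data.frame(id = as.integer(num[1, ]), type = as.integer(num[2, ]),
                      x = num[3, ], y = num[4, ], z = num[5, ],
                      radius = num[6, ], parent = as.integer(num[7, ]),
                      stringsAsFactors = FALSE)
  if (ncol_seen > 7) {
    extra_names <- if (!is.null(col_names)) col_names[-(1:7)] else
      paste0("extra", seq_len(ncol_seen - 7))
    for (k in seq_len(ncol_seen - 7)) {
      v <- mat[7 + k, ]
      v[v == "NA"] <- NA_character_
      nodes[[extra_names[k]]] <- v
    }
  }
  src <- if (is.null(text)) paste0("read from ", source) else "read from text"
  neuron_tree(nodes, unit = unit, provenance = src)
}

empty_node_table <- function() {
  data.frame(id = integer(), type = integer(), x = numeric(), y = numeric(),
             z = numeric(), radius = numeric(), parent = integer(),
             stringsAsFactors = FALSE)
}

#' Write an SWC reconstruction
#'
#' Serialises a tree back to SWC text. Numeric fields use the shortest
#' representation that round-trips doubles exactly, so
#' `read_swc(write_swc(tree))` reproduces the node table bit-for-bit and
#' repeated writes are byte-identical.
#'
#' @param tree A `neuron_tree`.
#' @param path Output file; when `NULL` the lines are returned.
#' @param include_labels Serialise extra label columns as additional SWC
#'   columns, declared in a `#columns` header.
#' @return `path` invisibly, or the character vector of lines when
#'   `path = NULL`.
#' @export
write_swc <- function(tree, path = NULL, include_labels = FALSE) {
  validate_neuron_tree(tree)
  nd <- tree$nodes
  extra <- setdiff(names(nd), SWC_CORE_COLS)
  use_extra <- include_labels && length(extra) > 0
  header <- c("# SWC reconstruction written by neurotrace",
              paste0("# units ", tree$unit))
  if (use_extra) {
    header <- c(header,
                paste0("#columns ", paste(c(SWC_CORE_COLS, extra), collapse = ",")))
  }
  fmt_num <- function(v) {
    s <- sprintf("%.17g", v)
    ok <- as.numeric(sprintf("%.15g", v)) == v
    s[ok] <- sprintf("%.15g", v[ok])
    s
  }
  body <- paste(nd$id, nd$type, fmt_num(nd$x), fmt_num(nd$y), fmt_num(nd$z),
                fmt_num(nd$radius), nd$parent)
  if (use_extra) {
    for (cc in extra) {
      val <- nd[[cc]]
      val[is.na(val)] <- "NA"
      body <- paste(body, val)
    }
  }
  out <- c(header, body)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Classify nodes as soma, branch, tip or internal
#'
#' Critical points of a reconstruction are the soma (the root node,
#' regardless of its SWC type code), branch points (two or more children)
#' and terminal tips (no children); every other node is `internal`. These
#' critical points bound the neurite segments used for quality profiling.
#'
#' @param tree A single-root `neuron_tree` (set `multi_root = TRUE` to
#'   classify each root of a forest as a soma).
#' @param multi_root Allow forests.
#' @return Named character vector (names are node ids) with values
#'   `"soma"`, `"branch"`, `"tip"`, `"internal"`.
#' @export
classify_nodes <- function(tree, multi_root = FALSE) {
  validate_neuron_tree(tree)
  nd <- tree$nodes
  roots <- tree_roots(tree)
  if (length(roots) != 1 && !multi_root) {
    stop_structural("tree has ", length(roots),
                    " roots; single-root required (use multi_root = TRUE)")
  }
  n_children <- tabulate(match(nd$parent, nd$id), nbins = nrow(nd))
  cls <- ifelse(n_children == 0, "tip",
                ifelse(n_children >= 2, "branch", "internal"))
  cls[nd$parent == -1L] <- "soma"
  stats::setNames(cls, nd$id)
}

is_critical <- function(cls) cls %in% c("soma", "branch", "tip")

#' Decompose a reconstruction into neurite segments
#'
#' Splits a neuron into segments, each bounded by a pair of critical points
#' (soma, branch points or tips) with only internal nodes in between. The
#' segments partition the tree's edges exactly once, so segment lengths sum
#' to the total tree length.
#'
#' @param tree A valid single-root `neuron_tree` with at least one node.
#' @return List of `neuron_segment` objects, each with fields `id`,
#'   `node_ids`, `nodes` (the node-table rows along the path), `length`, and
#'   `endpoint_kinds` (classification of first and last node).
#' @export
decompose_segments <- function(tree) {
  if (nrow(tree$nodes) == 0) stop_structural("cannot decompose an empty tree")
  cls <- classify_nodes(tree)
  nd <- tree$nodes
  children <- tree_children(tree)
  id_chr <- as.character(nd$id)
  segs <- list()
  for (i in seq_len(nrow(nd))) {
    u <- nd$id[i]
    if (!is_critical(cls[[id_chr[i]]])) next
    for (v in children[[id_chr[i]]]) {
      path <- c(u, v)
      cur <- v
      while (!is_critical(cls[[as.character(cur)]])) {
        cur <- children[[as.character(cur)]][1]
        path <- c(path, cur)
      }
      segs[[length(segs) + 1L]] <- path
    }
  }
  lapply(seq_along(segs), function(k) {
    path <- segs[[k]]
    rows <- nd[match(path, nd$id), , drop = FALSE]
    rownames(rows) <- NULL
    structure(list(
      id = k, node_ids = path, nodes = rows,
      length = polyline_length(rows),
      endpoint_kinds = unname(c(cls[[as.character(path[1])]],
                                cls[[as.character(path[length(path)])]]))),
      class = "neuron_segment")
  })
}

#' @export
print.neuron_segment <- function(x, ...) {
  cat(sprintf("<neuron_segment #%d> %d nodes, length %.4g, %s -> %s\n",
              x$id, length(x$node_ids), x$length,
              x$endpoint_kinds[1], x$endpoint_kinds[2]))
  invisible(x)
}

polyline_length <- function(rows) {
  if (nrow(rows) < 2) return(0)
  dx <- diff(rows$x); dy <- diff(rows$y); dz <- diff(rows$z)
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Total cable length of a reconstruction
#'
#' Sum of Euclidean parent-child edge lengths, in the tree's coordinate
#' unit. Zero for a single node.
#'
#' @param tree A `neuron_tree`.
#' @return Non-negative scalar.
#' @export
total_length <- function(tree) {
  nd <- tree$nodes
  has_par <- nd$parent != -1L
  if (!any(has_par)) return(0)
  pi <- match(nd$parent[has_par], nd$id)
  sum(sqrt((nd$x[has_par] - nd$x[pi])^2 +
           (nd$y[has_par] - nd$y[pi])^2 +
           (nd$z[has_par] - nd$z[pi])^2))
}
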