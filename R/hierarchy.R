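# Decision-hierarchy model: goal, nested objective tree, alternatives.

canon_label <- function(x) tolower(trimws(x))

# Normalize a node given as a bare string (leaf) or list(name, children)
norm_node <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    return(list(name = trimws(x), children = list()))
  }
  if (is.list(x) && !is.null(x$name)) {
    kids <- x$children
    if (is.null(kids)) kids <- list()
    if (is.character(kids)) kids <- as.list(kids)
    return(list(name = trimws(x$name), children = lapply(kids, norm_node)))
  }
  stop("objective node must be a string or a list with a 'name' field", call. = FALSE)
}

#' Construct a decision hierarchy
#'
#' A decision hierarchy is the backbone of an Analytic Hierarchy Process
#' (AHP) model: a single goal at the top, a tree of objectives (criteria)
#' below it, and an ordered set of decision alternatives compared under
#' every leaf objective.
#'
#' Objective nodes may be given as bare strings (leaves) or as lists with
#' `name` and `children` fields. Single-child nodes are allowed; the sole
#' child inherits its parent's full weight, since a one-item comparison
#' group needs no judgments. Labels are matched case-insensitively after
#' whitespace trimming and must be unique across the goal, all objectives,
#' and all alternatives.
#'
#' @param goal Character label of the decision goal.
#' @param objectives List of objective nodes (strings or
#'   `list(name =, children =)` trees).
#' @param alternatives Character vector of at least two alternative labels.
#' @param context Optional free-text description of the decision context.
#' @param validate If `TRUE` (default), error-level findings abort
#'   construction and warning-level findings are surfaced as R warnings.
#' @return An object of class `decision_hierarchy`.
#' @seealso [read_hierarchy()], [validate_hierarchy()], [comparison_groups()]
#' @examples
#' h <- decision_hierarchy(
#'   goal = "Choose treatment",
#'   objectives = list("Efficacy", "Safety"),
#'   alternatives = c("Drug A", "Drug B")
#' )
#' @export
decision_hierarchy <- function(goal, objectives, alternatives, context = "",
                               validate = TRUE) {
  if (!is.character(goal) || length(goal) != 1L) {
    stop("'goal' must be a single character label", call. = FALSE)
  }
  if (is.character(objectives)) objectives <- as.list(objectives)
  h <- structure(
    list(
      goal = trimws(goal),
      objectives = lapply(objectives, norm_node),
      alternatives = trimws(as.character(alternatives)),
      context = as.character(context)[1]
    ),
    class = "decision_hierarchy"
  )
  if (validate) {
    f <- validate_hierarchy(h)
    errs <- f[f$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0L) {
      stop("invalid decision hierarchy:\n",
           paste0("  [", errs$path, "] ", errs$message, collapse = "\n"),
           call. = FALSE)
    }
    warns <- f[f$severity == "warning", , drop = FALSE]
    for (i in seq_len(nrow(warns))) {
      warning(sprintf("[%s] %s", warns$path[i], warns$message[i]), call. = FALSE)
    }
  }
  h
}

# Flat preorder table of objective nodes: label, parent, depth, n_children
hierarchy_nodes <- function(h) {
  rows <- list()
  walk <- function(node, parent, depth, path) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = node$name, parent = parent, depth = depth,
      n_children = length(node$children), path = path,
      stringsAsFactors = FALSE
    )
    for (ch in node$children) {
      walk(ch, node$name, depth + 1L, paste0(path, "/", ch$name))
    }
  }
  for (ob in h$objectives) walk(ob, h$goal, 1L, paste0("objectives/", ob$name))
  if (length(rows) == 0L) {
    return(data.frame(label = character(), parent = character(),
                      depth = integer(), n_children = integer(),
                      path = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

leaf_objectives <- function(h) {
  nd <- hierarchy_nodes(h)
  nd$label[nd$n_children == 0L]
}

children_of <- function(h, label) {
  if (canon_label(label) == canon_label(h$goal)) {
    return(vapply(h$objectives, function(n) n$name, character(1)))
  }
  found <- NULL
  walk <- function(node) {
    if (canon_label(node$name) == canon_label(label)) {
      found <<- vapply(node$children, function(n) n$name, character(1))
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  for (ob in h$objectives) walk(ob)
  if (is.null(found)) stop(sprintf("objective '%s' not found in hierarchy", label),
                           call. = FALSE)
  found
}

new_finding <- function(severity, path, message) {
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a decision hierarchy
#'
#' Checks structural invariants and returns findings rather than raising:
#' unique labels (case-insensitive), at least two alternatives, non-empty
#' labels. A node with more than seven children yields a warning-severity
#' finding, reflecting the elicitation-burden convention of keeping seven
#' or fewer items per comparison level; larger groups remain legal.
#'
#' @param h A `decision_hierarchy` (validated or not; pass
#'   `validate = FALSE` to the constructor to inspect a broken model).
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `path`, and `message`; zero rows when all invariants hold.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "decision_hierarchy"))
  f <- new_finding(character(), character(), character())
  nd <- hierarchy_nodes(h)

  if (!nzchar(trimws(h$goal))) {
    f <- rbind(f, new_finding("error", "goal", "goal label is empty"))
  }
  if (any(!nzchar(trimws(nd$label)))) {
    f <- rbind(f, new_finding("error", "objectives", "empty objective label"))
  }
  if (length(h$alternatives) < 2L) {
    f <- rbind(f, new_finding("error", "alternatives",
                              "at least 2 alternatives are required"))
  }
  if (any(!nzchar(trimws(h$alternatives)))) {
    f <- rbind(f, new_finding("error", "alternatives", "empty alternative label"))
  }

  all_labels <- c(h$goal, nd$label, h$alternatives)
  all_paths <- c("goal", nd$path,
                 paste0("alternatives/", h$alternatives))
  cl <- canon_label(all_labels)
  dup <- duplicated(cl) | duplicated(cl, fromLast = TRUE)
  if (any(dup)) {
    for (lab in unique(cl[dup])) {
      where <- all_paths[cl == lab]
      f <- rbind(f, new_finding(
        "error", where[2],
        sprintf("duplicate label '%s' (also at %s)", all_labels[cl == lab][1],
                where[1])
      ))
    }
  }

  big <- nd[nd$n_children > 7L, , drop = FALSE]
  ngoal <- length(h$objectives)
  if (ngoal > 7L) {
    f <- rbind(f, new_finding("warning", "goal",
                              sprintf("goal has %d children (> 7)", ngoal)))
  }
  for (i in seq_len(nrow(big))) {
    f <- rbind(f, new_finding(
      "warning", big$path[i],
      sprintf("node '%s' has %d children (> 7); consider regrouping",
              big$label[i], big$n_children[i])
    ))
  }
  f
}

#' Enumerate the comparison groups of a hierarchy
#'
#' Every non-leaf node (including the goal) defines one objective group —
#' its children are compared pairwise for importance. Every leaf objective
#' defines one alternative group — the alternatives are compared pairwise
#' for how well they meet that objective. Alternative groups are listed
#' first, mirroring elicitation designs in which treatment comparisons are
#' collected before outcome weighting. A single-item group requires no
#' judgments: its sole item receives local weight 1.
#'
#' @param h A validated `decision_hierarchy`.
#' @return A list of `comparison_group` objects, each with fields
#'   `parent`, `items`, `kind` (`"alternative"`/`"objective"`), `n_items`,
#'   `n_judgments` (`n(n-1)/2`), and `requires_judgments`.
#' @export
comparison_groups <- function(h) {
  stopifnot(inherits(h, "decision_hierarchy"))
  nd <- hierarchy_nodes(h)
  grp <- function(parent, items, kind) {
    n <- length(items)
    structure(list(parent = parent, items = items, kind = kind,
                   n_items = n, n_judgments = n * (n - 1L) / 2L,
                   requires_judgments = n > 1L),
              class = "comparison_group")
  }
  alt_groups <- lapply(nd$label[nd$n_children == 0L], function(leaf) {
    grp(leaf, h$alternatives, "alternative")
  })
  nonleaf <- c(h$goal, nd$label[nd$n_children > 0L])
  obj_groups <- lapply(nonleaf, function(p) grp(p, children_of(h, p), "objective"))
  c(alt_groups, obj_groups)
}

#' @export
print.comparison_group <- function(x, ...) {
  tag <- if (x$requires_judgments) {
    sprintf("%d pairwise judgments", x$n_judgments)
  } else {
    "no judgments required, local weight 1"
  }
  cat(sprintf("<comparison group> %s [%s]: %s (%s)\n",
              x$parent, x$kind, paste(x$items, collapse = ", "), tag))
  invisible(x)
}

#' @export
print.decision_hierarchy <- function(x, ...) {
  nd <- hierarchy_nodes(x)
  cat("<decision hierarchy>\n")
  cat("Goal:", x$goal, "\n")
  if (nzchar(x$context)) cat("Context:", x$context, "\n")
  for (i in seq_len(nrow(nd))) {
    cat(strrep("  ", nd$depth[i]), "- ", nd$label[i],
        if (nd$n_children[i] == 0L) " [leaf]" else "", "\n", sep = "")
  }
  cat("Alternatives:", paste(x$alternatives, collapse = ", "), "\n")
  invisible(x)
}

as_hierarchy_list <- function(h) {
  unnode <- function(node) {
    if (length(node$children) == 0L) return(list(name = node$name))
    list(name = node$name, children = lapply(node$children, unnode))
  }
  list(goal = h$goal,
       objectives = lapply(h$objectives, unnode),
       alternatives = as.list(h$alternatives),
       context = h$context)
}

#' Read a decision hierarchy from a YAML or JSON model file
#'
#' The model file schema is `{goal, objectives, alternatives, context}`
#' where `objectives` is a list of nodes, each a string (leaf) or a map
#' with `name` and `children`. A machine-readable JSON Schema for this
#' format ships with the package at
#' `system.file("extdata", "hierarchy-schema.json", package = "ahpbr")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` model file.
#' @return A validated `decision_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("goal", "objectives", "alternatives")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("model file schema violation at '%s': field missing", field),
           call. = FALSE)
    }
  }
  alts <- unlist(doc$alternatives, use.names = FALSE)
  if (!is.character(alts)) {
    stop("model file schema violation at 'alternatives': expected strings",
         call. = FALSE)
  }
  decision_hierarchy(goal = doc$goal, objectives = doc$objectives,
                     alternatives = alts,
                     context = if (is.null(doc$context)) "" else doc$context)
}

#' Write a decision hierarchy to a YAML or JSON model file
#'
#' @param h A `decision_hierarchy`.
#' @param path Output path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "decision_hierarchy"))
  doc <- as_hierarchy_list(h)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
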