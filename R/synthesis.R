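# Hierarchical synthesis: local priorities -> global objective weights and
# overall alternative scores (ideal or distributive mode), plus the
# relative-difference significance table.

# Look up the local priority vector for a comparison group, reordered to
# `items`; single-item groups default to weight 1. Vectors are
# renormalized to sum 1 so downstream conservation holds to machine
# precision.
get_local <- function(locals, parent, items, context = "group") {
  if (length(items) == 1L) {
    return(stats::setNames(1, items))
  }
  hit <- match(canon_label(parent), canon_label(names(locals)))
  if (is.na(hit)) {
    stop(sprintf("missing local priorities for %s '%s'", context, parent),
         call. = FALSE)
  }
  w <- locals[[hit]]
  v <- as.numeric(w)
  if (!is.null(names(w)) && any(nzchar(names(w)))) {
    ord <- match(canon_label(items), canon_label(names(w)))
    if (anyNA(ord)) {
      stop(sprintf("local priorities for '%s' do not cover item '%s'",
                   parent, items[which(is.na(ord))[1]]), call. = FALSE)
    }
    v <- v[ord]
  } else if (length(v) != length(items)) {
    stop(sprintf("local priorities for '%s' have wrong length", parent),
         call. = FALSE)
  }
  if (anyNA(v) || any(v < 0)) {
    stop(sprintf("local priorities for '%s' must be nonnegative", parent),
         call. = FALSE)
  }
  s <- sum(v)
  if (s <= 0) stop(sprintf("local priorities for '%s' sum to zero", parent),
                   call. = FALSE)
  if (s != 1) v <- v / s
  stats::setNames(v, items)
}

#' Propagate local weights into global objective priorities
#'
#' The goal carries a global priority of 100%; each child's global
#' priority is its parent's global times its local weight within the
#' sibling group, so every sibling partition's globals sum to the
#' parent's global. A single child inherits its parent's full weight.
#'
#' @param h A `decision_hierarchy`.
#' @param locals Named list mapping each objective-group parent label to
#'   its local priority vector (a [derive_all()] result is accepted too).
#'   Alternative-group entries are ignored here.
#' @return Named numeric vector of global priorities in percent, one
#'   entry per objective node, in hierarchy preorder.
#' @examples
#' h <- decision_hierarchy("g", list(
#'   list(name = "A", children = c("A1", "A2")), "B"), c("x", "y"))
#' global_priorities(h, list(g = c(A = 0.5, B = 0.5), A = c(A1 = 0.5, A2 = 0.5)))
#' @export
global_priorities <- function(h, locals) {
  stopifnot(inherits(h, "decision_hierarchy"))
  locals <- local_priorities(locals)
  glob <- numeric(0)
  descend <- function(parent, parent_global) {
    kids <- children_of(h, parent)
    if (length(kids) == 0L) return(invisible())
    loc <- get_local(locals, parent, kids, "objective group")
    for (k in seq_along(kids)) {
      glob[kids[k]] <<- parent_global * loc[k]
      descend(kids[k], glob[[kids[k]]])
    }
  }
  descend(h$goal, 100)
  # report in preorder
  nd <- hierarchy_nodes(h)
  glob[nd$label]
}

#' Synthesize overall alternative scores
#'
#' Combines the leaf objectives' global weights with each leaf's local
#' alternative priorities.
#'
#' In **distributive** mode the sum-normalized local priorities are
#' weighted directly: `score_k = sum_leaf g_leaf * p_leaf,k`, so scores
#' are proportional shares of the decision.
#'
#' In **ideal** mode each leaf's alternative vector is first divided by
#' its maximum (the best alternative on each objective gets 1), then
#' weighted and summed; the final vector is renormalized to sum 1 for
#' reporting. Ideal mode targets the single best alternative and
#' preserves the relative ranks of existing alternatives when an
#' alternative that is nowhere best is added or removed, at the cost of
#' scores no longer being proportional shares.
#'
#' @param h A `decision_hierarchy`.
#' @param locals Named list of local priority vectors covering every
#'   objective group and every leaf (alternative) group; a
#'   [derive_all()] result is accepted.
#' @param mode `"ideal"` or `"distributive"`.
#' @return An object of class `synthesis_result`: list with `mode`,
#'   `objective_globals` (percent), `alternative_scores` (normalized,
#'   named), `raw_scores` (pre-normalization), `leaf_locals`, and
#'   `ranking` (data frame with ties sharing the better rank).
#' @export
score_alternatives <- function(h, locals, mode = c("ideal", "distributive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(h, "decision_hierarchy"))
  locals <- local_priorities(locals)
  globals_pct <- global_priorities(h, locals)
  leaves <- leaf_objectives(h)
  g <- globals_pct[leaves] / 100
  alts <- h$alternatives
  leaf_locals <- list()
  raw <- stats::setNames(rep(0, length(alts)), alts)
  for (leaf in leaves) {
    p <- get_local(locals, leaf, alts, "leaf alternative group")
    leaf_locals[[leaf]] <- p
    v <- if (mode == "ideal") p / max(p) else p
    raw <- raw + g[[leaf]] * v
  }
  scores <- raw / sum(raw)
  ord <- order(-scores, match(alts, alts))
  ranking <- data.frame(
    alternative = alts[ord],
    score = as.numeric(scores[ord]),
    rank = as.integer(unname(rank(-scores, ties.method = "min")[ord])),
    stringsAsFactors = FALSE
  )
  structure(list(mode = mode, objective_globals = globals_pct,
                 alternative_scores = scores, raw_scores = raw,
                 leaf_locals = leaf_locals, ranking = ranking),
            class = "synthesis_result")
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis result> mode = %s\n", x$mode))
  cat("Global objective priorities (%):\n")
  print(round(x$objective_globals, 2))
  cat("Overall alternative scores:\n")
  df <- x$ranking
  df$score <- round(df$score, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Relative-difference table of priority scores
#'
#' Pairwise ratios of priority scores, always expressed as the larger
#' score over the smaller, with a ratio of at least `threshold`
#' (default 1.1, i.e. a 10% multiplicative difference) treated as a
#' significant difference per standard AHP practice. For display the
#' ratio is placed in the row of the larger-scoring item (ties resolved
#' by item order) and rounded to 2 decimals; internal values are never
#' rounded.
#'
#' @param scores Named positive numeric vector of priority scores.
#' @param threshold Significance ratio; default 1.1.
#' @return An object of class `relative_difference_table`: list with
#'   `items`, `ratios` (full matrix `r[a, b] = score_a / score_b`),
#'   `significant` (symmetric logical mask on the larger/smaller ratio),
#'   `display` (character matrix, blank below the placement rule), and
#'   `threshold`.
#' @examples
#' rd <- relative_differences(c(hypo = 14.01, fracture = 2.57))
#' rd$ratios["hypo", "fracture"]  # 5.45...
#' @export
relative_differences <- function(scores, threshold = 1.1) {
  s <- as.numeric(scores)
  items <- names(scores)
  if (is.null(items)) items <- paste0("item", seq_along(s))
  if (anyNA(s) || any(s <= 0)) {
    stop("relative differences require strictly positive scores", call. = FALSE)
  }
  n <- length(s)
  r <- outer(s, s, "/")
  dimnames(r) <- list(items, items)
  big <- pmax(r, t(r))
  sig <- big >= threshold
  diag(sig) <- FALSE
  disp <- matrix("", n, n, dimnames = list(items, items))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      show <- (i == j) || s[i] > s[j] || (s[i] == s[j] && i < j)
      if (show) {
        disp[i, j] <- sprintf("%.2f", r[i, j])
        if (i != j && sig[i, j]) disp[i, j] <- paste0(disp[i, j], "*")
      }
    }
  }
  structure(list(items = items, ratios = r, significant = sig,
                 display = disp, threshold = threshold),
            class = "relative_difference_table")
}

#' Look up the larger-over-smaller ratio between two items
#'
#' @param rd A `relative_difference_table`.
#' @param a,b Item labels (matched case-insensitively).
#' @return The ratio of the larger score to the smaller, as a number.
#' @export
ratio_between <- function(rd, a, b) {
  stopifnot(inherits(rd, "relative_difference_table"))
  ia <- match(canon_label(a), canon_label(rd$items))
  ib <- match(canon_label(b), canon_label(rd$items))
  if (is.na(ia) || is.na(ib)) stop("unknown item label", call. = FALSE)
  max(rd$ratios[ia, ib], rd$ratios[ib, ia])
}

#' @export
print.relative_difference_table <- function(x, ...) {
  cat(sprintf("<relative differences> (* marks ratio >= %.2f)\n", x$threshold))
  print(as.data.frame(x$display), right = TRUE)
  invisible(x)
}
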