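# Group aggregation: geometric mean of individual experts' priorities
# (AIP — aggregation of individual priorities) and disagreement spread.

coerce_weight_list <- function(vectors) {
  if (inherits(vectors, "priority_vector") || (is.numeric(vectors) &&
                                               !is.list(vectors))) {
    vectors <- list(vectors)
  }
  lapply(vectors, function(v) stats::setNames(as.numeric(v), names(v)))
}

align_items <- function(vectors) {
  ref <- names(vectors[[1]])
  if (is.null(ref)) {
    len <- unique(vapply(vectors, length, integer(1)))
    if (length(len) != 1L) stop("priority vectors differ in length", call. = FALSE)
    return(vectors)
  }
  lapply(vectors, function(v) {
    ord <- match(canon_label(ref), canon_label(names(v)))
    if (anyNA(ord) || length(v) != length(ref)) {
      stop("priority vectors are not over identical items", call. = FALSE)
    }
    stats::setNames(as.numeric(v)[ord], ref)
  })
}

#' Aggregate expert priorities by the geometric mean
#'
#' Element-wise geometric mean of the experts' priority vectors,
#' renormalized to sum 1 — the standard AIP group rule. In the log domain
#' the unnormalized group weight is exactly the mean of the individual
#' log weights, which makes the rule invariant to any per-expert positive
#' rescaling applied before normalization.
#'
#' @param vectors List of priority vectors (named numerics over identical
#'   items, any order). All weights must be strictly positive: eigenvector
#'   priorities of positive reciprocal matrices always are, so a zero
#'   signals an upstream problem rather than a judgment.
#' @return A normalized `priority_vector`; the pre-normalization
#'   geometric means are attached as attribute `"unnormalized"`.
#' @examples
#' aggregate_priorities(list(c(a = .8, b = .2), c(a = .2, b = .8)))  # (.5, .5)
#' @export
aggregate_priorities <- function(vectors) {
  vectors <- coerce_weight_list(vectors)
  if (length(vectors) < 1L) stop("need at least one priority vector", call. = FALSE)
  vectors <- align_items(vectors)
  W <- do.call(rbind, vectors)
  if (anyNA(W) || any(W <= 0)) {
    stop("geometric-mean aggregation requires strictly positive weights",
         call. = FALSE)
  }
  gm <- exp(colMeans(log(W)))
  out <- priority_vector(gm / sum(gm), items = colnames(W))
  attr(out, "unnormalized") <- stats::setNames(gm, colnames(W))
  out
}

#' Between-expert spread of priorities
#'
#' Per-item sample standard deviation (n-1 denominator) of the experts'
#' weights, expressed in percentage points — the conventional summary of
#' agreement or disagreement across a small expert panel.
#'
#' @param vectors List of at least two priority vectors over identical
#'   items.
#' @return Named numeric vector of standard deviations (% points).
#' @export
priority_dispersion <- function(vectors) {
  vectors <- coerce_weight_list(vectors)
  if (length(vectors) < 2L) {
    stop("dispersion requires at least two experts", call. = FALSE)
  }
  vectors <- align_items(vectors)
  W <- do.call(rbind, vectors) * 100
  apply(W, 2, stats::sd)
}

#' Group synthesis from a panel of experts
#'
#' Aggregates the panel at the local-priority level (AIP: the geometric
#' mean of each expert's local priority vector, per comparison group),
#' then synthesizes once on the group locals. Alternatively
#' (`aggregate = "scores"`) each expert is synthesized individually and
#' the final alternative scores are geometric-mean aggregated — a
#' sensitivity check on the aggregation level; objective globals are
#' still reported from the aggregated locals.
#'
#' @param h A `decision_hierarchy`.
#' @param experts List with one element per expert: either a
#'   [derive_all()] result or a plain named list of local priority
#'   vectors covering all groups.
#' @param mode Synthesis mode, `"ideal"` or `"distributive"`.
#' @param aggregate `"locals"` (default, AIP on local priorities) or
#'   `"scores"` (aggregate final synthesized scores).
#' @return An object of class `group_result`: list with `synthesis` (a
#'   `synthesis_result`), `group_locals`, `dispersion` (named list of
#'   per-group SD vectors in % points; `NULL` for a single expert), and
#'   `n_experts`.
#' @export
group_synthesize <- function(h, experts, mode = c("ideal", "distributive"),
                             aggregate = c("locals", "scores")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(h, "decision_hierarchy"), length(experts) >= 1L)
  experts <- lapply(experts, local_priorities)

  group_names <- names(experts[[1]])
  group_locals <- list()
  dispersion <- if (length(experts) >= 2L) list() else NULL
  for (p in group_names) {
    vecs <- lapply(experts, function(e) {
      hit <- match(canon_label(p), canon_label(names(e)))
      if (is.na(hit)) {
        stop(sprintf("an expert's locals are missing group '%s'", p),
             call. = FALSE)
      }
      e[[hit]]
    })
    if (length(vecs[[1]]) == 1L) {
      group_locals[[p]] <- vecs[[1]]
      if (!is.null(dispersion)) {
        dispersion[[p]] <- stats::setNames(0, names(vecs[[1]]))
      }
      next
    }
    group_locals[[p]] <- aggregate_priorities(vecs)
    if (!is.null(dispersion)) dispersion[[p]] <- priority_dispersion(vecs)
  }

  synthesis <- score_alternatives(h, group_locals, mode)
  if (aggregate == "scores") {
    per <- lapply(experts, function(e) {
      score_alternatives(h, e, mode)$alternative_scores
    })
    grp_scores <- aggregate_priorities(per)
    synthesis$alternative_scores <- stats::setNames(as.numeric(grp_scores),
                                                    names(grp_scores))
    ord <- order(-synthesis$alternative_scores,
                 seq_along(synthesis$alternative_scores))
    synthesis$ranking <- data.frame(
      alternative = names(synthesis$alternative_scores)[ord],
      score = as.numeric(synthesis$alternative_scores[ord]),
      rank = as.integer(unname(rank(-synthesis$alternative_scores,
                                    ties.method = "min")[ord])),
      stringsAsFactors = FALSE
    )
  }
  structure(list(synthesis = synthesis, group_locals = group_locals,
                 dispersion = dispersion, n_experts = length(experts),
                 aggregate = aggregate),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group result> %d expert(s), aggregated on %s\n",
              x$n_experts, x$aggregate))
  print(x$synthesis)
  invisible(x)
}
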