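# Weight-scenario sensitivity analysis and synthesis-mode comparison.

#' Re-synthesize under forced objective weights
#'
#' Implements weight-override scenarios such as "set maximizing benefits
#' to 100%": the overridden objectives' local weights within their
#' sibling group are replaced by the forced shares, the remaining
#' siblings are scaled proportionally to fill the remainder, and the
#' model is fully re-synthesized. The internal weights of any subtree
#' below an overridden node are left untouched — the scenario varies
#' only the targeted split.
#'
#' A scenario whose forced shares equal the current weights is an exact
#' no-op: the proportional rescaling factor is snapped to 1 when it is
#' within 1e-12, so the baseline is reproduced bit-identically.
#'
#' @param h A `decision_hierarchy`.
#' @param locals Named list of local priority vectors covering all
#'   groups (a [derive_all()] result is accepted).
#' @param overrides Named numeric vector: objective label -> forced local
#'   share in `[0, 1]`. Objectives sharing a sibling group may be
#'   overridden together (their shares must leave a nonnegative
#'   remainder).
#' @param mode Synthesis mode for the re-synthesis.
#' @return A `synthesis_result` with a `"scenario"` attribute recording
#'   the overrides and mode.
#' @examples
#' # force one of two equal top-level objectives to 100%
#' h <- decision_hierarchy("g", list("A", "B"), c("x", "y"))
#' loc <- list(g = c(A = .5, B = .5), A = c(x = .7, y = .3),
#'             B = c(x = .2, y = .8))
#' apply_scenario(h, loc, c(A = 1), mode = "distributive")
#' @export
apply_scenario <- function(h, locals, overrides,
                           mode = c("ideal", "distributive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(h, "decision_hierarchy"))
  locals <- local_priorities(locals)
  if (length(overrides) == 0L || is.null(names(overrides))) {
    stop("'overrides' must be a named numeric vector of objective shares",
         call. = FALSE)
  }
  if (anyNA(overrides) || any(overrides < 0) || any(overrides > 1)) {
    stop("override shares must lie within [0, 1]", call. = FALSE)
  }

  nd <- hierarchy_nodes(h)
  parent_of <- stats::setNames(nd$parent, canon_label(nd$label))
  by_group <- split(seq_along(overrides),
                    vapply(names(overrides), function(lab) {
                      p <- unname(parent_of[canon_label(lab)])
                      if (is.na(p)) {
                        stop(sprintf("override target '%s' is not an objective", lab),
                             call. = FALSE)
                      }
                      p
                    }, character(1)))

  new_locals <- locals
  for (parent in names(by_group)) {
    idx <- by_group[[parent]]
    siblings <- children_of(h, parent)
    if (length(siblings) == 1L) {
      stop(sprintf(
        "cannot override '%s': its group under '%s' has a single member with fixed weight 1",
        names(overrides)[idx[1]], parent), call. = FALSE)
    }
    cur <- get_local(locals, parent, siblings, "objective group")
    pos <- match(canon_label(names(overrides)[idx]), canon_label(siblings))
    forced <- as.numeric(overrides[idx])
    total <- sum(forced)
    if (total > 1 + 1e-12) {
      stop(sprintf("override shares under '%s' exceed 1 (%.4f)", parent, total),
           call. = FALSE)
    }
    others <- setdiff(seq_along(siblings), pos)
    w <- cur
    w[pos] <- forced
    if (length(others) > 0L) {
      so <- sum(cur[others])
      if (so <= 0) {
        if (abs(1 - total) > 1e-12) {
          stop(sprintf("cannot redistribute remainder under '%s': non-overridden siblings carry zero weight",
                       parent), call. = FALSE)
        }
        w[others] <- 0
      } else {
        s <- (1 - total) / so
        if (abs(s - 1) < 1e-12) s <- 1  # exact no-op guard
        w[others] <- cur[others] * s
      }
    } else if (abs(total - 1) > 1e-9) {
      stop(sprintf("overrides cover the whole group under '%s' but sum to %.6f, not 1",
                   parent, total), call. = FALSE)
    }
    key <- names(locals)[match(canon_label(parent), canon_label(names(locals)))]
    if (is.na(key)) key <- parent
    new_locals[[key]] <- w
  }

  res <- score_alternatives(h, new_locals, mode)
  attr(res, "scenario") <- list(overrides = overrides, mode = mode)
  res
}

#' Compare ideal and distributive synthesis on identical inputs
#'
#' Runs both synthesis modes from the same local priorities and reports
#' per-alternative ranks under each, the two score vectors, and whether
#' the rank orders agree.
#'
#' @param h A `decision_hierarchy`.
#' @param locals Named list of local priority vectors covering all
#'   groups.
#' @return An object of class `mode_comparison`: list with `ranks` (data
#'   frame: alternative, rank_ideal, rank_distributive), `scores_ideal`,
#'   `scores_distributive`, and `agreement` (logical).
#' @export
compare_modes <- function(h, locals) {
  ideal <- score_alternatives(h, locals, "ideal")
  distr <- score_alternatives(h, locals, "distributive")
  alts <- h$alternatives
  r_i <- rank(-ideal$alternative_scores, ties.method = "min")
  r_d <- rank(-distr$alternative_scores, ties.method = "min")
  structure(list(
    ranks = data.frame(alternative = alts,
                       rank_ideal = as.integer(r_i),
                       rank_distributive = as.integer(r_d),
                       stringsAsFactors = FALSE),
    scores_ideal = ideal$alternative_scores,
    scores_distributive = distr$alternative_scores,
    agreement = all(r_i == r_d)
  ), class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf("<mode comparison> rankings %s\n",
              if (x$agreement) "agree" else "DISAGREE"))
  print(x$ranks, row.names = FALSE)
  invisible(x)
}
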