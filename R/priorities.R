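# Principal-eigenvector priority derivation and consistency diagnostics.

# Saaty random-index table: expected consistency index of random reciprocal
# matrices of order n. Values beyond n = 10 change little; the n = 10 value
# is reused there.
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Saaty random index
#'
#' Expected consistency index of random positive reciprocal matrices of
#' order `n`; the denominator of the consistency ratio. Tabulated for
#' `n <= 10`; the `n = 10` value is reused for larger matrices.
#'
#' @param n Matrix order.
#' @return The random index (0 for `n <= 2`).
#' @export
random_index <- function(n) {
  stopifnot(n >= 1L)
  if (n <= 10L) SAATY_RI[n] else SAATY_RI[10L]
}

#' Construct a priority vector
#'
#' @param weights Nonnegative numeric weights; names become item labels.
#' @param items Optional labels overriding `names(weights)`.
#' @param convention `"normalized"` (weights sum to 1) or `"idealized"`
#'   (maximum weight equals 1).
#' @return A named numeric vector of class `priority_vector` with a
#'   `convention` attribute.
#' @export
priority_vector <- function(weights, items = names(weights),
                            convention = c("normalized", "idealized")) {
  convention <- match.arg(convention)
  w <- as.numeric(weights)
  if (anyNA(w) || any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (convention == "normalized" && abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("normalized priority vector must sum to 1 (got %.12g)", sum(w)),
         call. = FALSE)
  }
  if (convention == "idealized" && abs(max(w) - 1) > 1e-9) {
    stop("idealized priority vector must have maximum 1", call. = FALSE)
  }
  if (is.null(items)) items <- paste0("item", seq_along(w))
  structure(stats::setNames(w, items), convention = convention,
            class = c("priority_vector", "numeric"))
}

#' @export
print.priority_vector <- function(x, digits = 4, ...) {
  cat(sprintf("<priority vector> (%s)\n", attr(x, "convention")))
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Derive local priorities by power iteration
#'
#' Computes the normalized principal right eigenvector of a positive
#' reciprocal judgment matrix by repeated matrix multiplication with
#' normalization (the classical "matrix multiplication method"), starting
#' from the uniform vector. The dominant eigenvalue is estimated as the
#' mean Rayleigh-type ratio `mean((M w)_i / w_i)`, which is numerically
#' more stable than any single component.
#'
#' @param M A `pairwise_matrix` (or plain positive square matrix).
#' @param tol Convergence tolerance on the max-abs change between
#'   successive normalized iterates. Default `1e-12`.
#' @param max_iter Iteration cap; non-convergence raises an error
#'   reporting the last residual.
#' @return A list with `priorities` (a normalized `priority_vector`),
#'   `lambda_max`, `iterations`, and `residual`.
#' @examples
#' M <- matrix_from_weights(c(0.5, 0.25, 0.25))
#' derive_priorities(M)$lambda_max  # 3: perfectly consistent
#' @export
derive_priorities <- function(M, tol = 1e-12, max_iter = 10000L) {
  m <- as.matrix(unclass(M))
  f <- validate_matrix(M)
  if (nrow(f) > 0L) {
    stop("refusing to prioritize an invalid matrix: ", f$message[1], call. = FALSE)
  }
  n <- nrow(m)
  items <- rownames(m)
  if (is.null(items)) items <- paste0("item", seq_len(n))
  if (n == 1L) {
    return(list(priorities = priority_vector(1, items), lambda_max = 1,
                iterations = 0L, residual = 0))
  }
  w <- rep(1 / n, n)
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v <- as.numeric(m %*% w)
    v <- v / sum(v)
    resid <- max(abs(v - w))
    w <- v
    if (resid <= tol) break
  }
  if (resid > tol) {
    stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
                 max_iter, resid), call. = FALSE)
  }
  lambda <- mean(as.numeric(m %*% w) / w)
  list(priorities = priority_vector(w, items), lambda_max = lambda,
       iterations = it, residual = resid)
}

#' Consistency diagnostics for a judgment matrix
#'
#' The consistency index `CI = (lambda_max - n) / (n - 1)` is 0 for a
#' perfectly consistent matrix and grows with intransitivity
#' (`lambda_max >= n` always, with equality iff consistent). The
#' consistency ratio `CR = CI / RI(n)` rescales by the Saaty random index;
#' judgments are flagged inconsistent when `CR` exceeds 0.15. Both CI and
#' CR are reported, since acceptability conventions in the literature are
#' variously phrased against either (cutoffs of 0.10-0.15 are typical).
#' Matrices of order 2 or less are consistent by construction
#' (`lambda_max = n`, `CI = 0`).
#'
#' @param M A `pairwise_matrix`.
#' @param threshold Verdict cutoff on CR; default 0.15.
#' @inheritParams derive_priorities
#' @return An object of class `consistency_report`: list with `n`,
#'   `lambda_max`, `ci`, `ri`, `cr`, `inconsistent`.
#' @export
consistency_report <- function(M, threshold = 0.15, tol = 1e-12,
                               max_iter = 10000L) {
  d <- derive_priorities(M, tol = tol, max_iter = max_iter)
  n <- length(d$priorities)
  ci <- if (n >= 2L) (d$lambda_max - n) / (n - 1) else 0
  if (n <= 2L) ci <- 0
  ri <- random_index(n)
  cr <- if (n >= 3L) ci / ri else 0
  structure(list(n = n, lambda_max = d$lambda_max, ci = ci, ri = ri, cr = cr,
                 inconsistent = cr > threshold, threshold = threshold),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency report> n = %d, lambda_max = %.6f, CI = %.4f, RI = %.2f, CR = %.4f -> %s\n",
    x$n, x$lambda_max, x$ci, x$ri, x$cr,
    if (x$inconsistent) sprintf("INCONSISTENT (CR > %.2f)", x$threshold)
    else "consistent"
  ))
  invisible(x)
}

#' Derive priorities and diagnostics for every comparison group
#'
#' Runs [derive_priorities()] and [consistency_report()] on each
#' multi-item comparison group of the hierarchy using one expert's
#' judgment set. Single-item groups (a node with one child) need no
#' judgments: the sole item receives local weight 1 with `lambda_max = 1`
#' and `CI = 0`.
#'
#' @param js A `judgment_set` covering every multi-item group of `h`.
#' @param h The `decision_hierarchy`.
#' @inheritParams derive_priorities
#' @return A named list (one entry per comparison group parent), each
#'   element a list with `priorities`, `report`, and `kind`.
#' @export
derive_all <- function(js, h, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(js, "judgment_set"), inherits(h, "decision_hierarchy"))
  groups <- comparison_groups(h)
  jmap <- stats::setNames(js$judgments,
                          canon_label(names(js$judgments)))
  out <- list()
  for (g in groups) {
    if (!g$requires_judgments) {
      out[[g$parent]] <- list(
        priorities = priority_vector(1, g$items),
        report = structure(list(n = 1L, lambda_max = 1, ci = 0,
                                ri = random_index(1L), cr = 0,
                                inconsistent = FALSE, threshold = 0.15),
                           class = "consistency_report"),
        kind = g$kind
      )
      next
    }
    M <- jmap[[canon_label(g$parent)]]
    if (is.null(M)) {
      stop(sprintf("expert '%s': judgment set is missing group '%s'",
                   js$expert_id, g$parent), call. = FALSE)
    }
    if (!identical(canon_label(rownames(M)), canon_label(g$items))) {
      stop(sprintf("expert '%s', group '%s': matrix items do not match group order",
                   js$expert_id, g$parent), call. = FALSE)
    }
    d <- derive_priorities(M, tol = tol, max_iter = max_iter)
    out[[g$parent]] <- list(priorities = d$priorities,
                            report = consistency_report(M, tol = tol,
                                                        max_iter = max_iter),
                            kind = g$kind)
  }
  structure(out, class = "derived_priorities")
}

#' Extract plain local priority vectors from a `derive_all()` result
#'
#' @param derived A `derived_priorities` object (or an already-plain named
#'   list of weight vectors, returned unchanged).
#' @return Named list mapping each comparison-group parent label to its
#'   named numeric local priority vector.
#' @export
local_priorities <- function(derived) {
  if (!inherits(derived, "derived_priorities")) return(derived)
  lapply(unclass(derived), function(e) {
    stats::setNames(as.numeric(e$priorities), names(e$priorities))
  })
}
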