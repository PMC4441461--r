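# Pairwise-comparison judgment matrices and their CSV interchange format.

RECIPROCITY_TOL <- 1e-9

#' Construct a pairwise comparison matrix
#'
#' A positive reciprocal matrix of ratio judgments: entry `a_ij` states how
#' many times item `i` is preferred to item `j`, so `a_ji = 1/a_ij` and the
#' diagonal is exactly 1. Under the Saaty convention entries lie in
#' `[1/9, 9]`.
#'
#' @param values Square numeric matrix of judgments.
#' @param items Character labels for rows/columns; defaults to the row
#'   names of `values`.
#' @param scale_mode `"free"` (any positive ratio) or `"saaty"` (entries
#'   restricted to `[1/9, 9]`).
#' @return An object of class `pairwise_matrix` (a matrix with `items` as
#'   dimnames and a `scale_mode` attribute).
#' @seealso [matrix_from_weights()], [validate_matrix()], [derive_priorities()]
#' @export
pairwise_matrix <- function(values, items = rownames(values),
                            scale_mode = c("free", "saaty")) {
  scale_mode <- match.arg(scale_mode)
  values <- as.matrix(values)
  if (is.null(items)) items <- paste0("item", seq_len(nrow(values)))
  M <- structure(unname(values), dimnames = list(items, items),
                 scale_mode = scale_mode, class = c("pairwise_matrix", "matrix"))
  f <- validate_matrix(M)
  if (nrow(f) > 0L) {
    stop("invalid pairwise comparison matrix:\n",
         paste0("  ", f$message, collapse = "\n"), call. = FALSE)
  }
  M
}

#' Validate a pairwise comparison matrix
#'
#' Non-raising check for squareness, positivity, unit diagonal,
#' reciprocity (`|a_ij * a_ji - 1| <= 1e-9`), and — in Saaty mode — the
#' `[1/9, 9]` range.
#'
#' @param M A matrix (need not be a valid `pairwise_matrix`).
#' @return A data frame of findings with columns `severity` and `message`;
#'   zero rows when the matrix is valid.
#' @export
validate_matrix <- function(M) {
  f <- data.frame(severity = character(), message = character(),
                  stringsAsFactors = FALSE)
  add <- function(msg) {
    f <<- rbind(f, data.frame(severity = "error", message = msg,
                              stringsAsFactors = FALSE))
  }
  m <- as.matrix(M)
  if (nrow(m) != ncol(m)) {
    add(sprintf("matrix is not square (%d x %d)", nrow(m), ncol(m)))
    return(f)
  }
  if (!is.numeric(m) || anyNA(m)) {
    add("matrix contains missing or non-numeric entries")
    return(f)
  }
  if (any(m <= 0)) add("all entries must be strictly positive")
  if (any(diag(m) != 1)) add("diagonal entries must equal 1 exactly")
  rec <- abs(m * t(m) - 1)
  if (any(rec > RECIPROCITY_TOL)) {
    ij <- which(rec == max(rec), arr.ind = TRUE)[1, ]
    add(sprintf("reciprocity violated at (%d,%d): a_ij*a_ji = %.6g",
                ij[1], ij[2], m[ij[1], ij[2]] * m[ij[2], ij[1]]))
  }
  mode <- attr(M, "scale_mode")
  if (identical(mode, "saaty") && any(m < 1 / 9 - 1e-12 | m > 9 + 1e-12)) {
    add("Saaty-mode entries must lie within [1/9, 9]")
  }
  f
}

#' Build a perfectly consistent matrix from direct weights
#'
#' Transforms directly elicited numeric weights (shares between 0 and 1,
#' or any positive scores) into the equivalent ratio-judgment matrix
#' `a_ij = w_i / w_j`. The result is perfectly consistent by construction:
#' its principal eigenvector recovers the normalized input weights and its
#' consistency index is 0. This is the transformation applied when a pilot
#' elicits weights directly instead of pairwise.
#'
#' @param weights Positive numeric vector (names become item labels).
#' @param items Optional item labels overriding `names(weights)`.
#' @param clamp_saaty If `TRUE`, upper-triangle ratios are clamped into
#'   `[1/9, 9]` (reciprocals filled afterwards, so reciprocity is exact)
#'   and the matrix is marked Saaty-mode. Default `FALSE`: the raw ratio
#'   matrix is returned in free mode. Clamping sacrifices perfect
#'   consistency when a ratio exceeds 9.
#' @return A `pairwise_matrix`.
#' @examples
#' M <- matrix_from_weights(c(a = 0.6, b = 0.2, c = 0.2))
#' derive_priorities(M)$priorities  # recovers (0.6, 0.2, 0.2)
#' @export
matrix_from_weights <- function(weights, items = names(weights),
                                clamp_saaty = FALSE) {
  w <- as.numeric(weights)
  if (length(w) < 1L || anyNA(w) || any(w <= 0)) {
    stop("direct weights must all be strictly positive (zeros are rejected: ",
         "a ratio a_ij = w_i/w_j is undefined at 0)", call. = FALSE)
  }
  if (is.null(items)) items <- paste0("item", seq_along(w))
  n <- length(w)
  m <- outer(w, w, "/")
  diag(m) <- 1
  if (clamp_saaty && n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- min(max(m[i, j], 1 / 9), 9)
        m[j, i] <- 1 / m[i, j]
      }
    }
  }
  pairwise_matrix(m, items = items,
                  scale_mode = if (clamp_saaty) "saaty" else "free")
}

#' Bundle one expert's judgment matrices
#'
#' @param expert_id Expert label.
#' @param judgments Named list mapping a comparison-group parent label to
#'   the expert's `pairwise_matrix` for that group.
#' @return An object of class `judgment_set`.
#' @export
judgment_set <- function(expert_id, judgments) {
  stopifnot(is.character(expert_id), length(expert_id) == 1L, is.list(judgments))
  structure(list(expert_id = expert_id, judgments = judgments),
            class = "judgment_set")
}

#' @export
print.judgment_set <- function(x, ...) {
  cat(sprintf("<judgment set> expert '%s': %d matrices (%s)\n", x$expert_id,
              length(x$judgments), paste(names(x$judgments), collapse = ", ")))
  invisible(x)
}

# Parse "3", "0.25" or "1/7" exactly
parse_ratio <- function(s) {
  s <- trimws(s)
  out <- numeric(length(s))
  frac <- grepl("/", s, fixed = TRUE)
  out[!frac] <- suppressWarnings(as.numeric(s[!frac]))
  if (any(frac)) {
    parts <- strsplit(s[frac], "/", fixed = TRUE)
    out[frac] <- vapply(parts, function(p) {
      if (length(p) != 2L) return(NA_real_)
      suppressWarnings(as.numeric(p[1]) / as.numeric(p[2]))
    }, numeric(1))
  }
  out
}

#' Read per-expert judgments from a long-format CSV
#'
#' Expected header: `expert_id,parent,row,col,value`. Each row supplies
#' one strict-upper-triangle cell `a(row, col)` of the pairwise matrix for
#' the comparison group whose parent node is `parent`; the lower triangle
#' is auto-filled by reciprocity. Values may be decimals or fractions
#' such as `"1/7"`. Supplying the same unordered pair twice (including as
#' its reciprocal) is an error, so reciprocity conflicts cannot arise.
#' Every multi-item comparison group of the hierarchy must be complete
#' for every expert.
#'
#' @param path CSV file path.
#' @param h The `decision_hierarchy` the judgments refer to.
#' @return A list of `judgment_set`, one per expert, in file order.
#' @seealso [write_judgments()]
#' @export
read_judgments <- function(path, h) {
  stopifnot(inherits(h, "decision_hierarchy"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("expert_id", "parent", "row", "col", "value")
  if (!all(need %in% names(df))) {
    stop("judgment CSV must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$value_num <- parse_ratio(df$value)
  if (anyNA(df$value_num)) {
    bad <- which(is.na(df$value_num))[1]
    stop(sprintf("unparseable judgment value '%s' (row %d)", df$value[bad], bad),
         call. = FALSE)
  }
  if (any(df$value_num <= 0)) {
    stop("judgment values must be strictly positive", call. = FALSE)
  }

  groups <- comparison_groups(h)
  groups <- Filter(function(g) g$requires_judgments, groups)
  names(groups) <- vapply(groups, function(g) g$parent, character(1))
  gmap <- stats::setNames(names(groups), canon_label(names(groups)))

  experts <- unique(df$expert_id)
  lapply(experts, function(ex) {
    sub <- df[df$expert_id == ex, , drop = FALSE]
    mats <- list()
    for (pc in unique(canon_label(sub$parent))) {
      if (!pc %in% names(gmap)) {
        stop(sprintf("expert '%s': unknown comparison group parent '%s'",
                     ex, sub$parent[canon_label(sub$parent) == pc][1]),
             call. = FALSE)
      }
      g <- groups[[gmap[[pc]]]]
      rows <- sub[canon_label(sub$parent) == pc, , drop = FALSE]
      n <- g$n_items
      m <- diag(1, n)
      seen <- matrix(FALSE, n, n)
      idx <- stats::setNames(seq_len(n), canon_label(g$items))
      for (k in seq_len(nrow(rows))) {
        ri <- idx[canon_label(rows$row[k])]
        ci <- idx[canon_label(rows$col[k])]
        if (is.na(ri) || is.na(ci)) {
          stop(sprintf("expert '%s', group '%s': unknown item label '%s'",
                       ex, g$parent,
                       if (is.na(ri)) rows$row[k] else rows$col[k]),
               call. = FALSE)
        }
        if (ri == ci) {
          stop(sprintf("expert '%s', group '%s': diagonal cell '%s' may not be supplied",
                       ex, g$parent, rows$row[k]), call. = FALSE)
        }
        if (seen[ri, ci]) {
          stop(sprintf(
            "expert '%s', group '%s': duplicate cell for pair (%s, %s) %s",
            ex, g$parent, g$items[min(ri, ci)], g$items[max(ri, ci)],
            "(possibly a reciprocal re-statement; store only the upper triangle)"
          ), call. = FALSE)
        }
        v <- rows$value_num[k]
        m[ri, ci] <- v
        m[ci, ri] <- 1 / v
        seen[ri, ci] <- TRUE
        seen[ci, ri] <- TRUE
      }
      missing <- which(upper.tri(seen) & !seen, arr.ind = TRUE)
      if (nrow(missing) > 0L) {
        stop(sprintf("expert '%s', group '%s': missing judgment for pair (%s, %s)",
                     ex, g$parent, g$items[missing[1, 1]], g$items[missing[1, 2]]),
             call. = FALSE)
      }
      mats[[g$parent]] <- pairwise_matrix(m, items = g$items)
    }
    incomplete <- setdiff(names(groups), names(mats))
    if (length(incomplete) > 0L) {
      stop(sprintf("expert '%s': no judgments for group(s): %s",
                   ex, paste(incomplete, collapse = ", ")), call. = FALSE)
    }
    judgment_set(ex, mats)
  })
}

#' Write judgment sets to the long-format CSV
#'
#' Emits only the strict upper triangle of each matrix (the reciprocal
#' half is redundant). `read_judgments()` on the output round-trips the
#' numeric cells bit-identically.
#'
#' @param judgment_sets A list of `judgment_set` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_judgments <- function(judgment_sets, path) {
  if (inherits(judgment_sets, "judgment_set")) judgment_sets <- list(judgment_sets)
  rows <- list()
  for (js in judgment_sets) {
    for (parent in names(js$judgments)) {
      M <- js$judgments[[parent]]
      items <- rownames(M)
      n <- nrow(M)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          rows[[length(rows) + 1L]] <- data.frame(
            expert_id = js$expert_id, parent = parent,
            row = items[i], col = items[j],
            value = format(M[i, j], digits = 17),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(expert_id = character(), parent = character(),
               row = character(), col = character(), value = character())
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
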