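# Built-in worked example: choosing an add-on pharmacotherapy to
# metformin for type 2 diabetes, as elicited from a nine-member expert
# panel. Ships the decision hierarchy and the published group global
# priorities of the objectives; the panel's raw alternative-level
# judgments were never published, so alternative scores are not part of
# the reference data.

DIABETES_GLOBALS <- c(
  "Maximizing benefits"          = 54.83,
  "Reduce HbA1c"                 = 54.83,
  "Minimizing harms"             = 45.17,
  "Minimizing non-serious harms" = 14.79,
  "Risk of fracture"             = 2.57,
  "Weight gain"                  = 7.65,
  "GI symptoms"                  = 4.57,
  "Minimizing serious harms"     = 30.38,
  "Severe hypoglycemia"          = 14.01,
  "CHF risk"                     = 7.96,
  "Acute pancreatitis"           = 4.46,
  "Risk of bladder cancer"       = 3.95
)

#' The diabetes add-on therapy decision hierarchy
#'
#' The hierarchy of the built-in worked example: maximize benefits
#' (HbA1c reduction) versus minimize harms, with harms split into
#' non-serious (fracture, weight gain, GI symptoms) and serious (severe
#' hypoglycemia, CHF, acute pancreatitis, bladder cancer), over five
#' alternatives: metformin (intensified), exenatide, sitagliptin,
#' sulfonylureas, and pioglitazone. Eight leaf objectives in all.
#'
#' @return A validated `decision_hierarchy`.
#' @seealso [diabetes_case()], [reference_locals()]
#' @export
diabetes_model <- function() {
  decision_hierarchy(
    goal = "Choose best add-on therapy to metformin",
    objectives = list(
      list(name = "Maximizing benefits",
           children = list("Reduce HbA1c")),
      list(name = "Minimizing harms", children = list(
        list(name = "Minimizing non-serious harms",
             children = list("Risk of fracture", "Weight gain", "GI symptoms")),
        list(name = "Minimizing serious harms",
             children = list("Severe hypoglycemia", "CHF risk",
                             "Acute pancreatitis", "Risk of bladder cancer"))
      ))
    ),
    alternatives = c("Metformin", "Exenatide", "Sitagliptin",
                     "Sulfonylureas", "Pioglitazone"),
    context = paste(
      "Add-on pharmacotherapy to metformin for adults with type 2",
      "diabetes; objectives limited to outcomes with comparative evidence."
    )
  )
}

#' The diabetes case fixture: hierarchy plus published global priorities
#'
#' Bundles the decision hierarchy with the published group global
#' priority scores of all objectives (in percent). The reference table
#' is exactly globally normalized: every sibling partition's globals sum
#' to the parent's global (54.83 + 45.17 = 100.00;
#' 2.57 + 7.65 + 4.57 = 14.79; 14.01 + 7.96 + 4.46 + 3.95 = 30.38;
#' 14.79 + 30.38 = 45.17).
#'
#' @return An object of class `case_fixture`: list with `hierarchy`,
#'   `reference_globals` (named percent vector over all objectives), and
#'   `notes`.
#' @export
diabetes_case <- function() {
  structure(list(
    hierarchy = diabetes_model(),
    reference_globals = DIABETES_GLOBALS,
    notes = paste(
      "Group (geometric-mean) global priorities of objectives from a",
      "nine-expert elicitation; alternative-level raw judgments were not",
      "published, so alternative scores are reproducible in structure only."
    )
  ), class = "case_fixture")
}

#' @export
print.case_fixture <- function(x, ...) {
  cat("<case fixture> add-on therapy to metformin, type 2 diabetes\n")
  print(x$hierarchy)
  cat("Reference global priorities (%):\n")
  print(x$reference_globals)
  invisible(x)
}

#' Reference local priorities implied by the published globals
#'
#' Recovers each comparison group's local weight vector from the global
#' table by the identity global(child) = global(parent) x local(child):
#' each child's global is divided by its parent's (the goal's global
#' being 100). Feeding these locals back through [global_priorities()]
#' reproduces the published global table. Covers objective groups only —
#' leaf-level alternative judgments are not part of the reference data.
#'
#' @param fixture A `case_fixture`; defaults to [diabetes_case()].
#' @return Named list mapping each objective-group parent to its local
#'   priority vector (normalized to sum 1).
#' @examples
#' loc <- reference_locals()
#' round(loc[["Choose best add-on therapy to metformin"]], 4)  # .5483 .4517
#' @export
reference_locals <- function(fixture = diabetes_case()) {
  stopifnot(inherits(fixture, "case_fixture"))
  h <- fixture$hierarchy
  glob <- c(stats::setNames(100, h$goal), fixture$reference_globals)
  nd <- hierarchy_nodes(h)
  out <- list()
  for (p in c(h$goal, nd$label[nd$n_children > 0L])) {
    kids <- children_of(h, p)
    gp <- glob[match(canon_label(p), canon_label(names(glob)))]
    gk <- glob[match(canon_label(kids), canon_label(names(glob)))]
    if (anyNA(gk) || is.na(gp)) {
      stop(sprintf("reference globals do not cover group '%s'", p),
           call. = FALSE)
    }
    w <- as.numeric(gk) / as.numeric(gp)
    out[[p]] <- stats::setNames(w / sum(w), kids)
  }
  out
}

#' Render result tables as CSV data frames and Markdown
#'
#' Formats a synthesis result (global priority listing plus alternative
#' ranking) or a relative-difference table (triangular layout, ratio
#' shown in the larger item's row, significant cells bolded in Markdown)
#' with 2-decimal display rounding. Internal values are never rounded;
#' this is presentation only.
#'
#' @param x A `synthesis_result`, `relative_difference_table`, or named
#'   numeric vector of priority scores.
#' @param ... Unused.
#' @return A list with `csv` (a data frame ready for `write.csv`) and
#'   `markdown` (character vector of table lines).
#' @export
render_report <- function(x, ...) UseMethod("render_report")

md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")

#' @export
render_report.synthesis_result <- function(x, ...) {
  g <- data.frame(objective = names(x$objective_globals),
                  global_priority_pct = sprintf("%.2f", x$objective_globals),
                  stringsAsFactors = FALSE)
  a <- x$ranking
  a$score <- sprintf("%.4f", a$score)
  md <- c(
    sprintf("Synthesis (%s mode)", x$mode), "",
    md_row(c("Objective", "Global Priority Score, %")),
    md_row(c("---", "---")),
    vapply(seq_len(nrow(g)), function(i) md_row(g[i, ]), character(1)),
    "",
    md_row(c("Alternative", "Score", "Rank")),
    md_row(c("---", "---", "---")),
    vapply(seq_len(nrow(a)), function(i) md_row(a[i, ]), character(1))
  )
  list(csv = g, markdown = md)
}

#' @export
render_report.relative_difference_table <- function(x, ...) {
  n <- length(x$items)
  md_cells <- x$display
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && nzchar(md_cells[i, j]) && x$significant[i, j]) {
        md_cells[i, j] <- paste0("**", sub("\\*$", "", md_cells[i, j]), "**")
      }
    }
  }
  md <- c(
    md_row(c("", x$items)),
    md_row(rep("---", n + 1L)),
    vapply(seq_len(n), function(i) {
      md_row(c(paste0("**", x$items[i], "**"), md_cells[i, ]))
    }, character(1)),
    "",
    sprintf("Bold: relative difference >= %.1f (significant).", x$threshold)
  )
  csv <- data.frame(item = x$items, as.data.frame(x$display),
                    stringsAsFactors = FALSE)
  names(csv) <- c("item", x$items)
  list(csv = csv, markdown = md)
}

#' @export
render_report.default <- function(x, ...) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  df <- data.frame(item = names(x), score = sprintf("%.2f", as.numeric(x)),
                   stringsAsFactors = FALSE)
  md <- c(md_row(c("Item", "Score")), md_row(c("---", "---")),
          vapply(seq_len(nrow(df)), function(i) md_row(df[i, ]), character(1)))
  list(csv = df, markdown = md)
}
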