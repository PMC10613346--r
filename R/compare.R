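# Cohort report layer: group descriptives (mean +/- sd, n-1 denominator),
# Mann-Whitney comparisons per index, chi-square for categorical demographics,
# and subgroup splits (tear +/- ; complete vs incomplete) in the layout of a
# two-group morphometry study.

#' Compare measurement indices between two groups
#'
#' One comparison row per index: per-group n, mean, sample sd and the
#' two-sided Mann-Whitney p-value. Invariant to row order and to group label
#' names. Optionally adds a Yates-corrected chi-square row for a binary
#' categorical column (e.g. sex).
#'
#' @param table measurement data.frame (see [measure_cohort()] /
#'   [read_measurements()]).
#' @param group_col column holding exactly two group labels.
#' @param params numeric columns to compare.
#' @param categorical optional name of a binary categorical column.
#' @return object of class `group_comparison` (a data.frame with attributes).
#' @export
compare_groups <- function(table, group_col = "group",
                           params = c("rmt", "pcm", "lm_ratio"),
                           categorical = NULL) {
  if (!group_col %in% names(table)) {
    stop("compare_invalid: no column '", group_col, "'", call. = FALSE)
  }
  groups <- sort(unique(as.character(table[[group_col]])))
  if (length(groups) != 2L) {
    stop("compare_needs_two_groups: found ",
         if (length(groups)) paste(groups, collapse = ", ") else "none",
         " in '", group_col, "' (need exactly 2)", call. = FALSE)
  }
  missing_p <- setdiff(params, names(table))
  if (length(missing_p)) {
    stop("compare_invalid: missing columns: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  g1 <- table[table[[group_col]] == groups[1], , drop = FALSE]
  g2 <- table[table[[group_col]] == groups[2], , drop = FALSE]

  rows <- lapply(params, function(p) {
    x <- g1[[p]]; y <- g2[[p]]
    mw <- mann_whitney(x, y)
    data.frame(parameter = p,
               group1 = groups[1], n1 = length(x),
               mean1 = mean(x), sd1 = stats::sd(x),
               group2 = groups[2], n2 = length(y),
               mean2 = mean(y), sd2 = stats::sd(y),
               U = mw$U, p = mw$p, method = mw$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  chi <- NULL
  if (!is.null(categorical)) {
    if (!categorical %in% names(table)) {
      stop("compare_invalid: no column '", categorical, "'", call. = FALSE)
    }
    tab2 <- base::table(factor(table[[group_col]], levels = groups),
                        table[[categorical]])
    if (!all(dim(tab2) == c(2L, 2L))) {
      stop("compare_invalid: '", categorical, "' is not binary", call. = FALSE)
    }
    chi <- chi2_yates(unclass(tab2)[, , drop = FALSE])
    chi$variable <- categorical
  }
  structure(out, class = c("group_comparison", "data.frame"),
            groups = groups, chi2 = chi)
}

#' @export
print.group_comparison <- function(x, ...) {
  groups <- attr(x, "groups")
  cat(sprintf("%-12s %-24s %-24s %10s\n", "",
              paste0(groups[1], " (n=", x$n1[1], ")"),
              paste0(groups[2], " (n=", x$n2[1], ")"), "P-value"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s %-24s %-24s %10s\n", x$parameter[i],
                sprintf("%.2f ± %.2f", x$mean1[i], x$sd1[i]),
                sprintf("%.2f ± %.2f", x$mean2[i], x$sd2[i]),
                format_p(x$p[i])))
  }
  chi <- attr(x, "chi2")
  if (!is.null(chi)) {
    cat(sprintf("%-12s chi2(Yates) = %.2f, p = %s", chi$variable, chi$stat,
                format_p(chi$p)))
    cat(sprintf("  [uncorrected Pearson: %.2f, p = %s]\n",
                chi$pearson_stat, format_p(chi$pearson_p)))
    if (chi$correction_matters) {
      cat("  note: corrected and uncorrected p-values differ materially;",
          "report which statistic was used\n")
    }
  }
  cat("Mean ± SD; two-sided Mann-Whitney U test\n")
  invisible(x)
}

format_p <- function(p) {
  if (p < 0.001) "<0.001" else sprintf("%.2f", p)
}

#' Subgroup comparison within a measurement table
#'
#' Filters the table to one group and compares two subgroups defined by
#' another column (e.g. `tear` yes/no, or `dlm_type` complete/incomplete
#' within the DLM group).
#'
#' @param table measurement data.frame.
#' @param within value of `group` to keep (`NULL` keeps all rows).
#' @param by subgroup column.
#' @param params numeric columns to compare.
#' @return a `group_comparison`.
#' @export
compare_subgroups <- function(table, by, within = NULL,
                              params = c("rmt", "pcm", "lm_ratio")) {
  if (!is.null(within)) {
    table <- table[table$group == within, , drop = FALSE]
    if (!nrow(table)) {
      stop("compare_invalid: no rows with group == '", within, "'",
           call. = FALSE)
    }
  }
  if (!by %in% names(table)) {
    stop("compare_invalid: no column '", by, "'", call. = FALSE)
  }
  keep <- !(table[[by]] %in% c("na", NA))
  compare_groups(table[keep, , drop = FALSE], group_col = by, params = params)
}
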