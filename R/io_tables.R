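#' Write a class profile as TSV
#'
#' One row per cell: `cell_id`, one 0/1 column per class, and a `subset`
#' column with the cell's combination label. Tab-separated, UTF-8, Unix
#' newlines; byte-deterministic for a given profile.
#'
#' @param profile a `ClassProfile`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_class_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ClassProfile"))
  mem <- profile$membership
  labels <- apply(mem, 1, function(row) {
    if (!any(row)) "none" else paste(colnames(mem)[row], collapse = "+")
  })
  if (nrow(mem) == 0) labels <- character()
  df <- data.frame(cell_id = rownames(mem) %||% character(),
                   ifelse(mem, 1L, 0L),
                   subset = labels, check.names = FALSE)
  colnames(df) <- c("cell_id", colnames(mem), "subset")
  write_tsv(df, path)
  invisible(path)
}

#' Read a class profile written by [write_class_profile()]
#' @param path TSV file.
#' @return A `ClassProfile`.
#' @export
read_class_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          colClasses = NA)
  cls <- setdiff(colnames(df), c("cell_id", "subset"))
  mem <- as.matrix(df[, cls, drop = FALSE]) == 1
  rownames(mem) <- as.character(df$cell_id)
  class_profile(mem)
}

#' Write a combination-count table as TSV
#'
#' Tabular twin of an UpSet plot. Columns: `combination`, `exclusive`,
#' `inclusive`, `pct_exclusive`, `pct_inclusive`. Rows are sorted by
#' descending exclusive count, ties broken lexicographically on the
#' combination label; subsets with zero exclusive count are omitted
#' except the empty set ("none"), which is always reported. The
#' exclusive column (including "none") sums to the total cell count.
#'
#' @param counts a `CombinationCounts`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_combination_table <- function(counts, path) {
  df <- combination_table(counts)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_combination_table
#' @export
combination_table <- function(counts) {
  stopifnot(inherits(counts, "CombinationCounts"))
  lbl <- names(counts$exclusive)
  keep <- counts$exclusive > 0 | lbl == "none"
  df <- data.frame(combination = lbl[keep],
                   exclusive = counts$exclusive[keep],
                   inclusive = counts$inclusive[keep],
                   row.names = NULL)
  if (counts$total_cells > 0) {
    df$pct_exclusive <- 100 * df$exclusive / counts$total_cells
    df$pct_inclusive <- 100 * df$inclusive / counts$total_cells
  } else {
    df$pct_exclusive <- df$pct_inclusive <- NA_real_
  }
  df[order(-df$exclusive, df$combination), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Read a combination table back into a CombinationCounts
#'
#' Accepts tables written by [write_combination_table()] as well as
#' minimal two-column tables (`combination` plus either `exclusive` or
#' `inclusive`). Inclusive-only tables are converted through
#' [exclusive_from_inclusive()].
#'
#' @param path TSV file.
#' @param class_names class universe; defaults to the classes appearing
#'   in the labels, in first-appearance order.
#' @param total_cells population size, needed to place cells outside all
#'   classes when reading inclusive-only tables.
#' @return A `CombinationCounts`.
#' @export
read_combination_table <- function(path, class_names = NULL,
                                   total_cells = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "")
  if (!"combination" %in% names(df))
    stop("format error in ", path, ": no 'combination' column")
  if (is.null(class_names)) {
    parts <- strsplit(df$combination[df$combination != "none"], "+",
                      fixed = TRUE)
    class_names <- unique(trimws(unlist(parts)))
  }
  if ("exclusive" %in% names(df)) {
    excl <- stats::setNames(df$exclusive, df$combination)
    combination_counts_from_exclusive(excl, class_names, total_cells)
  } else if ("inclusive" %in% names(df)) {
    incl <- stats::setNames(df$inclusive, df$combination)
    excl <- exclusive_from_inclusive(incl, class_names, total_cells)
    combination_counts_from_exclusive(excl, class_names, total_cells)
  } else {
    stop("format error in ", path,
         ": need an 'exclusive' or 'inclusive' column")
  }
}

#' Write a boolean cell mask as two-column TSV
#' @param mask named logical vector (cell_id -> TRUE/FALSE).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_cell_mask <- function(mask, path) {
  df <- data.frame(cell_id = names(mask),
                   selected = ifelse(mask, "TRUE", "FALSE"))
  write_tsv(df, path)
  invisible(path)
}

# deterministic TSV: UTF-8, Unix newlines, no quoting, full precision
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- format_num(df[[j]])
  lines <- c(paste(colnames(df), collapse = "\t"),
             if (nrow(df)) do.call(paste,
                                   c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v)
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
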