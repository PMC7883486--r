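# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's bitmask/zeta-transform code paths: subsets are enumerated
# as index vectors and counted cell by cell.

dense_expr <- function(m, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(m)))
  dimnames(m) <- list(cells, genes)
  ExpressionMatrix(m)
}

toy_panel <- function(k = 2, markers_per_class = 1,
                      class_names = LETTERS[seq_len(k)]) {
  classes <- lapply(seq_len(k), function(j)
    sprintf("%s_m%d", tolower(class_names[j]), seq_len(markers_per_class)))
  names(classes) <- class_names
  marker_panel_set("toy", classes)
}

random_profile <- function(n_cells, class_names, p = 0.4) {
  mem <- matrix(runif(n_cells * length(class_names)) < p,
                nrow = n_cells,
                dimnames = list(sprintf("c%d", seq_len(n_cells)),
                                class_names))
  class_profile(mem)
}

# Enumerate all subsets of class indices as a list of integer vectors,
# in the same mask order the package labels use (bit j = class j).
enumerate_subsets <- function(k) {
  lapply(0:(2^k - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(k) - 1)) != 0))
}

oracle_subset_label <- function(idx, class_names) {
  if (!length(idx)) "none" else paste(class_names[idx], collapse = "+")
}

# Brute force: test every subset against every cell.
oracle_counts <- function(membership) {
  k <- ncol(membership)
  subsets <- enumerate_subsets(k)
  class_names <- colnames(membership)
  excl <- incl <- integer(length(subsets))
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]]
    for (i in seq_len(nrow(membership))) {
      row <- which(membership[i, ])
      if (all(idx %in% row)) incl[s] <- incl[s] + 1L
      if (length(row) == length(idx) && setequal(row, idx))
        excl[s] <- excl[s] + 1L
    }
  }
  labels <- vapply(subsets, oracle_subset_label, character(1), class_names)
  list(exclusive = stats::setNames(excl, labels),
       inclusive = stats::setNames(incl, labels))
}

# Same brute-force definition, vectorized over cells (still tests every
# subset against every cell; no bitmasks, no lattice transforms).
oracle_counts_vec <- function(membership) {
  k <- ncol(membership)
  subsets <- enumerate_subsets(k)
  class_names <- colnames(membership)
  n_pos <- rowSums(membership)
  excl <- incl <- integer(length(subsets))
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]]
    in_s <- rowSums(membership[, idx, drop = FALSE]) == length(idx)
    incl[s] <- sum(in_s)
    excl[s] <- sum(in_s & n_pos == length(idx))
  }
  labels <- vapply(subsets, oracle_subset_label, character(1), class_names)
  list(exclusive = stats::setNames(excl, labels),
       inclusive = stats::setNames(incl, labels))
}

expect_same_counts <- function(counts, oracle) {
  expect_identical(counts$exclusive[names(oracle$exclusive)],
                   oracle$exclusive)
  expect_identical(counts$inclusive[names(oracle$inclusive)],
                   oracle$inclusive)
}
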