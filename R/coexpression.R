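#' Assign per-cell neurotransmitter class sets
#'
#' A cell is positive for a class iff ANY of the class's resolved marker
#' genes exceeds the threshold on the chosen layer — the OR-over-markers
#' semantics under which co-expression is called positive when one marker
#' gene of each class is expressed. The comparison is strictly greater
#' than, matching the published "> 1" rules.
#'
#' @param x an `ExpressionMatrix`.
#' @param panel a `MarkerPanelSet` (resolved on the fly) or
#'   `ResolvedPanelSet`.
#' @param threshold expression threshold (default 1).
#' @param layer `"normalized"` (default) or `"counts"`.
#' @param case_insensitive passed to [resolve_panels()] when `panel` is
#'   unresolved.
#' @return A `ClassProfile`: cell x class logical membership plus the
#'   parameters that produced it.
#' @export
assign_classes <- function(x, panel, threshold = 1,
                           layer = c("normalized", "counts"),
                           case_insensitive = FALSE) {
  layer <- match.arg(layer)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (inherits(panel, "MarkerPanelSet"))
    panel <- resolve_panels(panel, x, case_insensitive)
  stopifnot(inherits(panel, "ResolvedPanelSet"))
  if (!length(panel$classes))
    stop("no resolvable classes in panel")
  m <- expression_layer(x, layer)
  membership <- vapply(panel$classes, function(idx) {
    Matrix::rowSums(m[, idx, drop = FALSE] > threshold) > 0
  }, logical(nrow(m)))
  membership <- matrix(membership, nrow = nrow(m),
                       dimnames = list(cell_ids(x), names(panel$classes)))
  class_profile(membership, threshold = threshold, layer = layer)
}

#' Construct a ClassProfile from a membership matrix
#' @param membership logical cells x classes matrix with dimnames.
#' @param threshold,layer parameters recorded for provenance.
#' @return A `ClassProfile`.
#' @export
class_profile <- function(membership, threshold = NA_real_,
                          layer = NA_character_) {
  stopifnot(is.matrix(membership), is.logical(membership))
  if (is.null(colnames(membership)))
    stop("membership needs class names as colnames")
  structure(
    list(cell_ids = rownames(membership),
         class_names = colnames(membership),
         membership = membership, threshold = threshold, layer = layer),
    class = "ClassProfile")
}

#' @export
print.ClassProfile <- function(x, ...) {
  cat(sprintf("ClassProfile: %d cells x %d classes (threshold %s on %s)\n",
              nrow(x$membership), ncol(x$membership),
              format(x$threshold), x$layer))
  pos <- colSums(x$membership)
  for (cls in x$class_names)
    cat(sprintf("  %-16s %d positive\n", cls, pos[cls]))
  invisible(x)
}

#' Merge classes of a profile by union
#'
#' Collapses member classes into one (e.g. serotonergic, dopaminergic and
#' tyraminergic subtypes grouped into a single aminergic category):
#' membership of the merged class is the union (elementwise OR) of the
#' member columns. The merged class takes the position of its first
#' member; other classes keep their order.
#'
#' @param profile a `ClassProfile`.
#' @param groups named list, merged-class name -> character vector of
#'   member class names.
#' @return A `ClassProfile`.
#' @export
merge_classes <- function(profile, groups) {
  stopifnot(inherits(profile, "ClassProfile"))
  mem <- profile$membership
  unknown <- setdiff(unlist(groups), colnames(mem))
  if (length(unknown))
    stop("unknown classes in group mapping: ",
         paste(unknown, collapse = ", "))
  owner <- stats::setNames(rep(NA_character_, ncol(mem)), colnames(mem))
  for (g in names(groups)) owner[groups[[g]]] <- g
  out_names <- character(); cols <- list()
  for (cls in colnames(mem)) {
    g <- owner[[cls]]
    nm <- if (is.na(g)) cls else g
    if (nm %in% out_names) next
    cols[[nm]] <- if (is.na(g)) mem[, cls]
                  else rowSums(mem[, groups[[g]], drop = FALSE]) > 0
    out_names <- c(out_names, nm)
  }
  newmem <- matrix(unlist(cols), nrow = nrow(mem),
                   dimnames = list(rownames(mem), out_names))
  class_profile(newmem, profile$threshold, profile$layer)
}

# ---- combination lattice ---------------------------------------------------

subset_label <- function(mask, class_names) {
  if (mask == 0L) return("none")
  paste(class_names[bitwAnd(mask, bitwShiftL(1L, seq_along(class_names) -
                                               1L)) != 0L],
        collapse = "+")
}

all_subset_labels <- function(class_names) {
  vapply(0:(2^length(class_names) - 1L), subset_label,
         character(1), class_names = class_names)
}

label_to_mask <- function(label, class_names) {
  label <- trimws(label)
  if (label %in% c("none", "", "(none)")) return(0L)
  parts <- trimws(strsplit(label, "+", fixed = TRUE)[[1]])
  idx <- match(parts, class_names)
  if (anyNA(idx))
    stop("unknown class in subset label '", label, "': ",
         paste(parts[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, idx - 1L))
}

#' Combination-lattice counts from a class profile
#'
#' The quantification shown in UpSet plots. For every subset S of the
#' class universe, the exclusive count is the number of cells whose class
#' set equals S exactly (the conventional UpSet bar); the inclusive count
#' is the number of cells whose class set contains S (the convention of
#' in-text statements such as "134 neurons showed coexpression of marker
#' genes for GABA and acetylcholine"). Both are computed in one pass over
#' cells plus a subset-lattice zeta transform.
#'
#' @param profile a `ClassProfile`.
#' @return A `CombinationCounts`: `class_names`, `exclusive` and
#'   `inclusive` named integer vectors over all 2^k subsets (labels join
#'   class names with "+" in declaration order; the empty set is "none"),
#'   and `total_cells`.
#' @export
combination_counts <- function(profile) {
  stopifnot(inherits(profile, "ClassProfile"))
  k <- length(profile$class_names)
  if (k > 24) stop("more than 24 classes not supported")
  mem <- profile$membership
  masks <- as.integer(mem %*% bitwShiftL(1L, seq_len(k) - 1L))
  excl <- tabulate(masks + 1L, nbins = 2L^k)
  incl <- superset_zeta(excl, k)
  new_combination_counts(profile$class_names, excl, incl, nrow(mem))
}

new_combination_counts <- function(class_names, excl, incl, total) {
  labels <- all_subset_labels(class_names)
  structure(
    list(class_names = class_names,
         exclusive = stats::setNames(as.integer(excl), labels),
         inclusive = stats::setNames(as.integer(incl), labels),
         total_cells = as.integer(total)),
    class = "CombinationCounts")
}

# inclusive[S] = sum over supersets T of S of x[T]; O(k 2^k)
superset_zeta <- function(x, k) {
  x <- as.numeric(x)
  n <- 2L^k
  for (b in seq_len(k) - 1L) {
    bit <- bitwShiftL(1L, b)
    s <- 0:(n - 1L)
    lo <- s[bitwAnd(s, bit) == 0L]
    x[lo + 1L] <- x[lo + 1L] + x[lo + bit + 1L]
  }
  x
}

# exclusive[S] = sum over supersets T of (-1)^{|T \ S|} inclusive[T]
superset_moebius <- function(x, k) {
  x <- as.numeric(x)
  n <- 2L^k
  for (b in seq_len(k) - 1L) {
    bit <- bitwShiftL(1L, b)
    s <- 0:(n - 1L)
    lo <- s[bitwAnd(s, bit) == 0L]
    x[lo + 1L] <- x[lo + 1L] - x[lo + bit + 1L]
  }
  x
}

#' @export
print.CombinationCounts <- function(x, ...) {
  cat(sprintf("CombinationCounts: %d classes, %d cells\n",
              length(x$class_names), x$total_cells))
  ord <- order(-x$exclusive, names(x$exclusive))
  shown <- ord[x$exclusive[ord] > 0 | names(x$exclusive)[ord] == "none"]
  for (i in shown)
    cat(sprintf("  %-30s exclusive %6d  inclusive %6d\n",
                names(x$exclusive)[i], x$exclusive[i], x$inclusive[i]))
  invisible(x)
}

as_subset_vector <- function(map, class_names, default = 0) {
  n <- 2L^length(class_names)
  out <- rep(as.numeric(default), n)
  names(out) <- all_subset_labels(class_names)
  seen <- logical(n)
  if (length(map)) {
    if (is.null(names(map))) stop("subset map must be named")
    for (i in seq_along(map)) {
      mk <- label_to_mask(names(map)[i], class_names)
      out[mk + 1L] <- map[[i]]
      seen[mk + 1L] <- TRUE
    }
  }
  attr(out, "seen") <- seen
  out
}

#' Inclusive counts from exclusive counts (and back)
#'
#' The signed-sum (Moebius / inclusion-exclusion) conversion between the
#' two subset-count conventions:
#' \deqn{inclusive(S) = \sum_{T \supseteq S} exclusive(T), \quad
#'       exclusive(S) = \sum_{T \supseteq S} (-1)^{|T \setminus S|}
#'       inclusive(T).}
#' `exclusive_from_inclusive` checks monotonicity of the input
#' (\eqn{S \subseteq T \Rightarrow inclusive(S) \ge inclusive(T)}) and
#' rejects inputs whose transform goes negative, naming the offending
#' subset. Missing subsets are treated as 0. In-text published counts are
#' inclusive and rarely state the empty set, so `total_cells` supplies
#' \eqn{inclusive(\emptyset)}; without it the union of the classes is
#' taken as the universe (empty-set exclusive 0) with a warning.
#'
#' @param inclusive,exclusive named numeric vector; names are subset
#'   labels joining class names with "+" ("none" or "" for the empty
#'   set).
#' @param class_names class universe, in declaration order.
#' @param total_cells optional population size.
#' @return Named numeric vector over all 2^k subsets.
#' @export
exclusive_from_inclusive <- function(inclusive, class_names,
                                     total_cells = NULL) {
  k <- length(class_names)
  v <- as_subset_vector(inclusive, class_names)
  seen <- attr(v, "seen")
  if (!seen[1]) {
    if (!is.null(total_cells)) {
      v[1] <- total_cells
    } else {
      warning("inclusive(empty set) unknown and total_cells not given; ",
              "taking the class union as the universe")
      v[1] <- NA  # patched after the union is known
    }
  }
  if (k == 0) stop("class_names must be non-empty")
  # monotonicity on covering pairs implies monotonicity on the lattice
  n <- 2L^k
  for (s in 0:(n - 2L)) {
    for (b in seq_len(k) - 1L) {
      bit <- bitwShiftL(1L, b)
      if (bitwAnd(s, bit) == 0L) {
        if (!is.na(v[s + 1L]) && v[s + 1L] < v[s + bit + 1L])
          stop("data-consistency error: inclusive('",
               subset_label(s, class_names), "') = ", v[s + 1L],
               " < inclusive('", subset_label(s + bit, class_names),
               "') = ", v[s + bit + 1L])
      }
    }
  }
  fill_empty <- is.na(v[1])
  if (fill_empty) v[1] <- 0
  excl <- superset_moebius(v, k)
  if (fill_empty) {
    union_size <- sum(excl[-1])
    excl[1] <- 0
    v[1] <- union_size
  }
  neg <- which(excl < -1e-9)
  if (length(neg))
    stop("data-consistency error: exclusive('",
         subset_label(neg[1] - 1L, class_names),
         "') = ", excl[neg[1]], " is negative; the inclusive map is ",
         "not realizable by any cell population")
  excl <- round(excl)
  names(excl) <- all_subset_labels(class_names)
  excl
}

#' @rdname exclusive_from_inclusive
#' @export
inclusive_from_exclusive <- function(exclusive, class_names) {
  v <- as_subset_vector(exclusive, class_names)
  if (any(v < 0))
    stop("exclusive counts must be non-negative")
  incl <- superset_zeta(v, length(class_names))
  names(incl) <- all_subset_labels(class_names)
  incl
}

#' Build a CombinationCounts object from an exclusive subset map
#' @param exclusive named numeric vector of exclusive counts.
#' @param class_names class universe.
#' @param total_cells optional total; defaults to the sum of the
#'   exclusive counts.
#' @return A `CombinationCounts`.
#' @export
combination_counts_from_exclusive <- function(exclusive, class_names,
                                              total_cells = NULL) {
  v <- as_subset_vector(exclusive, class_names)
  if (!is.null(total_cells)) {
    extra <- total_cells - sum(v)
    if (extra < -1e-9)
      stop("total_cells (", total_cells,
           ") smaller than the sum of exclusive counts (", sum(v), ")")
    v[1] <- v[1] + extra   # cells outside all classes
  }
  incl <- superset_zeta(v, length(class_names))
  new_combination_counts(class_names, v, incl, sum(v))
}

#' Binary expression table for a gene list
#'
#' Thresholded presence/absence per cell and gene — the tabular form of a
#' binarized expression heatmap (e.g. of neurotransmitter receptors).
#' Absent genes produce all-FALSE columns with a warning. Equivalent to
#' [assign_classes()] with one singleton panel per gene.
#'
#' @param x an `ExpressionMatrix`.
#' @param genes non-empty character vector of gene IDs.
#' @param threshold expression threshold.
#' @param layer layer to threshold.
#' @return Logical cells x genes matrix.
#' @export
binary_expression_matrix <- function(x, genes, threshold = 1,
                                     layer = c("normalized", "counts")) {
  layer <- match.arg(layer)
  if (!length(genes)) stop("gene list must be non-empty")
  m <- expression_layer(x, layer)
  out <- matrix(FALSE, nrow(m), length(genes),
                dimnames = list(cell_ids(x), genes))
  idx <- match(genes, colnames(m))
  if (anyNA(idx))
    warning("genes absent from matrix (all-FALSE columns): ",
            paste(genes[is.na(idx)], collapse = ", "))
  present <- which(!is.na(idx))
  if (length(present))
    out[, present] <- as.matrix(m[, idx[present], drop = FALSE] > threshold)
  out
}

#' Subset counts as percentages of the population
#'
#' @param counts a `CombinationCounts`.
#' @param type percentage base: exclusive (UpSet-bar convention) or
#'   inclusive counts.
#' @return Named numeric vector, percentages of `total_cells` (exclusive
#'   percentages sum to 100).
#' @export
combination_proportions <- function(counts,
                                    type = c("exclusive", "inclusive")) {
  type <- match.arg(type)
  stopifnot(inherits(counts, "CombinationCounts"))
  if (counts$total_cells <= 0)
    stop("undefined proportions: total_cells is 0")
  100 * counts[[type]] / counts$total_cells
}

# Restrict a CombinationCounts to a subset of its classes by projecting
# every cell's class set onto the retained classes.
project_counts <- function(counts, keep) {
  idx <- match(keep, counts$class_names)
  stopifnot(!anyNA(idx))
  k_old <- length(counts$class_names)
  old_masks <- 0:(2L^k_old - 1L)
  proj <- integer(length(old_masks))
  for (j in seq_along(idx))
    proj <- proj + bitwShiftL(1L, j - 1L) *
      as.integer(bitwAnd(old_masks, bitwShiftL(1L, idx[j] - 1L)) != 0L)
  excl <- as.integer(rowsum(as.numeric(counts$exclusive), proj))
  incl <- superset_zeta(excl, length(keep))
  new_combination_counts(keep, excl, incl, counts$total_cells)
}

#' Descriptive comparison of combination counts across two datasets
#'
#' Percentages are computed from each dataset's own total (the
#' dataset-size-free scale on which larval vs adult, or young vs aged,
#' populations are compared). Class universes are intersected first, with
#' a warning on mismatch and an error when disjoint; counts are projected
#' onto the common classes. A normal-approximation confidence interval
#' for the difference of proportions is emitted for orientation only —
#' the comparison stays descriptive.
#'
#' @param counts_a,counts_b `CombinationCounts` objects.
#' @param label_a,label_b dataset labels used in column names.
#' @param type compare exclusive (default) or inclusive counts.
#' @param conf_level confidence level of the interval.
#' @return A data.frame with one row per class subset: counts,
#'   percentages, difference (percentage points, A - B), ratio (A / B)
#'   and the interval bounds.
#' @export
compare_datasets <- function(counts_a, counts_b, label_a = "A",
                             label_b = "B",
                             type = c("exclusive", "inclusive"),
                             conf_level = 0.95) {
  type <- match.arg(type)
  stopifnot(inherits(counts_a, "CombinationCounts"),
            inherits(counts_b, "CombinationCounts"))
  common <- intersect(counts_a$class_names, counts_b$class_names)
  if (!length(common))
    stop("comparability error: the two datasets share no classes")
  if (!setequal(counts_a$class_names, common) ||
      !setequal(counts_b$class_names, common))
    warning("class universes differ; comparing the ", length(common),
            " shared class(es): ", paste(common, collapse = ", "))
  a <- project_counts(counts_a, common)
  b <- project_counts(counts_b, common)
  na <- a$total_cells; nb <- b$total_cells
  ca <- a[[type]]; cb <- b[[type]]
  pa <- ca / na; pb <- cb / nb
  diff <- 100 * (pa - pb)
  ratio <- (pa) / (pb)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pa * (1 - pa) / na + pb * (1 - pb) / nb)
  out <- data.frame(
    subset = names(ca),
    count_a = as.integer(ca), count_b = as.integer(cb),
    pct_a = 100 * pa, pct_b = 100 * pb,
    diff_pct = diff, ratio = ratio,
    ci_lo = diff - 100 * z * se, ci_hi = diff + 100 * z * se,
    row.names = NULL, check.names = FALSE)
  names(out)[2:5] <- c(paste0("count_", label_a), paste0("count_", label_b),
                       paste0("pct_", label_a), paste0("pct_", label_b))
  attr(out, "labels") <- c(label_a, label_b)
  out
}
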