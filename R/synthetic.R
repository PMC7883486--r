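#' Parameters for the synthetic co-expression generator
#'
#' Defines a study population with planted neurotransmitter class
#' subsets: each cell draws one class subset from `subset_prevalence`,
#' marker genes of planted-positive classes draw counts from a negative
#' binomial with mean `mu_marker`, everything else (other classes'
#' markers and the background genes) from mean `mu_background`, and
#' independent Bernoulli dropout zeroes each entry with probability
#' `dropout`. This is the minimal standard sparse scRNA-seq noise model:
#' over-dispersed counts plus technical zeroing, which is exactly what
#' the OR-over-markers thresholding rule has to withstand.
#'
#' @param n_cells number of cells.
#' @param panel a `MarkerPanelSet` providing class names and marker
#'   genes.
#' @param subset_prevalence named numeric vector over class-subset labels
#'   ("none" for the empty set, classes joined with "+"); non-negative,
#'   summing to 1 within 1e-9.
#' @param mu_marker mean count of a marker gene in cells positive for its
#'   class.
#' @param mu_background mean count otherwise.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed; the NB zero probability is
#'   `(1 + mu/size)^(-size)`).
#' @param dropout probability in `[0, 1]` of zeroing any drawn count.
#' @param n_background_genes genes outside all panels, always at
#'   `mu_background`.
#' @param seed integer RNG seed; the full draw order is documented in
#'   [generate_dataset()].
#' @return A `SimulationParams` object.
#' @export
simulation_params <- function(n_cells, panel, subset_prevalence,
                              mu_marker, mu_background = 0,
                              dispersion = 1, dropout = 0,
                              n_background_genes = 0, seed = 1) {
  stopifnot(inherits(panel, "MarkerPanelSet"))
  if (n_cells < 0 || n_cells != round(n_cells))
    stop("parameter error: n_cells must be a non-negative integer")
  if (mu_marker <= 0) stop("parameter error: mu_marker must be positive")
  if (mu_background < 0)
    stop("parameter error: mu_background must be non-negative")
  if (dispersion <= 0)
    stop("parameter error: dispersion must be positive")
  if (dropout < 0 || dropout > 1)
    stop("parameter error: dropout must be in [0, 1]")
  prev <- unlist(subset_prevalence)
  if (is.null(names(prev)) || any(!nzchar(names(prev))))
    stop("parameter error: subset_prevalence must be named")
  if (any(prev < 0))
    stop("parameter error: subset prevalences must be non-negative")
  if (abs(sum(prev) - 1) > 1e-9)
    stop("parameter error: subset prevalences must sum to 1 (got ",
         format(sum(prev), digits = 12), ")")
  classes <- panel_classes(panel)
  for (lbl in names(prev)) label_to_mask(lbl, classes)  # validates subsets
  structure(
    list(n_cells = as.integer(n_cells), panel = panel,
         subset_prevalence = prev, mu_marker = mu_marker,
         mu_background = mu_background, dispersion = dispersion,
         dropout = dropout,
         n_background_genes = as.integer(n_background_genes),
         seed = as.integer(seed)),
    class = "SimulationParams")
}

#' Generate a synthetic expression matrix with planted class subsets
#'
#' Fully reproducible from `params$seed` with a documented draw order:
#' (1) one subset draw per cell (cells in order); (2) one negative
#' binomial count per cell x gene, cells outer, genes inner (panel genes
#' in panel-declaration order, then background genes); (3) when
#' `dropout > 0`, one uniform per cell x gene in the same order, zeroing
#' the count where it falls below `dropout`. R's default Mersenne-Twister
#' generator and `stats::rnbinom(size, mu)` are used; the algorithm names
#' are recorded in the truth object.
#'
#' @param params a [simulation_params()] object.
#' @return A list with `matrix` (an [ExpressionMatrix()]) and `truth`
#'   (a `SyntheticTruth`: per-cell planted subset labels, the planted
#'   membership matrix, a parameter echo, and the RNG description).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  classes <- panel_classes(params$panel)
  k <- length(classes)
  genes <- unlist(params$panel$classes, use.names = FALSE)
  gene_class <- rep(seq_len(k), lengths(params$panel$classes))
  if (params$n_background_genes > 0) {
    genes <- c(genes, sprintf("background_%03d",
                              seq_len(params$n_background_genes)))
    gene_class <- c(gene_class, rep(0L, params$n_background_genes))
  }
  n <- params$n_cells
  g <- length(genes)
  cellnames <- sprintf("cell_%05d", seq_len(n))

  set.seed(params$seed)
  labels <- if (n > 0)
    sample(names(params$subset_prevalence), n, replace = TRUE,
           prob = params$subset_prevalence)
  else character()
  masks <- vapply(labels, label_to_mask, integer(1),
                  class_names = classes, USE.NAMES = FALSE)
  membership <- matrix(FALSE, n, k, dimnames = list(cellnames, classes))
  for (j in seq_len(k))
    membership[, j] <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L

  # cell-major mean vector: cell 1 genes 1..g, cell 2 genes 1..g, ...
  if (n > 0 && g > 0) {
    pos <- membership[, pmax(gene_class, 1L), drop = FALSE]
    pos[, gene_class == 0L] <- FALSE
    mu <- ifelse(t(pos), params$mu_marker, params$mu_background)
    draws <- stats::rnbinom(n * g, size = params$dispersion, mu = as.vector(mu))
    if (params$dropout > 0) {
      u <- stats::runif(n * g)
      draws[u < params$dropout] <- 0
    }
    counts <- Matrix::Matrix(matrix(draws, nrow = n, ncol = g, byrow = TRUE,
                                    dimnames = list(cellnames, genes)),
                             sparse = TRUE)
  } else {
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                   x = numeric(), dims = c(n, g),
                                   dimnames = list(cellnames, genes))
  }
  truth <- structure(
    list(cell_ids = cellnames, subsets = labels, membership = membership,
         params = params,
         rng = paste("Mersenne-Twister; stats::rnbinom(size, mu);",
                     "subsets per cell, then counts cells-outer/",
                     "genes-inner, then dropout uniforms in the same",
                     "order (skipped when dropout = 0)")),
    class = "SyntheticTruth")
  list(matrix = ExpressionMatrix(counts,
                                 meta = c(source = "cotransmitr synthetic",
                                          seed = as.character(params$seed))),
       truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d cells, %d classes (seed %d)\n",
              length(x$cell_ids), ncol(x$membership), x$params$seed))
  tab <- sort(table(x$subsets), decreasing = TRUE)
  for (nm in names(tab)) cat(sprintf("  %-24s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Expected called inclusive class frequencies under the generator model
#'
#' The Bernoulli-thinning calculation for the generator: a marker gene of
#' a planted-positive class is detected (non-zero after dropout) with
#' probability \eqn{(1-d)(1 - (1 + \mu_m/\theta)^{-\theta})}, an
#' off-class marker with the analogous `mu_background` expression, and a
#' class is called when any of its `k` markers is detected. Exact as long
#' as every non-zero normalized value exceeds the classification
#' threshold, which holds for the defaults (threshold 1, scale factor
#' 10,000) whenever cell library sizes stay a few orders of magnitude
#' below the scale factor.
#'
#' @param params a `SimulationParams` object.
#' @return Named numeric vector: expected fraction of cells called
#'   positive per class.
#' @export
expected_called_frequency <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  classes <- panel_classes(params$panel)
  kk <- lengths(params$panel$classes)
  nb_zero <- function(mu) if (mu == 0) 1 else
    (1 + mu / params$dispersion)^(-params$dispersion)
  p_det_marker <- (1 - params$dropout) * (1 - nb_zero(params$mu_marker))
  p_det_bg <- (1 - params$dropout) * (1 - nb_zero(params$mu_background))
  prev <- params$subset_prevalence
  masks <- vapply(names(prev), label_to_mask, integer(1),
                  class_names = classes)
  out <- stats::setNames(numeric(length(classes)), classes)
  for (j in seq_along(classes)) {
    planted <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L
    p_called_pos <- 1 - (1 - p_det_marker)^kk[j]
    p_called_neg <- 1 - (1 - p_det_bg)^kk[j]
    out[j] <- sum(prev[planted]) * p_called_pos +
      sum(prev[!planted]) * p_called_neg
  }
  out
}

#' Score recovery of planted structure by the classification pipeline
#'
#' @param truth a `SyntheticTruth`.
#' @param profile the `ClassProfile` called on the generated matrix; must
#'   cover the same cells in the same order.
#' @return A `RecoveryReport`: per-class sensitivity/specificity, planted
#'   vs called exclusive subset frequencies with absolute errors, and the
#'   overall exact-subset accuracy.
#' @export
evaluate_recovery <- function(truth, profile) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(profile, "ClassProfile"))
  if (!identical(truth$cell_ids, profile$cell_ids))
    stop("cell misalignment between truth and profile")
  classes <- colnames(truth$membership)
  if (!all(classes %in% profile$class_names))
    stop("profile lacks classes present in truth: ",
         paste(setdiff(classes, profile$class_names), collapse = ", "))
  called <- profile$membership[, classes, drop = FALSE]
  planted <- truth$membership
  per_class <- data.frame(
    class = classes,
    planted_positive = colSums(planted),
    called_positive = colSums(called),
    sensitivity = vapply(classes, function(c) {
      p <- planted[, c]
      if (!any(p)) NA_real_ else mean(called[p, c])
    }, numeric(1)),
    specificity = vapply(classes, function(c) {
      p <- planted[, c]
      if (all(p)) NA_real_ else mean(!called[!p, c])
    }, numeric(1)),
    row.names = NULL)
  n <- length(truth$cell_ids)
  planted_lbl <- truth$subsets
  called_lbl <- apply(called, 1, function(row)
    if (!any(row)) "none" else paste(classes[row], collapse = "+"))
  if (n == 0) called_lbl <- character()
  labels <- union(unique(planted_lbl), unique(called_lbl))
  labels <- labels[order(match(labels, c("none", labels)))]
  per_subset <- data.frame(
    subset = labels,
    planted_freq = as.numeric(table(factor(planted_lbl, labels))) / max(n, 1),
    called_freq = as.numeric(table(factor(called_lbl, labels))) / max(n, 1),
    row.names = NULL)
  per_subset$abs_error <- abs(per_subset$planted_freq -
                                per_subset$called_freq)
  structure(
    list(per_class = per_class, per_subset = per_subset,
         exact_subset_accuracy = if (n == 0) NA_real_
                                 else mean(planted_lbl == called_lbl),
         n_cells = n),
    class = "RecoveryReport")
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat(sprintf("RecoveryReport: %d cells, exact-subset accuracy %.4f\n",
              x$n_cells, x$exact_subset_accuracy))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
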