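#' Marker panel sets: neurotransmitter classes as gene lists
#'
#' A `MarkerPanelSet` maps neurotransmitter class names (e.g. "GABAergic",
#' "Cholinergic") to non-empty lists of marker-gene IDs: vesicular
#' transporters, biosynthetic enzymes and membrane transporters whose
#' expression defines the class. A cell is positive for a class when ANY
#' of the class's genes exceeds the expression threshold (see
#' [assign_classes()]), so partially resolvable panels remain usable.
#'
#' Gene entries may carry aliases in the form `"primary (alias1, alias2)"`;
#' resolution against a matrix tries the primary ID first, then each alias
#' in order.
#'
#' @param species species label.
#' @param classes named list, class name -> character vector of gene
#'   entries (possibly with aliases).
#' @param provenance optional named character vector of per-class citation
#'   notes.
#' @param gating optional gating-rule string recorded with the panel (the
#'   neuron-selection rule used upstream of classification).
#' @param class_groups optional named list mapping a merged class name to
#'   the member classes (e.g. aminergic subtypes collapsed into one
#'   category); applied via [merge_classes()].
#' @param allow_shared allow one gene to appear in several classes
#'   (disallowed by default; none of the shipped panels share genes).
#' @param notes free-text notes.
#' @return An object of class `MarkerPanelSet`.
#' @export
marker_panel_set <- function(species, classes, provenance = character(),
                             gating = NULL, class_groups = NULL,
                             allow_shared = FALSE, notes = NULL) {
  if (!length(classes)) stop("panel must declare at least one class")
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("every class needs a name")
  if (anyDuplicated(names(classes)))
    stop("duplicate class name: ",
         names(classes)[duplicated(names(classes))][1])
  parsed <- lapply(classes, function(entries) {
    entries <- as.character(unlist(entries))
    lapply(entries, parse_gene_entry)
  })
  for (cls in names(parsed))
    if (!length(parsed[[cls]]))
      stop("validation error: class '", cls, "' has an empty gene list")
  primaries <- lapply(parsed, vapply, function(e) e$primary, character(1))
  if (!allow_shared) {
    all_genes <- unlist(primaries, use.names = FALSE)
    if (anyDuplicated(all_genes)) {
      dup <- all_genes[duplicated(all_genes)][1]
      owners <- names(primaries)[vapply(primaries, function(g) dup %in% g,
                                        logical(1))]
      stop("validation error: gene '", dup, "' appears in classes ",
           paste(owners, collapse = " and "),
           " (set allow_shared = TRUE to permit)")
    }
  }
  structure(
    list(species = species, classes = primaries, entries = parsed,
         provenance = provenance, gating = gating,
         class_groups = class_groups, allow_shared = allow_shared,
         notes = notes),
    class = "MarkerPanelSet")
}

parse_gene_entry <- function(entry) {
  entry <- trimws(entry)
  m <- regmatches(entry, regexec("^([^()]+?)\\s*\\(([^()]+)\\)$", entry))[[1]]
  if (length(m) == 3) {
    list(primary = trimws(m[2]),
         aliases = trimws(strsplit(m[3], ",")[[1]]))
  } else {
    list(primary = entry, aliases = character())
  }
}

#' @export
print.MarkerPanelSet <- function(x, ...) {
  cat("MarkerPanelSet:", x$species, "-", length(x$classes), "classes\n")
  for (cls in names(x$classes))
    cat(sprintf("  %-16s %s\n", cls, paste(x$classes[[cls]],
                                           collapse = ", ")))
  if (!is.null(x$gating)) cat("  gating:", x$gating, "\n")
  invisible(x)
}

#' Class names of a panel set
#' @param panel a `MarkerPanelSet`.
#' @return Character vector in declaration order.
#' @export
panel_classes <- function(panel) names(panel$classes)

#' Load a marker panel set from a YAML (or JSON) config file
#'
#' The config carries `species`, `classes` (name -> gene-ID list, aliases
#' in `"primary (alias)"` form), and optionally `provenance`, `gating`,
#' `class_groups` and `notes`. Panels for the shipped species live under
#' `system.file("extdata", "panels", package = "cotransmitr")`.
#'
#' @param path config file path.
#' @param allow_shared permit a gene in more than one class.
#' @return A [marker_panel_set()].
#' @export
load_panel_config <- function(path, allow_shared = FALSE) {
  if (!file.exists(path)) stop("no such panel file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$classes))
    stop("validation error in ", path, ": no 'classes' section")
  prov <- unlist(cfg$provenance %||% character())
  marker_panel_set(
    species = cfg$species %||% basename(path),
    classes = cfg$classes,
    provenance = prov,
    gating = cfg$gating,
    class_groups = cfg$class_groups,
    allow_shared = isTRUE(cfg$allow_shared) || allow_shared,
    notes = cfg$notes)
}

#' Path to a shipped species panel
#' @param species fixture name, e.g. `"celegans"`, `"smed"`, `"hydra"`,
#'   `"drosophila"`, `"ciona"`, `"zebrafish"`, `"reptile"`, `"mouse"`.
#' @return File path of the YAML fixture.
#' @export
panel_fixture <- function(species) {
  p <- system.file("extdata", "panels", paste0(species, ".yaml"),
                   package = "cotransmitr")
  if (!nzchar(p)) stop("no shipped panel for '", species, "'")
  p
}

#' Resolve a marker panel against a matrix's gene universe
#'
#' Maps every class to the column indices of its genes present in the
#' matrix. Gene matching is exact and case-sensitive by default (the
#' shipped panels mix conventions such as "VAChT", "slc18a3a", "Gad1");
#' set `case_insensitive = TRUE` to fold case. Missing genes are reported;
#' a class with zero resolvable genes is excluded from downstream
#' classification with a warning, never an error.
#'
#' @param panel a `MarkerPanelSet`.
#' @param x an `ExpressionMatrix`.
#' @param case_insensitive fold case when matching gene IDs.
#' @return A `ResolvedPanelSet`: list with `classes` (class -> integer
#'   column indices), `missing` (class -> unresolved entries), `dropped`
#'   (classes with no resolvable gene), `class_names`, `species`.
#' @export
resolve_panels <- function(panel, x, case_insensitive = FALSE) {
  stopifnot(inherits(panel, "MarkerPanelSet"))
  universe <- gene_ids(x)
  key <- if (case_insensitive) tolower(universe) else universe
  fold <- if (case_insensitive) tolower else identity
  res <- list(); missing <- list()
  for (cls in names(panel$entries)) {
    idx <- integer(); miss <- character()
    for (e in panel$entries[[cls]]) {
      hit <- match(fold(c(e$primary, e$aliases)), key)
      hit <- hit[!is.na(hit)]
      if (length(hit)) idx <- c(idx, hit[1]) else miss <- c(miss, e$primary)
    }
    res[[cls]] <- sort(unique(idx))
    if (length(miss)) missing[[cls]] <- miss
  }
  dropped <- names(res)[lengths(res) == 0]
  if (length(dropped))
    warning("classes with no resolvable marker excluded: ",
            paste(dropped, collapse = ", "))
  structure(
    list(classes = res[lengths(res) > 0], missing = missing,
         dropped = dropped, class_names = names(res)[lengths(res) > 0],
         species = panel$species, case_insensitive = case_insensitive,
         class_groups = panel$class_groups),
    class = "ResolvedPanelSet")
}

#' @export
print.ResolvedPanelSet <- function(x, ...) {
  cat("ResolvedPanelSet:", x$species, "-", length(x$classes),
      "resolved classes\n")
  for (cls in names(x$classes))
    cat(sprintf("  %-16s %d gene(s)%s\n", cls, length(x$classes[[cls]]),
                if (!is.null(x$missing[[cls]]))
                  paste0(" [missing: ",
                         paste(x$missing[[cls]], collapse = ", "), "]")
                else ""))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
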