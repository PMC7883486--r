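#' Log-normalize counts with a fixed scale factor
#'
#' Per-cell normalization in the standard single-cell convention: for cell
#' i with library size \eqn{T_i = \sum_g c_{ig} > 0}, the normalized value
#' of a count \eqn{c} is \eqn{\ln(1 + c \cdot s / T_i)} with scale factor
#' \eqn{s} (default 10,000). The natural logarithm is used. Cells with
#' zero total get all-zero normalized rows, so degenerate inputs flow
#' through; the counts layer is left untouched and the zero pattern is
#' preserved exactly.
#'
#' @param x an `ExpressionMatrix`.
#' @param scale_factor positive scale factor \eqn{s}.
#' @return `x` with a `normalized` layer.
#' @export
log_normalize <- function(x, scale_factor = 10000) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      !is.finite(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be a positive number")
  m <- x$counts
  ti <- Matrix::rowSums(m)
  ti[ti == 0] <- 1          # zero-total rows have no entries to divide
  tm <- methods::as(m, "TsparseMatrix")
  norm <- Matrix::sparseMatrix(
    i = tm@i + 1L, j = tm@j + 1L,
    x = log1p(tm@x * scale_factor / ti[tm@i + 1L]),
    dims = dim(m), dimnames = dimnames(m))
  x$normalized <- as_cell_gene_sparse(norm)
  # log1p of a positive value is positive, so the pattern is unchanged
  dimnames(x$normalized) <- dimnames(m)
  x
}

# ---- gating-rule language --------------------------------------------------

#' Parse a boolean gating rule over gene-expression thresholds
#'
#' Grammar: `atom := GENE CMP NUMBER` with `CMP` one of `>`, `>=` (the
#' Unicode `≥` is accepted); expressions combine atoms with `and`,
#' `or`, `not` (case-insensitive; `&`, `|`, `!` are synonyms) and
#' parentheses. Precedence is NOT > AND > OR, left associative. A comma is
#' accepted as a synonym for the adjacent keyword connective, so the
#' published style `"nSyb > 1, elav > 1 and Syt1 > 1"` parses as the AND
#' of three atoms.
#'
#' @param text rule string.
#' @return A `GatingRule` expression tree.
#' @export
parse_gating_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- tokenize_rule(text)
  toks <- resolve_commas(toks, text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  tree <- parse_or(st)
  if (st$pos <= length(st$toks))
    rule_error(st, "unexpected trailing input")
  structure(tree, class = "GatingRule", source = text)
}

TOK_PATTERNS <- list(
  c("lparen", "\\("), c("rparen", "\\)"), c("comma", ","),
  c("cmp", ">=|≥|>"),
  c("number", "[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?|\\.[0-9]+"),
  c("word", "[A-Za-z0-9_./:-]+"),
  c("and", "&&?"), c("or", "\\|\\|?"), c("not", "!"))

tokenize_rule <- function(text) {
  toks <- list(); i <- 1L; n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { i <- i + nchar(ws); next }
    rest <- substr(text, i, n)
    matched <- FALSE
    for (p in TOK_PATTERNS) {
      m <- regmatches(rest, regexpr(paste0("^(", p[2], ")"), rest))
      if (length(m)) {
        type <- p[1]; val <- m
        if (type == "word") {
          lw <- tolower(val)
          if (lw %in% c("and", "or", "not")) type <- lw
        }
        toks[[length(toks) + 1L]] <- list(type = type, value = val, pos = i)
        i <- i + nchar(val); matched <- TRUE; break
      }
    }
    if (!matched)
      stop("syntax error at position ", i, ": unknown token near '",
           substr(text, i, min(n, i + 8)), "'")
  }
  toks
}

# A comma stands for whichever keyword connective sits next to it in the
# same parenthesis nesting level; the published rule strings write
# "a > 1, b > 1 and c > 1" for a conjunction.
resolve_commas <- function(toks, text) {
  if (!length(toks)) return(toks)
  depth <- integer(length(toks)); d <- 0L
  for (k in seq_along(toks)) {
    if (toks[[k]]$type == "lparen") d <- d + 1L
    depth[k] <- d
    if (toks[[k]]$type == "rparen") d <- d - 1L
  }
  for (k in seq_along(toks)) {
    if (toks[[k]]$type != "comma") next
    cand <- which(depth == depth[k] &
                    vapply(toks, function(t) t$type %in% c("and", "or"),
                           logical(1)))
    after <- cand[cand > k]
    before <- cand[cand < k]
    if (length(after)) toks[[k]]$type <- toks[[after[1]]]$type
    else if (length(before)) toks[[k]]$type <-
        toks[[before[length(before)]]]$type
    else stop("syntax error at position ", toks[[k]]$pos,
              ": comma with no adjacent 'and'/'or' to stand for")
    toks[[k]]$value <- toks[[k]]$type
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }
rule_error <- function(st, msg) {
  t <- peek(st)
  at <- if (is.null(t)) paste0("end of input (position ", nchar(st$text) + 1,
                               ")")
        else paste0("position ", t$pos, " ('", t$value, "')")
  stop("syntax error at ", at, ": ", msg, call. = FALSE)
}

parse_or <- function(st) {
  lhs <- parse_and(st)
  while (!is.null(peek(st)) && peek(st)$type == "or") {
    advance(st)
    lhs <- list(type = "or", lhs = lhs, rhs = parse_and(st))
  }
  lhs
}

parse_and <- function(st) {
  lhs <- parse_not(st)
  while (!is.null(peek(st)) && peek(st)$type == "and") {
    advance(st)
    lhs <- list(type = "and", lhs = lhs, rhs = parse_not(st))
  }
  lhs
}

parse_not <- function(st) {
  if (!is.null(peek(st)) && peek(st)$type == "not") {
    advance(st)
    return(list(type = "not", arg = parse_not(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  t <- peek(st)
  if (is.null(t)) rule_error(st, "expected an atom or '('")
  if (t$type == "lparen") {
    advance(st)
    inner <- parse_or(st)
    t2 <- peek(st)
    if (is.null(t2) || t2$type != "rparen")
      rule_error(st, "expected ')'")
    advance(st)
    return(inner)
  }
  if (t$type %in% c("word", "number")) {
    gene <- advance(st)$value
    cmp <- peek(st)
    if (is.null(cmp) || cmp$type != "cmp")
      rule_error(st, paste0("expected '>' or '>=' after gene '", gene, "'"))
    cmp <- advance(st)$value
    if (cmp == "≥") cmp <- ">="
    num <- peek(st)
    if (is.null(num) || num$type != "number")
      rule_error(st, "expected a numeric threshold")
    num <- advance(st)$value
    return(list(type = "atom", gene = gene, cmp = cmp,
                threshold = as.numeric(num)))
  }
  rule_error(st, "expected an atom or '('")
}

#' Render a gating rule back to its canonical string form
#' @param rule a `GatingRule`.
#' @return A single string that reparses to an equivalent tree.
#' @export
deparse_gating_rule <- function(rule) deparse_node(unclass(rule), 0L)

deparse_node <- function(node, parent_prec) {
  prec <- switch(node$type, atom = 4L, not = 3L, and = 2L, or = 1L)
  s <- switch(node$type,
    atom = paste(node$gene, node$cmp, format(node$threshold)),
    not = paste("not", deparse_node(node$arg, prec)),
    and = paste(deparse_node(node$lhs, prec), "and",
                deparse_node(node$rhs, prec + 1L)),
    or = paste(deparse_node(node$lhs, prec), "or",
               deparse_node(node$rhs, prec + 1L)))
  if (prec < parent_prec) paste0("(", s, ")") else s
}

#' @export
print.GatingRule <- function(x, ...) {
  cat("GatingRule:", deparse_gating_rule(x), "\n")
  invisible(x)
}

#' Evaluate a gating rule to a boolean cell mask
#'
#' Atoms referencing genes absent from the matrix evaluate FALSE for all
#' cells, with a warning (panels span genome versions, so a soft miss is
#' deliberate). The result is a pure function of the selected layer.
#'
#' @param x an `ExpressionMatrix`.
#' @param rule a `GatingRule` or rule string (parsed on the fly).
#' @param layer layer the thresholds apply to; the published "> 1" rules
#'   follow the convention of thresholding log-normalized values.
#' @return Named logical vector, one entry per cell.
#' @export
evaluate_gating_rule <- function(x, rule,
                                 layer = c("normalized", "counts")) {
  layer <- match.arg(layer)
  if (is.character(rule)) rule <- parse_gating_rule(rule)
  stopifnot(inherits(rule, "GatingRule"))
  m <- expression_layer(x, layer)
  mask <- eval_node(unclass(rule), m)
  names(mask) <- cell_ids(x)
  mask
}

eval_node <- function(node, m) {
  switch(node$type,
    atom = {
      j <- match(node$gene, colnames(m))
      if (is.na(j)) {
        warning("gene '", node$gene,
                "' absent from matrix; atom evaluates FALSE")
        rep(FALSE, nrow(m))
      } else {
        v <- as.numeric(m[, j])
        if (node$cmp == ">") v > node$threshold else v >= node$threshold
      }
    },
    not = !eval_node(node$arg, m),
    and = eval_node(node$lhs, m) & eval_node(node$rhs, m),
    or = eval_node(node$lhs, m) | eval_node(node$rhs, m),
    stop("malformed rule node"))
}

#' Subset cells by mask or explicit whitelist
#'
#' The whitelist path covers datasets whose neuron selection was done
#' upstream (cluster-identity whitelists supplied with the original
#' atlases); IDs absent from the matrix are an error naming them. An
#' empty result is legal and only warned about. Both layers are carried
#' over; because normalization is per-cell, normalize-then-subset equals
#' subset-then-normalize.
#'
#' @param x an `ExpressionMatrix`.
#' @param cells logical mask (length = number of cells) or character
#'   vector of cell IDs; the whitelist order is preserved.
#' @return A row-subset `ExpressionMatrix` with the full gene universe.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.logical(cells)) {
    if (length(cells) != nrow(x$counts))
      stop("mask length ", length(cells), " != number of cells ",
           nrow(x$counts))
    idx <- which(cells)
  } else {
    cells <- as.character(cells)
    idx <- match(cells, cell_ids(x))
    if (anyNA(idx))
      stop("unknown cell IDs: ",
           paste(cells[is.na(idx)], collapse = ", "))
  }
  if (!length(idx)) warning("cell subset is empty")
  out <- x
  out$counts <- x$counts[idx, , drop = FALSE]
  if (!is.null(x$normalized))
    out$normalized <- x$normalized[idx, , drop = FALSE]
  out
}
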