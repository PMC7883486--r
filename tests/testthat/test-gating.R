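test_that("log_normalize matches ln(1 + c*s/T) computed independently", {
  x <- dense_expr(matrix(c(2, 0, 8), nrow = 1))
  x <- log_normalize(x)
  expect_equal(as.numeric(x$normalized[1, ]),
               c(log(2001), 0, log(8001)), tolerance = 1e-14)

  # independent evaluation path: log(T + c*s) - log(T)
  set.seed(41)
  m <- matrix(rpois(300, 3), nrow = 15,
              dimnames = list(sprintf("c%d", 1:15), sprintf("g%d", 1:20)))
  xn <- log_normalize(ExpressionMatrix(m))
  ti <- rowSums(m)
  ref <- log(sweep(m * 10000, 1, ti, "+")) - log(ti)
  ref[m == 0] <- 0
  got <- as.matrix(xn$normalized)
  rel <- abs(got - ref) / pmax(abs(ref), .Machine$double.xmin)
  expect_lt(max(rel[m > 0]), 1e-12)
})

test_that("normalization handles degenerate cells and scale choices", {
  # zero-total cell stays all-zero
  m <- rbind(c(1, 2), c(0, 0))
  x <- log_normalize(dense_expr(m))
  expect_equal(as.numeric(x$normalized[2, ]), c(0, 0))
  # T equal to the scale factor: values reduce to ln(1 + c)
  m2 <- matrix(c(9999, 1), nrow = 1)
  x2 <- log_normalize(dense_expr(m2))
  expect_equal(as.numeric(x2$normalized[1, ]), log(1 + c(9999, 1)))
  expect_error(log_normalize(x, scale_factor = 0), "positive")
  expect_error(log_normalize(x, scale_factor = -5), "positive")
})

test_that("normalization preserves the zero pattern and monotonicity", {
  set.seed(42)
  m <- matrix(rpois(600, 0.6), nrow = 30)
  x <- log_normalize(dense_expr(m))
  n <- as.matrix(x$normalized)
  expect_identical(unname(n == 0), unname(m == 0))
  # strictly monotone in c within each cell
  for (i in seq_len(nrow(m))) {
    ord <- order(m[i, ])
    expect_true(all(diff(n[i, ord]) >= 0))
    expect_true(all(diff(n[i, ord])[diff(m[i, ord]) > 0] > 0))
  }
})

test_that("normalize-then-subset-cells equals subset-cells-then-normalize", {
  set.seed(43)
  m <- matrix(rpois(200, 2), nrow = 20,
              dimnames = list(sprintf("c%d", 1:20), sprintf("g%d", 1:10)))
  x <- ExpressionMatrix(m)
  keep <- sprintf("c%d", c(17, 3, 8))
  a <- subset_cells(log_normalize(x), keep)
  b <- log_normalize(subset_cells(x, keep))
  expect_equal(as.matrix(a$normalized), as.matrix(b$normalized))
})

test_that("the rule grammar parses atoms, precedence and synonyms", {
  r <- parse_gating_rule("Syt1 > 1")
  expect_equal(unclass(r)[c("type", "gene", "cmp", "threshold")],
               list(type = "atom", gene = "Syt1", cmp = ">",
                    threshold = 1))

  r3 <- parse_gating_rule("nSyb > 1 and elav > 1 and Syt1 > 1")
  expect_equal(deparse_gating_rule(r3),
               "nSyb > 1 and elav > 1 and Syt1 > 1")

  # published comma style parses as the adjacent keyword connective
  r_comma <- parse_gating_rule("nSyb > 1, elav > 1 and Syt1 > 1")
  expect_equal(deparse_gating_rule(r_comma), deparse_gating_rule(r3))

  # NOT > AND > OR, parentheses override
  r_prec <- parse_gating_rule("a > 1 or b > 1 and not c > 2")
  expect_equal(deparse_gating_rule(r_prec),
               "a > 1 or b > 1 and not c > 2")
  r_par <- parse_gating_rule("(a > 1 or b > 1) and c >= 0.5")
  expect_equal(deparse_gating_rule(r_par),
               "(a > 1 or b > 1) and c >= 0.5")
  expect_equal(deparse_gating_rule(parse_gating_rule("g ≥ 2")), "g >= 2")
  expect_equal(deparse_gating_rule(parse_gating_rule("a > 1 & b > 1 | !c > 0")),
               "a > 1 and b > 1 or not c > 0")
})

test_that("rule syntax errors carry a position", {
  expect_error(parse_gating_rule("Syt1 >"), "syntax error at")
  expect_error(parse_gating_rule("Syt1 > 1 and"), "syntax error at")
  expect_error(parse_gating_rule("(a > 1"), "expected '\\)'")
  expect_error(parse_gating_rule("a > 1, b > 2"), "comma")
  expect_error(parse_gating_rule("a § 1"), "unknown token")
})

test_that("rule evaluation uses strict thresholds and soft absent genes", {
  norm <- matrix(c(1.0, 1.2, 0.4), nrow = 1)
  x <- ExpressionMatrix(matrix(c(1, 1, 1), nrow = 1,
                               dimnames = list("c1", c("E", "G", "H"))),
                        normalized = norm)
  expect_false(evaluate_gating_rule(x, "E > 1")[["c1"]])   # boundary
  expect_true(evaluate_gating_rule(x, "E >= 1")[["c1"]])
  expect_false(evaluate_gating_rule(x, "G > 1 and H > 1")[["c1"]])
  expect_true(evaluate_gating_rule(x, "G > 1 or H > 1")[["c1"]])
  expect_warning(res <- evaluate_gating_rule(x, "Z > 1 or G > 1"),
                 "absent from matrix")
  expect_true(res[["c1"]])
})

test_that("composite rules equal elementwise composition of atom masks", {
  set.seed(44)
  m <- matrix(rpois(400, 2), nrow = 40,
              dimnames = list(sprintf("c%d", 1:40), c(letters[1:10])))
  x <- log_normalize(ExpressionMatrix(m))
  a <- evaluate_gating_rule(x, "a > 1")
  b <- evaluate_gating_rule(x, "b > 1")
  c_ <- evaluate_gating_rule(x, "c >= 2")
  expect_identical(evaluate_gating_rule(x, "a > 1 and b > 1"), a & b)
  expect_identical(evaluate_gating_rule(x, "a > 1 or b > 1"), a | b)
  expect_identical(evaluate_gating_rule(x, "not a > 1"), !a)
  expect_identical(evaluate_gating_rule(x, "a > 1 and (b > 1 or c >= 2)"),
                   a & (b | c_))
  # pure function of the selected layer
  expect_identical(evaluate_gating_rule(x, "a > 1", layer = "counts"),
                   stats::setNames(m[, "a"] > 1, rownames(m)))
})

test_that("subset_cells honours masks, whitelists and error contracts", {
  m <- matrix(seq_len(10), nrow = 5,
              dimnames = list(sprintf("c%d", 1:5), c("g1", "g2")))
  x <- log_normalize(ExpressionMatrix(m))
  expect_equal(as.matrix(subset_cells(x, rep(TRUE, 5))$counts),
               as.matrix(x$counts))
  w <- subset_cells(x, c("c4", "c2"))
  expect_equal(cell_ids(w), c("c4", "c2"))
  expect_equal(gene_ids(w), gene_ids(x))
  expect_equal(dim(w$normalized), c(2L, 2L))
  expect_error(subset_cells(x, c("c2", "nope")), "unknown cell IDs: nope")
  expect_error(subset_cells(x, rep(TRUE, 4)), "mask length")
  expect_warning(subset_cells(x, rep(FALSE, 5)), "empty")
})
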