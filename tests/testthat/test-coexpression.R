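test_that("assign_classes implements OR-over-markers with strict threshold", {
  panel <- marker_panel_set("h", list(GABA = "PNPO", ACh = "ChT"))
  norm <- matrix(c(1.5, 0.3), nrow = 1,
                 dimnames = list("c1", c("PNPO", "ChT")))
  x <- ExpressionMatrix(matrix(c(2, 1), 1,
                               dimnames = dimnames(norm)),
                        normalized = norm)
  prof <- assign_classes(x, panel)
  expect_identical(prof$membership,
                   matrix(c(TRUE, FALSE), 1,
                          dimnames = list("c1", c("GABA", "ACh"))))

  # any one marker suffices for the class call
  chol <- marker_panel_set("ce", list(Chol = c("cha-1", "unc-17",
                                               "cho-1")))
  norm2 <- matrix(c(0, 2, 0), 1,
                  dimnames = list("c1", c("cha-1", "unc-17", "cho-1")))
  x2 <- ExpressionMatrix((norm2 > 0) * 1, normalized = norm2)
  expect_true(assign_classes(x2, chol)$membership[1, "Chol"])

  # values exactly at the threshold do not pass (strict >)
  norm3 <- matrix(c(1, 1, 1), 1, dimnames = dimnames(norm2))
  x3 <- ExpressionMatrix(norm3, normalized = norm3)
  expect_false(assign_classes(x3, chol)$membership[1, "Chol"])
})

test_that("combination_counts matches enumeration on the tiny example", {
  mem <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, FALSE))
  dimnames(mem) <- list(c("c1", "c2", "c3"), c("G", "A"))
  cc <- combination_counts(class_profile(mem))
  expect_equal(cc$exclusive[c("none", "G", "A", "G+A")],
               c(none = 1L, G = 1L, A = 0L, `G+A` = 1L))
  expect_equal(cc$inclusive[c("none", "G", "A", "G+A")],
               c(none = 3L, G = 2L, A = 1L, `G+A` = 1L))
  expect_equal(cc$total_cells, 3L)

  all_empty <- class_profile(matrix(FALSE, 4, 2,
                                    dimnames = list(sprintf("c%d", 1:4),
                                                    c("G", "A"))))
  cc2 <- combination_counts(all_empty)
  expect_equal(cc2$exclusive[["none"]], 4L)
  expect_true(all(cc2$inclusive[names(cc2$inclusive) != "none"] == 0))
})

test_that("combination_counts equals the brute-force oracle on random profiles", {
  set.seed(101)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    prof <- random_profile(sample(1:200, 1), LETTERS[1:k],
                           p = runif(1, 0.1, 0.7))
    expect_same_counts(combination_counts(prof),
                       oracle_counts(prof$membership))
  }
})

test_that("the inclusive/exclusive transforms satisfy the Moebius identities", {
  set.seed(102)
  for (rep in 1:50) {
    k <- sample(1:5, 1)
    cls <- LETTERS[1:k]
    prof <- random_profile(sample(1:100, 1), cls, p = runif(1, 0.1, 0.8))
    cc <- combination_counts(prof)
    expect_identical(sum(cc$exclusive), nrow(prof$membership))
    expect_equal(cc$inclusive[["none"]], cc$total_cells)
    # transforms round-trip with integer equality
    incl <- inclusive_from_exclusive(cc$exclusive, cls)
    expect_equal(unname(incl), as.numeric(cc$inclusive))
    back <- exclusive_from_inclusive(cc$inclusive, cls,
                                     total_cells = cc$total_cells)
    expect_equal(unname(back), as.numeric(cc$exclusive))
    # monotone along the subset order
    for (lbl in names(cc$inclusive)) {
      if (lbl == "none") next
      parts <- strsplit(lbl, "+", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      sub_lbl <- paste(parts[-length(parts)], collapse = "+")
      expect_gte(cc$inclusive[[sub_lbl]], cc$inclusive[[lbl]])
    }
  }
})

test_that("non-realizable inclusive maps are rejected with the subset named", {
  cls <- c("G", "A")
  expect_error(
    exclusive_from_inclusive(c(G = 1, A = 1, `G+A` = 2), cls,
                             total_cells = 10),
    "data-consistency error")
  # union exceeding pairwise overlaps: exclusive(G) would be negative
  expect_error(
    exclusive_from_inclusive(c(G = 2, A = 5, `G+A` = 2), cls,
                             total_cells = 1),
    "data-consistency error")
  # single class: exclusive equals inclusive
  one <- exclusive_from_inclusive(c(G = 7), "G", total_cells = 10)
  expect_equal(one, c(none = 3, G = 7))
})

test_that("the published tunicate counts decompose as inclusive counts", {
  cls <- c("GABA", "ACh", "Glut")
  incl <- c(GABA = 495, ACh = 152, Glut = 19,
            `GABA+ACh` = 134, `GABA+Glut` = 18, `ACh+Glut` = 2,
            `GABA+ACh+Glut` = 2)
  excl <- exclusive_from_inclusive(incl, cls, total_cells = 644)
  expect_true(all(excl >= 0))
  expect_equal(excl[["Glut"]], 1)
  expect_equal(excl[["GABA+ACh"]], 132)
  expect_equal(excl[["GABA+Glut"]], 16)
  expect_equal(excl[["ACh+Glut"]], 0)
  expect_equal(excl[["GABA"]], 345)
  expect_equal(excl[["ACh"]], 18)
  expect_equal(excl[["GABA+ACh+Glut"]], 2)
  expect_equal(sum(excl[names(excl) != "none"]), 514)  # union
  expect_equal(excl[["none"]], 130)

  # oracle: realize the exclusives as an actual cell population and
  # recount inclusives per cell
  mem <- do.call(rbind, lapply(names(excl), function(lbl) {
    n <- excl[[lbl]]
    if (n == 0) return(NULL)
    row <- cls %in% strsplit(lbl, "+", fixed = TRUE)[[1]]
    matrix(rep(row, n), ncol = 3, byrow = TRUE)
  }))
  colnames(mem) <- cls
  rownames(mem) <- sprintf("cell%d", seq_len(nrow(mem)))
  expect_equal(nrow(mem), 644)
  recount <- oracle_counts(mem)
  expect_equal(recount$inclusive[names(incl)], incl,
               ignore_attr = FALSE, tolerance = 0)

  # under the alternative reading (singletons counting cells with ONLY
  # that transmitter, i.e. exclusive singletons alongside inclusive
  # duals) the lattice is not realizable: the glutamatergic total would
  # have to absorb 18 + 2 + 2 > 19 overlap cells, so the transform must
  # reject a map where the duals are raised above the singleton
  alt <- incl
  alt[["GABA+Glut"]] <- 20  # any overlap exceeding the Glut singleton
  expect_error(exclusive_from_inclusive(alt, cls, total_cells = 644),
               "data-consistency error")
})

test_that("raising the threshold never increases any inclusive count", {
  set.seed(103)
  panel <- toy_panel(3, markers_per_class = 2)
  params <- simulation_params(400, panel,
                              c(none = 0.3, A = 0.2, B = 0.2,
                                `A+B` = 0.15, `A+B+C` = 0.15),
                              mu_marker = 8, mu_background = 0.5,
                              dispersion = 1, seed = 9)
  x <- log_normalize(generate_dataset(params)$matrix)
  prev <- NULL
  for (thr in c(0.5, 1, 2, 4)) {
    cc <- combination_counts(assign_classes(x, panel, threshold = thr))
    if (!is.null(prev)) expect_true(all(cc$inclusive <= prev))
    prev <- cc$inclusive
  }
})

test_that("permuting cells or classes permutes outputs consistently", {
  set.seed(104)
  prof <- random_profile(120, c("X", "Y", "Z"))
  cc <- combination_counts(prof)
  perm_cells <- sample(nrow(prof$membership))
  cc_cells <- combination_counts(
    class_profile(prof$membership[perm_cells, , drop = FALSE]))
  expect_identical(cc_cells$exclusive, cc$exclusive)
  perm <- c("Z", "X", "Y")
  cc_cls <- combination_counts(
    class_profile(prof$membership[, perm, drop = FALSE]))
  relabel <- function(lbl) {
    if (lbl == "none") return("none")
    parts <- strsplit(lbl, "+", fixed = TRUE)[[1]]
    paste(perm[sort(match(parts, perm))], collapse = "+")
  }
  for (lbl in names(cc$exclusive))
    expect_identical(cc_cls$exclusive[[relabel(lbl)]],
                     cc$exclusive[[lbl]])
})

test_that("binary_expression_matrix thresholds genes like singleton panels", {
  norm <- matrix(c(2, 0, 0.5, 3), 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("r1", "r2")))
  x <- ExpressionMatrix((norm > 0) * 5, normalized = norm)
  b <- binary_expression_matrix(x, c("r1", "r2"), threshold = 1)
  expect_identical(b, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, byrow = TRUE,
                             dimnames = dimnames(norm)))
  expect_warning(b2 <- binary_expression_matrix(x, c("r1", "zz")),
                 "absent")
  expect_false(any(b2[, "zz"]))
  panel <- marker_panel_set("t", list(r1 = "r1", r2 = "r2"))
  expect_identical(unname(b),
                   unname(assign_classes(x, panel)$membership))
})

test_that("proportions are percentages of total and conserve mass", {
  # 5 positive cells out of 100
  mem <- matrix(FALSE, 100, 1, dimnames = list(sprintf("c%d", 1:100), "G"))
  mem[1:5, 1] <- TRUE
  cc <- combination_counts(class_profile(mem))
  p <- combination_proportions(cc)
  expect_equal(p[["G"]], 5.0)
  expect_equal(sum(p), 100)
  empty <- combination_counts(class_profile(
    matrix(FALSE, 0, 1, dimnames = list(NULL, "G"))))
  expect_error(combination_proportions(empty), "undefined")
})

test_that("dataset comparison is antisymmetric and descriptive", {
  mkcounts <- function(n, pos) {
    mem <- matrix(FALSE, n, 2, dimnames = list(sprintf("c%d", 1:n),
                                               c("G", "A")))
    if (pos > 0) mem[seq_len(pos), ] <- TRUE
    combination_counts(class_profile(mem))
  }
  a <- mkcounts(100, 10); b <- mkcounts(100, 5)
  cmp <- compare_datasets(a, b, "larva", "adult")
  row <- cmp[cmp$subset == "G+A", ]
  expect_equal(row$diff_pct, 5)
  expect_equal(row$ratio, 2)
  expect_true(all(c("pct_larva", "pct_adult") %in% names(cmp)))
  swapped <- compare_datasets(b, a, "adult", "larva")
  expect_equal(swapped$diff_pct, -cmp$diff_pct)
  expect_equal(swapped$ratio[cmp$ratio > 0 & is.finite(cmp$ratio)],
               1 / cmp$ratio[cmp$ratio > 0 & is.finite(cmp$ratio)])
  ident <- compare_datasets(a, a)
  expect_true(all(ident$diff_pct == 0))

  # disjoint class universes cannot be compared
  memx <- matrix(FALSE, 5, 1, dimnames = list(sprintf("c%d", 1:5), "X"))
  expect_error(compare_datasets(a, combination_counts(
    class_profile(memx))), "comparability error")
})

test_that("merge_classes unions membership columns", {
  mem <- cbind(Ser = c(TRUE, FALSE, FALSE), Dop = c(FALSE, TRUE, FALSE),
               ACh = c(FALSE, TRUE, TRUE))
  rownames(mem) <- sprintf("c%d", 1:3)
  prof <- class_profile(mem)
  merged <- merge_classes(prof, list(Aminergic = c("Ser", "Dop")))
  expect_equal(colnames(merged$membership), c("Aminergic", "ACh"))
  expect_equal(unname(merged$membership[, "Aminergic"]),
               c(TRUE, TRUE, FALSE))
  expect_error(merge_classes(prof, list(X = "nope")), "unknown classes")
})
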