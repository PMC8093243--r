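# Panel joining, correlation screen, extreme labeling, and RFE-SVM
# signature selection.

test_that("panel join restricts both objects to shared lines, in order", {
  vals <- matrix(rnorm(12), 3,
                 dimnames = list(paste0("g", 1:3), c("A", "B", "C", "D")))
  expr <- expr_matrix(abs(vals) * 10, unit = "CPM")
  resp <- data.frame(cell_line = c("B", "C", "D", "E"), auc = 1:4)
  expect_error(join_panel(expr, resp), "shared cell lines")
  j <- suppressMessages(join_panel(expr, resp, min_shared = 2))
  expect_equal(colnames(j$expr), c("B", "C", "D"))
  expect_equal(j$resp$cell_line, c("B", "C", "D"))
  # identical sets: identity
  j2 <- suppressMessages(join_panel(j$expr, j$resp, min_shared = 2))
  expect_equal(unclass(j2$expr)[, ], unclass(j$expr)[, ])
})

test_that("per-gene PCC matches the textbook formula and flags degeneracy", {
  mk <- function(rows) expr_matrix(
    matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
           dimnames = list(names(rows), c("l1", "l2", "l3"))),
    unit = "logCPM")
  expr <- mk(list(gpos = c(1, 2, 3), gneg = c(1, 2, 3), godd = c(1, 2, 4)))
  resp <- data.frame(cell_line = c("l1", "l2", "l3"), auc = c(2, 4, 6))
  ct <- correlate_expression_response(expr, resp)
  expect_equal(ct$pcc[ct$gene == "gpos"], 1.0)
  resp$auc <- c(6, 4, 2)
  ct <- correlate_expression_response(expr, resp)
  expect_equal(ct$pcc[ct$gene == "gneg"], -1.0)
  resp$auc <- c(1, 3, 3)
  ct <- correlate_expression_response(expr, resp)
  expect_equal(ct$pcc[ct$gene == "godd"],
               oracle_pcc(c(1, 2, 4), c(1, 3, 3)), tolerance = 1e-12)
  expect_equal(ct$n, rep(3L, 3), ignore_attr = TRUE)

  flat <- mk(list(gflat = c(2, 2, 2), gok = c(1, 2, 3)))
  expect_warning(ct <- correlate_expression_response(flat, resp),
                 "zero-variance")
  expect_equal(ct$gene, "gok")
})

test_that("top-marker selection orders by PCC with a stable ID tie-break", {
  ct <- data.frame(gene = c("g1", "g2", "g3"), pcc = c(0.9, 0.1, -0.5), n = 5)
  expect_equal(select_top_markers(ct, 2), c("g1", "g2"))
  expect_equal(select_top_markers(ct, 3), c("g1", "g2", "g3"))
  expect_error(select_top_markers(ct, 4), "exceeds")
  tie <- data.frame(gene = c("gB", "gA", "gC"), pcc = c(0.5, 0.5, 0.9), n = 5)
  expect_equal(select_top_markers(tie, 2), c("gC", "gA"))
  # output PCCs are non-increasing
  set.seed(3)
  ct <- data.frame(gene = sprintf("g%03d", 1:50), pcc = runif(50, -1, 1), n = 9)
  sel <- select_top_markers(ct, 20)
  expect_true(all(diff(ct$pcc[match(sel, ct$gene)]) <= 0))
})

test_that("extreme labeling takes the AUC tails by interpolated quantiles", {
  resp <- data.frame(cell_line = sprintf("c%03d", 1:100), auc = 1:100)
  lab <- label_extremes(resp)
  expect_equal(sum(lab$label == "sensitive"), 5)
  expect_equal(sum(lab$label == "resistant"), 5)
  expect_setequal(lab$cell_line[lab$label == "sensitive"], sprintf("c%03d", 1:5))
  expect_setequal(lab$cell_line[lab$label == "resistant"], sprintf("c%03d", 96:100))

  r20 <- data.frame(cell_line = letters[1:20], auc = 1:20)
  lab20 <- label_extremes(r20)
  expect_equal(as.vector(table(lab20$label)[c("sensitive", "resistant")]),
               c(1, 1))

  expect_error(label_extremes(data.frame(cell_line = letters[1:20], auc = 1)),
               "degenerate response")
  expect_error(label_extremes(resp, low_q = 0.6, high_q = 0.4), "overlap")
})

test_that("RFE-SVM keeps separating features and honors the size contract", {
  # 2 perfectly separating features + 2 pure noise, target 2
  set.seed(71)
  n <- 16
  y <- rep(c("sensitive", "resistant"), each = n / 2)
  sep1 <- ifelse(y == "resistant", 2, -2) + rnorm(n, sd = 0.1)
  sep2 <- ifelse(y == "resistant", -3, 3) + rnorm(n, sd = 0.1)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  vals <- rbind(gsep1 = sep1, gsep2 = sep2, gnoiseA = noise1, gnoiseB = noise2)
  colnames(vals) <- sprintf("L%02d", 1:n)
  expr <- expr_matrix(vals, unit = "logCPM")
  labels <- data.frame(cell_line = colnames(vals), label = y)
  sig <- rfe_svm_select(expr, labels, target = 2, seed = 1)
  expect_setequal(as.character(sig), c("gsep1", "gsep2"))
  # independent confirmation that the survivors really separate the classes:
  # each kept feature alone classifies perfectly by its sign
  expect_true(all(sign(vals["gsep1", ]) == ifelse(y == "resistant", 1, -1)))

  # target = starting size: no elimination
  all4 <- rfe_svm_select(expr, labels, target = 4, seed = 1)
  expect_setequal(as.character(all4), rownames(vals))

  # size contract holds under random labels
  set.seed(72)
  vals <- matrix(rnorm(100 * 24), 100,
                 dimnames = list(sprintf("g%03d", 1:100), sprintf("L%02d", 1:24)))
  labels <- data.frame(cell_line = colnames(vals),
                       label = sample(rep(c("sensitive", "resistant"), 12)))
  sig <- rfe_svm_select(expr_matrix(vals, unit = "logCPM"), labels,
                        target = 50, seed = 2)
  expect_length(sig, 50)
  expect_false(anyDuplicated(sig) > 0)

  expect_error(rfe_svm_select(expr_matrix(vals, unit = "logCPM"),
                              data.frame(cell_line = colnames(vals),
                                         label = "sensitive"),
                              target = 10, seed = 1),
               "both classes")
  expect_error(rfe_svm_select(expr_matrix(vals, unit = "logCPM"), labels,
                              target = 200, seed = 1),
               "target exceeds")
})

test_that("RFE-SVM is invariant to feature-order permutation", {
  set.seed(73)
  panel <- small_panel()
  lcpm <- expr_matrix(log2(unclass(cpm_normalize(panel$counts)) + 1),
                      unit = "logCPM")
  labels <- label_extremes(panel$resp, low_q = 0.2, high_q = 0.8)
  genes <- rownames(lcpm)[1:60]
  a <- rfe_svm_select(lcpm, labels, genes = genes, target = 20, seed = 5)
  b <- rfe_svm_select(lcpm, labels, genes = rev(genes), target = 20, seed = 5)
  expect_setequal(as.character(a), as.character(b))
})

test_that("the pipeline recovers planted markers on a small panel", {
  panel <- small_panel()
  cpm <- cpm_normalize(panel$counts)
  sig <- suppressMessages(
    build_signature(cpm, panel$resp, top_k = 100, target = 40,
                    low_q = 0.1, high_q = 0.9, seed = 7))
  top <- attr(sig, "pcc_top")
  expect_gte(sum(panel$truth$markers %in% top), 18)   # 20 planted
  expect_gte(sum(panel$truth$markers %in% sig), 12)
})

test_that("with no planted effect, marker counts match the hypergeometric null", {
  panel <- simulate_ccl_panel(n_lines = 60, n_genes = 400, n_markers = 40,
                              beta = 0, gamma = 1, seed = 202)
  cpm <- cpm_normalize(panel$counts)
  lcpm <- expr_matrix(log2(unclass(cpm) + 1), unit = "logCPM")
  ct <- correlate_expression_response(lcpm, panel$resp)
  top <- select_top_markers(ct, 100)
  hits <- sum(panel$truth$markers %in% top)
  m <- sum(panel$truth$markers %in% ct$gene)
  N <- nrow(ct)
  mu <- 100 * m / N
  sdv <- sqrt(100 * (m / N) * (1 - m / N) * (N - 100) / (N - 1))
  expect_lt(abs(hits - mu), 3 * sdv)
})
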