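test_that("the packaged channel list has the 145 classified genes", {
  cl <- channel_gene_list()
  expect_equal(nrow(cl), 145)
  expect_false(anyDuplicated(cl$gene) > 0)
  expect_true(all(c("Kcnma1", "Kcnd3", "Cacna1a", "Scn8a", "Hcn1") %in% cl$gene))
  expect_true(all(!is.na(cl$subfamily)))
})

test_that("subsetting keeps channel genes in list order and reports missing", {
  tb <- simulate_expression_table(n_genes = 500, n_signif_channels = 5, seed = 2)
  sub <- subset_channels(tb)
  expect_equal(nrow(sub), 145)
  expect_equal(sub$gene, channel_gene_list()$gene)

  # genes absent from the table are reported, not fatal
  small <- tb[tb$gene %in% c("Kcnma1", "Kcnc3"), ]
  expect_message(sub2 <- subset_channels(small), "absent")
  expect_equal(nrow(sub2), 2)
  expect_equal(length(attr(sub2, "missing_genes")), 143)

  # empty intersection: empty table plus a full missing report
  none <- tb[!tb$is_channel, ][1:10, ]
  suppressMessages(sub3 <- subset_channels(none))
  expect_equal(nrow(sub3), 0)
  expect_equal(length(attr(sub3, "missing_genes")), 145)

  # duplicated symbols violate the uniqueness invariant
  expect_error(subset_channels(rbind(tb, tb[1, ])), "unique")
})

test_that("significance is inclusive at q = 0.05 and NA-safe", {
  tb <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       fold_change = c(2, 0.5, 1, 1.2),
                       p_value = c(0.01, 0.02, 0.5, NA),
                       q_value = c(0.05, 0.050001, 0.9, NA))
  fl <- flag_significant(tb)
  expect_identical(fl$significant, c(TRUE, FALSE, FALSE, NA))
  expect_error(flag_significant(tb, q_cut = 1.5), "probability")
})

test_that("log2 heat-map matrix transforms fold changes as expected", {
  t5 <- structure(tibble::tibble(gene = c("g1", "g2", "g3"),
                                 fold_change = c(1, 0.5, 2),
                                 p_value = 0.01, q_value = c(0.2, 0.01, 0.01)),
                  class = c("gene_table", class(tibble::tibble())),
                  timepoint = "5wk")
  t12 <- structure(tibble::tibble(gene = c("g1", "g2", "g3"),
                                  fold_change = c(1, 2, 0.25),
                                  p_value = 0.01, q_value = c(0.2, 0.2, 0.01)),
                   class = c("gene_table", class(tibble::tibble())),
                   timepoint = "12wk")
  m <- log2_heatmap_matrix(list(t5, t12))
  expect_equal(unname(m["g1", ]), c(0, 0))
  expect_equal(unname(m["g2", ]), c(-1, 1))
  expect_equal(unname(m["g3", ]), c(1, -2))
  expect_equal(colnames(m), c("5wk", "12wk"))

  # inverting the ratio negates the entry
  t5_inv <- t5
  t5_inv$fold_change <- 1 / t5$fold_change
  m_inv <- log2_heatmap_matrix(list(t5_inv, t12))
  expect_equal(m_inv[, "5wk"], -m[, "5wk"])

  # significant-only filtering keeps rows significant somewhere, masks others
  ms <- log2_heatmap_matrix(list(flag_significant(t5), flag_significant(t12)),
                            significant_only = TRUE)
  expect_setequal(rownames(ms), c("g2", "g3"))
  expect_true(is.na(ms["g2", "12wk"]))
  expect_equal(ms["g3", "12wk"], -2)

  bad <- t5
  bad$fold_change[1] <- 0
  expect_error(log2_heatmap_matrix(list(bad)), "positive")
})

test_that("persistent set is the signed intersection of significant sets", {
  cl <- channel_gene_list()
  shared <- c("Kcnma1", "Kcnc3", "Cacna1g")
  t5 <- simulate_expression_table(
    n_genes = 400, signif_channel_genes = c(shared, "Kcnd3"), seed = 3)
  t12 <- simulate_expression_table(
    n_genes = 400, signif_channel_genes = c(shared, "Trpc3"), seed = 4)
  f5 <- flag_significant(subset_channels(t5))
  f12 <- flag_significant(subset_channels(t12))
  pers <- persistent_dysregulated(f5, f12)
  expect_setequal(pers$gene, shared)
  expect_true(all(pers$direction_5wk %in% c("up", "down")))
  expect_lte(nrow(pers), min(sum(f5$significant), sum(f12$significant)))

  # disjoint significant sets give an empty result
  t_a <- flag_significant(subset_channels(
    simulate_expression_table(n_genes = 400, signif_channel_genes = "Kcnq2", seed = 5)))
  t_b <- flag_significant(subset_channels(
    simulate_expression_table(n_genes = 400, signif_channel_genes = "Hcn2", seed = 6)))
  expect_equal(nrow(persistent_dysregulated(t_a, t_b)), 0)

  expect_error(persistent_dysregulated(t5, f12), "flagged")
})

test_that("subset-then-flag commutes with flag-then-subset", {
  tb <- simulate_expression_table(n_genes = 600, n_signif_channels = 9, seed = 7)
  a <- flag_significant(subset_channels(tb))
  b <- subset_channels(flag_significant(tb))
  expect_equal(a$gene, b$gene)
  expect_equal(a$significant, b$significant)
})

test_that("gene tables survive a CSV round trip", {
  tb <- simulate_expression_table(n_genes = 200, n_signif_channels = 4, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gene_table(tb, path)
  back <- read_gene_table(path, timepoint = "5wk")
  expect_equal(back$gene, tb$gene)
  expect_equal(back$q_value, tb$q_value, tolerance = 1e-12)
  expect_equal(attr(back, "timepoint"), "5wk")
  expect_error(read_gene_table("table.pdf"), "unsupported")
})
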