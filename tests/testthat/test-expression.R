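make_matrix <- function(values, groups = NULL, map = NULL) {
  if (is.null(groups))
    groups <- setNames(rep(c("case", "control"),
                           length.out = ncol(values)), colnames(values))
  expression_matrix(values, groups, map)
}

test_that("parse_matrix reads TSV and rejects malformed tables", {
  tsv <- c("probe\ts1\ts2", "p1\t1.5\t2.5", "p2\t3\t4")
  labels <- c(s1 = "case", s2 = "control")
  m <- parse_matrix(tsv, "tsv", group_labels = labels)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(m$values["p1", "s2"], 2.5)
  expect_equal(m$values["p2", "s1"], 3)

  expect_error(parse_matrix("probe\ts1\ts2", "tsv", group_labels = labels),
               "empty")
  expect_error(parse_matrix(c(tsv, "p3\t9"), "tsv", group_labels = labels),
               "ragged")
  expect_error(parse_matrix(c(tsv, "p1\t5\t6"), "tsv", group_labels = labels),
               "duplicate probe id: p1")
  expect_error(parse_matrix(c(tsv, "p3\tx\t6"), "tsv", group_labels = labels),
               "non-numeric")
})

test_that("SOFT dialect extracts the data table and subset-derived groups", {
  soft <- c(
    "^DATASET = GDS_test",
    "!dataset_title = synthetic example",
    "^SUBSET = GDS_test_1",
    "!subset_description = glioblastoma",
    "!subset_sample_id = GSM1,GSM2",
    "^SUBSET = GDS_test_2",
    "!subset_description = non-tumor",
    "!subset_sample_id = GSM3,GSM4",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3\tGSM4",
    "p1\tGENE1\t5\t6\t1\t2",
    "p2\tGENE2\t3\tnull\t3\t3",
    "!dataset_table_end")
  m <- parse_matrix(soft, "soft", case_subsets = "glioblastoma",
                    control_subsets = "non-tumor")
  # p2 has an unparseable cell and is dropped
  expect_equal(rownames(m$values), "p1")
  expect_equal(unname(m$group_labels[c("GSM1", "GSM3")]), c("case", "control"))
  expect_equal(unname(m$probe_gene_map["p1"]), "GENE1")
})

test_that("global-median probe filter keeps max >= grid median, strictly", {
  # [[1,2],[3,4]]: global median 2.5; probe 1 (max 2) removed
  v <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  f <- filter_probes(make_matrix(v))
  expect_equal(rownames(f$values), "p2")

  # constant matrix: max == median everywhere, nothing removed
  vc <- matrix(7, 3, 4, dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  expect_equal(nrow(filter_probes(make_matrix(vc))$values), 3)

  # a single probe above the median is untouched
  v1 <- matrix(c(5, 6), 1, 2, dimnames = list("p1", c("s1", "s2")))
  expect_equal(filter_probes(make_matrix(v1))$values, v1)

  # all probes below an impossible bar cannot happen, but an all-removed
  # grid must error rather than return an empty matrix
  v2 <- matrix(c(1, 1, 100, 100), nrow = 2, byrow = TRUE,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_equal(rownames(filter_probes(make_matrix(v2))$values), "p2")
})

test_that("log transform is the natural log and guards positivity", {
  v <- matrix(c(1, exp(1), exp(2), 4), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  lt <- log_transform(make_matrix(v))
  expect_equal(lt$values["p1", "s1"], 0)
  expect_equal(lt$values["p2", "s1"], 1)
  expect_equal(lt$values["p1", "s2"], 2)

  v[2, 2] <- 0
  expect_error(log_transform(make_matrix(v)), "probe p2, sample s2")
  floored <- log_transform(make_matrix(v), floor = 1e-6)
  expect_equal(floored$values[2, 2], log(1e-6))
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  v <- rbind(p1 = c(1, 2, 3, 4, 5, 6))
  colnames(v) <- paste0("s", 1:6)
  groups <- setNames(rep(c("case", "control"), each = 3), colnames(v))
  de <- differential_expression(make_matrix(v, groups), alpha = 0.05)
  # textbook pooled formula on {1,2,3} vs {4,5,6}
  sp <- sqrt(((3 - 1) * 1 + (3 - 1) * 1) / (3 + 3 - 2))  # both variances are 1
  t_expected <- (2 - 5) / (sp * sqrt(2 / 3))
  expect_equal(de$table$t, t_expected)
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(de$table$t, unname(oracle$statistic))
  expect_equal(de$table$p_raw, oracle$p.value)

  welch <- differential_expression(make_matrix(v, groups), var_equal = FALSE)
  ow <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(welch$table$p_raw, ow$p.value)
})

test_that("degenerate probes, Bonferroni arithmetic, and gene aggregation", {
  v <- rbind(p_flat = rep(5, 8),
             p_sig  = c(rep(1, 4), rep(9, 4)) + c(0.1, -0.1, 0.2, -0.2),
             p_null = c(5.1, 4.9, 5.2, 4.8, 5.05, 4.95, 5.15, 4.85))
  colnames(v) <- paste0("s", 1:8)
  groups <- setNames(rep(c("case", "control"), each = 4), colnames(v))
  map <- c(p_flat = "geneA", p_sig = "geneB", p_null = "geneB")
  de <- differential_expression(make_matrix(v, groups, map))
  tab <- de$table
  # constant identical probe: no-signal convention
  expect_equal(tab$p_raw[tab$probe_id == "p_flat"], 1)
  expect_equal(tab$t[tab$probe_id == "p_flat"], 0)
  # Bonferroni = min(1, n_tests * p_raw)
  expect_equal(de$n_tests, 3)
  expect_equal(tab$p_bonferroni, pmin(1, 3 * tab$p_raw))
  # best-probe rule: geneB is DE through p_sig despite p_null
  expect_equal(de$de_genes, "geneB")
  all_pr <- differential_expression(make_matrix(v, groups, map),
                                    aggregate = "all_probes")
  expect_length(all_pr$de_genes, 0)

  # unmapped probes are tallied, groups of < 2 samples rejected
  de2 <- differential_expression(make_matrix(v, groups,
                                             map[c("p_sig", "p_null")]))
  expect_equal(de2$n_unmapped_probes, 1)
  small <- setNames(c("case", rep("control", 7)), colnames(v))
  expect_error(differential_expression(make_matrix(v, small)),
               "at least 2 samples")
})

test_that("swapping group labels negates t and preserves p", {
  cfg <- small_config(5)
  study <- simulate_study(cfg)
  m <- log_transform(filter_probes(study$expr))
  de1 <- differential_expression(m)
  flipped <- m
  flipped$group_labels <- setNames(
    ifelse(m$group_labels == "case", "control", "case"),
    names(m$group_labels))
  de2 <- differential_expression(flipped)
  expect_equal(de2$table$t, -de1$table$t)
  expect_equal(de2$table$p_raw, de1$table$p_raw)
})

test_that("de_genes shrinks as alpha decreases", {
  study <- simulate_study(small_config(9))
  m <- log_transform(filter_probes(study$expr))
  sizes <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a)
    length(differential_expression(m, alpha = a)$de_genes), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
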