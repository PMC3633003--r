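# end-to-end helpers shared across evaluation tests
run_study <- function(cfg) {
  study <- simulate_study(cfg)
  m <- log_transform(filter_probes(study$expr))
  de <- differential_expression(m)
  list(study = study, de = de,
       config = series_config(restrict_to =
                                unname(study$expr$probe_gene_map)))
}

test_that("a one-snapshot series equals the standalone enrichment path", {
  rs <- run_study(small_config(21))
  s <- rs$study$snapshots[[length(rs$study$snapshots)]]
  terms <- c(rs$study$planted_term, "GO:0000001")

  tr <- run_series(list(s), rs$de$de_genes, terms, rs$config)

  annos <- filter_annotations(s$annos, aspect = "P")
  coll <- filter_by_size(build_gene_sets(s$graph, annos),
                         restrict_to = rs$config$restrict_to)
  standalone <- term_report(enrich(rs$de$de_genes, coll), terms)

  expect_identical(tr$status, standalone$status)
  expect_identical(tr$rank, standalone$rank)
  expect_identical(tr$p_raw, standalone$p_raw)
  expect_identical(tr$p_adjusted, standalone$p_adjusted)
  expect_identical(tr$set_size, standalone$set_size)
})

test_that("identical snapshots yield identical trajectory columns", {
  rs <- run_study(small_config(22))
  s <- rs$study$snapshots[[length(rs$study$snapshots)]]
  snaps <- list(snapshot("a", s$graph, s$annos),
                snapshot("b", s$graph, s$annos),
                snapshot("c", s$graph, s$annos))
  tr <- run_series(snaps, rs$de$de_genes, rs$study$planted_term, rs$config)
  cols <- split(tr[c("status", "rank", "p_raw", "set_size")], tr$snapshot)
  for (col in cols[-1]) {
    rownames(col) <- NULL
    ref <- cols[[1]]; rownames(ref) <- NULL
    expect_equal(col, ref)
  }
})

test_that("decouple freezes the chosen component and errors on bad labels", {
  rs <- run_study(small_config(23))
  snaps <- rs$study$snapshots
  expect_error(decouple(snaps, "fix_structure", "nope"), "not in the series")

  fixed_a <- decouple(snaps, "fix_annotations", snaps[[2]]$label)
  expect_true(all(vapply(fixed_a, function(s)
    identical(s$annos, snaps[[2]]$annos), logical(1))))
  expect_equal(vapply(fixed_a, `[[`, character(1), "label"),
               vapply(snaps, `[[`, character(1), "label"))

  fixed_s <- decouple(snaps, "fix_structure", snaps[[1]]$label)
  expect_true(all(vapply(fixed_s, function(s)
    identical(s$graph, snaps[[1]]$graph), logical(1))))

  # a series already sharing both components is a fixed point
  same <- list(snapshot("x", snaps[[1]]$graph, snaps[[1]]$annos),
               snapshot("y", snaps[[1]]$graph, snaps[[1]]$annos))
  expect_equal(decouple(same, "fix_annotations", "x"), same)
})

test_that("decoupling modes cross-check against direct enrichment on all graph/annotation pairs", {
  # two snapshots differing ONLY in annotations
  rs <- run_study(small_config(24))
  snaps <- rs$study$snapshots[c(2, 5)]
  term <- rs$study$planted_term
  genes <- rs$de$de_genes

  plain <- run_series(snaps, genes, term, rs$config)
  # fix_structure at either reference leaves everything unchanged
  # (the graphs are already identical)
  fs <- run_series(decouple(snaps, "fix_structure", snaps[[2]]$label),
                   genes, term, rs$config)
  expect_equal(as.data.frame(fs), as.data.frame(plain))

  # fix_annotations at snapshot 2 makes every column the snapshot-2 column
  fa <- run_series(decouple(snaps, "fix_annotations", snaps[[2]]$label),
                   genes, term, rs$config)
  ref_col <- fa[fa$snapshot == snaps[[2]]$label,
                c("status", "rank", "p_raw", "p_adjusted", "set_size")]
  for (lab in unique(fa$snapshot)) {
    col <- fa[fa$snapshot == lab,
              c("status", "rank", "p_raw", "p_adjusted", "set_size")]
    rownames(col) <- rownames(ref_col) <- NULL
    expect_equal(col, ref_col)
  }

  # direct per-combination enrichment agrees with both modes
  direct <- function(graph, annos) {
    coll <- filter_by_size(
      build_gene_sets(graph, filter_annotations(annos, aspect = "P")),
      restrict_to = rs$config$restrict_to)
    term_report(enrich(genes, coll), term)
  }
  d12 <- direct(snaps[[1]]$graph, snaps[[2]]$annos)
  expect_equal(fa$p_raw[fa$snapshot == snaps[[1]]$label], d12$p_raw)
})

test_that("top_terms truncates under the enrichment ordering with tie-breaks", {
  sets <- list("GO:0000300" = c("g1", "g2", "g3"),
               "GO:0000100" = c("g4", "g5", "g6"),
               "GO:0000200" = c("g7", "g8", "g9"))
  coll <- make_collection(sets, universe = paste0("g", 1:15))
  res <- enrich(c("g10", "g11"), coll)  # three-way tie at p = 1
  expect_equal(top_terms(res, 10),
               c("GO:0000100", "GO:0000200", "GO:0000300"))
  expect_equal(top_terms(res, 2), c("GO:0000100", "GO:0000200"))
  expect_equal(top_terms(res, 0), character(0))
})

test_that("track_terms applies the omission rule and drops empty rows", {
  tab <- structure(data.frame(
    term_id = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000002"),
    snapshot = c("t1", "t2", "t1", "t2"),
    status = "tested",
    rank = c(5L, 1L, 3L, 4L),
    p_raw = c(1, 1e-6, 1, 1),
    p_adjusted = c(1, 1e-4, 1, 1),
    set_size = c(2L, 10L, 8L, 9L),
    stringsAsFactors = FALSE),
    class = c("trajectory_table", "data.frame"),
    snapshot_labels = c("t1", "t2"))
  out <- track_terms(tab)
  # size < 3 wins over p = 1 as the recorded reason
  r1 <- out[out$term_id == "GO:0000001" & out$snapshot == "t1", ]
  expect_equal(r1$status, "fewer_than_min_genes")
  expect_true(is.na(r1$p_raw))
  # p = 1 cells masked; term 2 absent everywhere -> row dropped
  expect_false("GO:0000002" %in% out$term_id)
  # surviving cell untouched
  expect_equal(out$p_raw[out$snapshot == "t2"], 1e-6)
})

test_that("trajectory tables round-trip losslessly through TSV", {
  rs <- run_study(small_config(25))
  tr <- run_series(rs$study$snapshots, rs$de$de_genes,
                   c(rs$study$planted_term, "GO:0000001"), rs$config)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(attr(back, "snapshot_labels"), attr(tr, "snapshot_labels"))
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})

test_that("manifest-driven corpora reload into the same series results", {
  cfg <- small_config(26)
  dir <- withr::local_tempdir()
  simulate_corpus(cfg, dir)
  snaps <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_length(snaps, length(cfg$growth_fractions))

  study <- simulate_study(cfg)
  planted <- readLines(file.path(dir, "planted_term.txt"))
  expect_equal(planted, study$planted_term)
  m <- parse_matrix(file.path(dir, "expression.tsv"), "tsv",
                    group_labels = with(
                      utils::read.delim(file.path(dir, "groups.tsv")),
                      setNames(group, sample_id)),
                    probe_gene_map = read_probe_map(
                      file.path(dir, "probe_map.tsv")))
  de_file <- differential_expression(log_transform(filter_probes(m)))
  de_mem <- differential_expression(log_transform(filter_probes(study$expr)))
  expect_equal(de_file$de_genes, de_mem$de_genes)

  cfg_series <- series_config(restrict_to = unname(m$probe_gene_map))
  tr_file <- run_series(snaps, de_file$de_genes, planted, cfg_series)
  tr_mem <- run_series(study$snapshots, de_mem$de_genes, planted, cfg_series)
  expect_equal(tr_file$p_raw, tr_mem$p_raw, tolerance = 1e-12)
  expect_equal(tr_file$rank, tr_mem$rank)
})
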