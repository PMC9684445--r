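test_that("expression TSV round-trips exactly and validates samples", {
  m <- matrix(c(5, 2, 3, 4, 8, 6, 1.5, 0, -2, 7, 7, 7), nrow = 3,
              dimnames = list(c("miR-a", "miR-b", "miR-c"),
                              c("S1", "S2", "S3", "S4")))
  sheet <- sample_sheet(c("S1", "S2", "S3", "S4"),
                        c("case", "case", "control", "control"))
  tmp <- tempfile(fileext = ".tsv")
  write_expression(m, tmp)
  expect_identical(load_expression(tmp, sheet), m)

  ## sheet order and restriction are honored
  sub <- sample_sheet(c("S3", "S1"), c("control", "case"))
  expect_identical(load_expression(tmp, sub), m[, c("S3", "S1")])

  expect_error(load_expression(tmp, sample_sheet("S9", "case")), "S9")
})

test_that("expression loader rejects duplicate features and bad cells", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "miR-a\t1\t2", "miR-a\t3\t4"), tmp)
  expect_error(load_expression(tmp, sample_sheet(c("S1", "S2"),
                                                 c("case", "control"))),
               "miR-a")
  writeLines(c("id\tS1\tS2", "miR-a\t1\toops", "miR-b\t3\t4"), tmp)
  expect_error(load_expression(tmp, sample_sheet(c("S1", "S2"),
                                                 c("case", "control"))),
               "oops.*miR-a.*S2")
})

test_that("edge tables load with signs preserved and validate invariants", {
  tmp <- tempfile(fileext = ".tsv")
  et <- edge_table(paste0("TF", 1:5), paste0("miR-", 1:5), "TF", "miRNA",
                   "regulates",
                   sign = c("activate", "repress", "activate", "repress",
                            "activate"),
                   evidence = "validated_strong", origin = "db")
  write_edge_table(et, tmp)
  back <- load_edge_table(tmp, "regulates")
  expect_equal(back$sign, et$sign)
  expect_equal(back$source_id, et$source_id)

  expect_error(load_edge_table(tmp, "targets"), "regulates")

  ## self-loop in a regulatory relation is rejected
  writeLines(paste(c("source_id\tsource_kind\ttarget_id\ttarget_kind\trelation\tevidence\torigin",
                     "TF1\tTF\tTF1\tgene\tregulates\tvalidated_strong\tdb"),
                   collapse = "\n"), tmp)
  expect_error(load_edge_table(tmp), "self-loop")

  ## missing sign column falls back to the default rule
  writeLines(c("source_id\tsource_kind\ttarget_id\ttarget_kind\trelation\tevidence\torigin",
               "miR-1\tmiRNA\tG1\tgene\ttargets\tvalidated_strong\tdb",
               "TF1\tTF\tG1\tgene\tregulates\tvalidated_strong\tdb"), tmp)
  back <- load_edge_table(tmp)
  expect_equal(back$sign, c("repress", "activate"))

  expect_error(edge_table("a", "b", "protein", "gene", "targets"),
               "source_kind")
  expect_error(edge_table(c("a", "a"), c("b", "b"), "miRNA", "gene",
                          "targets", origin = "x",
                          evidence = "validated_strong"),
               "duplicate")
  expect_error(edge_table("a", "b", "miRNA", "gene", "targets",
                          evidence = "predicted", score = NA_real_),
               "without score")
})

test_that("GMT files round-trip with descriptions", {
  gsc <- gene_set_collection(list(pathway1 = c("A", "B", "C"),
                                  pathway2 = c("B", "D")),
                             description = c("first", "second"))
  tmp <- tempfile(fileext = ".gmt")
  write_gmt(gsc, tmp)
  back <- read_gmt(tmp)
  expect_equal(back$pathway1, c("A", "B", "C"))
  expect_equal(unname(attr(back, "description")["pathway2"]), "second")

  writeLines("badset\tonly-description", tmp)
  expect_error(read_gmt(tmp), "malformed")
  expect_error(gene_set_collection(list(a = character())), "empty")
})

test_that("consensus filter keeps pairs passing cutoffs in enough origins", {
  cutoffs <- list(miRDB = list(dir = "ge", value = 84),
                  TargetScan = list(dir = "le", value = -0.4),
                  microT = list(dir = "ge", value = 0.7),
                  mirDIP = list(dir = "class", value = "very high"))
  pred <- edge_table(
    source_id = rep("miR-x", 7),
    target_id = c("G1", "G1", "G1", "G2", "G2", "G1", "G3"),
    source_kind = "miRNA", target_kind = "gene", relation = "targets",
    evidence = "predicted",
    origin = c("miRDB", "TargetScan", "microT", "miRDB", "TargetScan",
               "mirDIP", "miRDB"),
    score = c(90, -0.5, 0.9, 85, -0.6, NA, 99),
    score_label = c(NA, NA, NA, NA, NA, " Very High ", NA))
  validated <- toy_targets("miR-x", "G9")

  out <- consensus_target_filter(pred, validated, cutoffs, min_sources = 3)
  ## G1 passes in miRDB, TargetScan, microT and mirDIP (label is
  ## case/whitespace-insensitive) -> retained; G2 passes only 2 -> dropped;
  ## G3 passes only 1 -> dropped; G9 validated -> always retained
  expect_setequal(out$target_id, c("G1", "G9"))
  expect_equal(out$status[out$target_id == "G1"], "predicted")
  expect_equal(out$status[out$target_id == "G9"], "validated")
  expect_equal(out$score[out$target_id == "G1"], 4)

  expect_error(
    consensus_target_filter(
      edge_table("miR-x", "G1", "miRNA", "gene", "targets",
                 evidence = "predicted", origin = "mystery", score = 1),
      validated, cutoffs), "mystery")
})

test_that("consensus filter matches a per-pair counting oracle", {
  set.seed(42)
  origins <- paste0("db", 1:6)
  cutoffs <- stats::setNames(
    lapply(1:6, function(i) list(dir = "ge", value = 0.5)), origins)
  pairs <- expand.grid(m = paste0("miR-", 1:10), g = paste0("G", 1:20),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    data.frame(m = pairs$m[i], g = pairs$g[i],
               origin = sample(origins, k),
               score = stats::runif(k), stringsAsFactors = FALSE)
  }))
  pred <- edge_table(rows$m, rows$g, "miRNA", "gene", "targets",
                     evidence = "predicted", origin = rows$origin,
                     score = rows$score)
  validated <- toy_targets(c("miR-1", "miR-2"), c("G100", "G101"))

  for (ms in 1:4) {
    out <- consensus_target_filter(pred, validated, cutoffs,
                                   min_sources = ms)
    ## oracle: per-pair count of origins with score >= 0.5
    pass <- rows[rows$score >= 0.5, , drop = FALSE]
    cnt <- table(paste(pass$m, pass$g))
    expected <- union(names(cnt)[cnt >= ms], c("miR-1 G100", "miR-2 G101"))
    expect_setequal(paste(out$source_id, out$target_id), expected)
  }

  ## monotone non-increasing in min_sources
  sizes <- vapply(1:6, function(ms)
    nrow(consensus_target_filter(pred, validated, cutoffs, ms)), 1L)
  expect_true(all(diff(sizes) <= 0))

  ## stricter cutoffs shrink the output
  strict <- stats::setNames(
    lapply(1:6, function(i) list(dir = "ge", value = 0.8)), origins)
  expect_lte(nrow(consensus_target_filter(pred, validated, strict, 2)),
             nrow(consensus_target_filter(pred, validated, cutoffs, 2)))
})

test_that("cutoff config reader validates structure", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("miRDB:", "  dir: ge", "  value: 84",
               "mirDIP:", "  dir: class", "  value: [very high]"), tmp)
  cfg <- read_cutoff_config(tmp)
  expect_equal(cfg$miRDB$value, 84)
  expect_equal(cfg$mirDIP$dir, "class")
  writeLines(c("bad:", "  dir: sideways", "  value: 1"), tmp)
  expect_error(read_cutoff_config(tmp), "sideways|must be one of")
})
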