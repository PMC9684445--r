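minimal_tables <- function() {
  list(
    tf_mirna = edge_table("T1", "m1", "TF", "miRNA", "regulates",
                          evidence = "validated_strong", origin = "toy"),
    tf_gene = edge_table("T1", "g1", "TF", "gene", "regulates",
                         evidence = "validated_strong", origin = "toy"),
    mirna_gene = toy_targets("m1", "g1"))
}

test_that("a minimal TF-FFL is assembled and classified", {
  tb <- minimal_tables()
  net <- assemble_coregulatory_network(tb$tf_mirna, tb$tf_gene,
                                       tb$mirna_gene,
                                       keep_mirnas = "m1",
                                       keep_genes = "g1", tf_ids = "T1")
  expect_setequal(net$nodes$id, c("T1", "m1", "g1"))
  ffls <- enumerate_and_classify_ffls(net)
  expect_equal(nrow(ffls), 1)
  expect_equal(ffls$ffl_class, "TF-FFL")
  ## default sign assumptions: TF activates, miRNA represses
  e <- net$edges
  expect_equal(e$sign[e$source_id == "T1" & e$target_id == "m1"],
               "activate")
  expect_equal(e$sign[e$source_id == "m1"], "repress")
})

test_that("composite precedence: mutual TF-miRNA regulation wins", {
  tb <- minimal_tables()
  mg <- rbind(tb$mirna_gene, toy_targets("m1", "T1"))
  class(mg) <- c("edge_table", "data.frame")
  net <- assemble_coregulatory_network(tb$tf_mirna, tb$tf_gene, mg,
                                       keep_mirnas = "m1",
                                       keep_genes = "g1", tf_ids = "T1")
  ffls <- enumerate_and_classify_ffls(net)
  expect_equal(nrow(ffls), 1)
  expect_equal(ffls$ffl_class, "composite")
})

test_that("annotated repression survives merging over the default sign", {
  tm <- edge_table(c("T1", "T2"), c("m1", "m1"), "TF", "miRNA",
                   "regulates", sign = c("repress", NA),
                   evidence = "validated_strong", origin = "db")
  tb <- minimal_tables()
  net <- assemble_coregulatory_network(tm, tb$tf_gene, tb$mirna_gene,
                                       keep_mirnas = "m1", keep_genes = "g1",
                                       tf_ids = c("T1", "T2"))
  e <- net$edges
  expect_equal(e$sign[e$source_id == "T1" & e$target_id == "m1"], "repress")
  expect_equal(e$sign[e$source_id == "T2" & e$target_id == "m1"],
               "activate")
})

test_that("FFL enumeration equals the exhaustive triple scan on random nets", {
  set.seed(27)
  for (i in 1:30) {
    net <- random_coreg_network(n_tf = sample(3:8, 1),
                                n_mirna = sample(3:8, 1),
                                n_gene = sample(3:10, 1))
    got <- enumerate_and_classify_ffls(net)
    want <- ffl_triple_scan(net$edges, stats::setNames(net$nodes$kind,
                                                       net$nodes$id))
    expect_setequal(paste(got$tf, got$mirna, got$gene, got$ffl_class),
                    paste(want$tf, want$mirna, want$gene, want$ffl_class))
    ## classes partition the qualifying triples
    expect_equal(anyDuplicated(paste(got$tf, got$mirna, got$gene)), 0)
    expect_equal(nrow(got),
                 sum(table(got$ffl_class)))
  }
})

test_that("enumeration is invariant under edge-list permutation", {
  set.seed(5)
  net <- random_coreg_network(6, 6, 8)
  g1 <- enumerate_and_classify_ffls(net)
  net2 <- net
  net2$edges <- net$edges[sample(nrow(net$edges)), , drop = FALSE]
  g2 <- enumerate_and_classify_ffls(net2)
  expect_equal(g1[c("tf", "mirna", "gene", "ffl_class")],
               g2[c("tf", "mirna", "gene", "ffl_class")])
})

test_that("removing miRNA->TF edges zeroes miRNA-FFL and composite counts", {
  set.seed(14)
  net <- random_coreg_network(6, 6, 8, p = 0.25)
  before <- enumerate_and_classify_ffls(net)
  kind <- stats::setNames(net$nodes$kind, net$nodes$id)
  drop <- kind[net$edges$source_id] == "miRNA" &
    kind[net$edges$target_id] == "TF"
  net$edges <- net$edges[!drop, , drop = FALSE]
  after <- enumerate_and_classify_ffls(net)
  expect_equal(sum(after$ffl_class != "TF-FFL"), 0)
  expect_equal(sum(after$ffl_class == "TF-FFL"),
               sum(before$ffl_class == "TF-FFL"))
})

test_that("planted FFLs are recovered with their planted classes", {
  for (s in c(1, 7)) {
    reg <- gen_regulatory_truth(seed = s)
    net <- assemble_coregulatory_network(
      reg$tf_mirna, reg$tf_gene, reg$mirna_gene,
      keep_mirnas = unique(reg$mirna_gene$source_id),
      keep_genes = unique(reg$mirna_gene$target_id),
      tf_ids = reg$tf_catalog)
    ffls <- enumerate_and_classify_ffls(net)
    planted <- reg$truth$planted_ffls
    expect_true(all(paste(planted$tf, planted$mirna, planted$gene,
                          planted$ffl_class) %in%
                      paste(ffls$tf, ffls$mirna, ffls$gene,
                            ffls$ffl_class)))
  }

  ## with background wiring disabled, recovery is exact set equality
  reg0 <- gen_regulatory_truth(n_background_edges = 0,
                               n_background_tf_edges = 0,
                               n_biomarkers = 0, seed = 3)
  net0 <- assemble_coregulatory_network(
    reg0$tf_mirna, reg0$tf_gene, reg0$mirna_gene,
    keep_mirnas = unique(c(reg0$mirna_gene$source_id,
                           reg0$tf_mirna$target_id)),
    keep_genes = unique(c(reg0$mirna_gene$target_id,
                          reg0$tf_gene$target_id)),
    tf_ids = reg0$tf_catalog)
  ffls0 <- enumerate_and_classify_ffls(net0)
  planted0 <- reg0$truth$planted_ffls
  expect_setequal(paste(ffls0$tf, ffls0$mirna, ffls0$gene, ffls0$ffl_class),
                  paste(planted0$tf, planted0$mirna, planted0$gene,
                        planted0$ffl_class))
})

test_that("hub ranking by degree matches a recount, with dual-role TFs", {
  tm <- edge_table(c("T1", "T1", "T2"), c("m1", "m2", "m1"), "TF", "miRNA",
                   "regulates", evidence = "validated_strong", origin = "t")
  tg <- edge_table(c("T1", "T1", "T2", "T1"), c("g1", "g2", "g1", "T2"),
                   "TF", c("gene", "gene", "gene", "TF"), "regulates",
                   evidence = "validated_strong", origin = "t")
  mg <- toy_targets(c("m1", "m1", "m2"), c("g1", "g2", "g1"))
  net <- assemble_coregulatory_network(tm, tg, mg,
                                       keep_mirnas = c("m1", "m2"),
                                       keep_genes = c("g1", "g2"),
                                       tf_ids = c("T1", "T2"))
  hubs <- rank_hubs(net, top_k = 2)
  ## recount: T1 touches m1,m2,g1,g2,T2 -> degree 5
  expect_equal(hubs$top_tfs$id[1], "T1")
  expect_equal(hubs$top_tfs$degree[1], 5)
  ## g1 is targeted by m1, m2 and regulated by T1, T2
  expect_equal(hubs$top_genes$id[1], "g1")
  expect_equal(hubs$top_genes$degree[1], 4)
  ## T2 is regulated by T1 -> dual role
  expect_equal(hubs$dual_role, "T2")

  set.seed(3)
  rn <- random_coreg_network(5, 5, 8, p = 0.3)
  h <- rank_hubs(rn, top_k = 3)
  deg <- table(factor(c(rn$edges$source_id, rn$edges$target_id),
                      levels = rn$nodes$id))
  for (row in seq_len(nrow(h$top_tfs)))
    expect_equal(h$top_tfs$degree[row],
                 as.integer(deg[h$top_tfs$id[row]]))
  tf_deg <- deg[rn$nodes$id[rn$nodes$kind == "TF"]]
  expect_equal(h$top_tfs$degree[1], max(as.integer(tf_deg)))
})
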