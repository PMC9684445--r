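#' Simulate case/control serum miRNA expression with planted signal
#'
#' Emulates a serum miRNA microarray study: per-feature baseline log2
#' intensities drawn from Normal(`baseline_mean`, `baseline_sd`), i.i.d.
#' Gaussian measurement noise per cell, and a planted set of up-regulated
#' features whose case samples are shifted by a per-feature amount drawn
#' uniformly from `shift_range` (serum biomarkers in this design are
#' up-regulated in cases). With `distortion = TRUE` every sample is passed
#' through a random strictly increasing map (affine plus cubic with positive
#' coefficients), which quantile normalization must undo.
#'
#' Defaults mirror a discovery cohort of the kind the pipeline targets:
#' ~2,500 miRNA probes with on the order of a hundred samples per group and
#' planted effects of at least one log2 unit.
#'
#' @param n_features number of miRNA features.
#' @param n_case,n_control samples per group.
#' @param n_de number of planted differentially expressed features.
#' @param shift_range interval for the per-feature case shift (log2 units),
#'   a subset of \[0.5, 4\].
#' @param noise_sd per-cell Gaussian noise sd (log2 units).
#' @param distortion apply a random monotone per-sample intensity distortion.
#' @param baseline_mean,baseline_sd baseline feature mean distribution.
#' @param seed integer RNG seed; the run is fully reproducible.
#' @return list with `matrix` (expression), `sheet` ([sample_sheet()]) and
#'   `truth` (list with `de_features` as a named shift vector, plus the seed
#'   and parameters).
#' @export
gen_case_control_expression <- function(n_features = 2500L,
                                        n_case = 115L, n_control = 100L,
                                        n_de = 250L,
                                        shift_range = c(1, 3),
                                        noise_sd = 0.5,
                                        distortion = FALSE,
                                        baseline_mean = 8, baseline_sd = 2,
                                        seed = 1L) {
  if (n_features <= 0L || n_case <= 0L || n_control <= 0L || n_de < 0L)
    stop("counts must be positive (n_de may be zero)")
  if (n_de > n_features) stop("n_de must not exceed n_features")
  stopifnot(length(shift_range) == 2L, shift_range[1] <= shift_range[2])
  if (n_de > 0L && (shift_range[1] < 0.5 || shift_range[2] > 4))
    stop("shift_range must lie within [0.5, 4]")

  withr_seed(seed)
  feature_ids <- sprintf("miR-%04d", seq_len(n_features))
  sample_ids <- c(sprintf("case_%03d", seq_len(n_case)),
                  sprintf("ctrl_%03d", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))

  baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)
  m <- matrix(stats::rnorm(n_features * length(sample_ids), 0, noise_sd),
              n_features, length(sample_ids),
              dimnames = list(feature_ids, sample_ids)) + baseline
  de_idx <- if (n_de > 0L) sample.int(n_features, n_de) else integer()
  shifts <- stats::setNames(
    stats::runif(length(de_idx), shift_range[1], shift_range[2]),
    feature_ids[de_idx])
  m[de_idx, group == "case"] <- m[de_idx, group == "case"] + shifts

  if (distortion) {
    for (j in seq_along(sample_ids)) {
      a <- stats::rnorm(1, 0, 0.5)
      b <- stats::runif(1, 0.5, 1.5)
      cc <- stats::runif(1, 1e-4, 1e-3)
      m[, j] <- a + b * m[, j] + cc * m[, j]^3
    }
  }

  list(matrix = m,
       sheet = sample_sheet(sample_ids, group, cohort = "synthetic"),
       truth = list(de_features = shifts, seed = seed,
                    params = list(n_features = n_features, n_case = n_case,
                                  n_control = n_control, n_de = n_de,
                                  shift_range = shift_range,
                                  noise_sd = noise_sd,
                                  distortion = distortion)))
}

#' Simulate regulatory edge tables with planted biomarkers and FFLs
#'
#' Builds the full regulatory input set for the downstream modules —
#' miRNA->gene targeting, signed TF->miRNA and TF->gene regulation and a TF
#' catalog — around planted structure whose ground truth is recorded
#' exactly:
#' \itemize{
#'   \item planted biomarker miRNAs receive `single_line_boost` private
#'     target genes touched by no other miRNA (their true NSR contribution)
#'     plus a TF-enriched shared target set (fraction `tf_target_boost` TFs);
#'   \item planted feed-forward loops are wired per class on dedicated
#'     nodes: TF-FFL (TF->miRNA, TF->gene, miRNA->gene), miRNA-FFL
#'     (miRNA->TF, TF->gene, miRNA->gene), composite (TF<->miRNA plus both
#'     ->gene edges);
#'   \item random background miRNA->gene, TF->miRNA and TF->gene edges are
#'     drawn last, re-drawing any edge that would collide with a planted
#'     single-line gene or reclassify a planted FFL.
#' }
#'
#' @param n_mirna,n_gene node budgets.
#' @param tf_fraction fraction of genes designated TFs, in (0, 1).
#' @param n_biomarkers number of planted biomarker miRNAs.
#' @param single_line_boost private (single-line) targets per planted
#'   biomarker.
#' @param tf_target_boost TF fraction of each planted biomarker's shared
#'   target set.
#' @param n_ffl_per_class integer vector `(TF-FFL, miRNA-FFL, composite)`.
#' @param n_shared_targets size of each planted biomarker's shared
#'   (non-private) target set.
#' @param n_background_edges random background miRNA->gene edges.
#' @param n_background_tf_edges random background TF->miRNA and TF->gene
#'   edges (each).
#' @param seed RNG seed.
#' @return list with `mirna_gene`, `tf_mirna`, `tf_gene` edge tables,
#'   `tf_catalog` (character vector) and `truth` (planted biomarkers with
#'   true NSR and TF-target fraction; planted FFL triples with classes).
#' @export
gen_regulatory_truth <- function(n_mirna = 40L, n_gene = 400L,
                                 tf_fraction = 0.15,
                                 n_biomarkers = 5L,
                                 single_line_boost = 30L,
                                 tf_target_boost = 0.4,
                                 n_ffl_per_class = c(5L, 3L, 2L),
                                 n_shared_targets = 20L,
                                 n_background_edges = 400L,
                                 n_background_tf_edges = 60L,
                                 seed = 1L) {
  stopifnot(tf_fraction > 0, tf_fraction < 1,
            single_line_boost >= 0, tf_target_boost >= 0,
            length(n_ffl_per_class) == 3L)
  n_ffl <- sum(n_ffl_per_class)
  if (n_biomarkers > n_mirna || n_ffl > n_mirna)
    stop("planted structure exceeds the miRNA node budget")
  need_genes <- n_biomarkers * (single_line_boost + n_shared_targets) + n_ffl
  if (need_genes > n_gene)
    stop("planted structure exceeds the gene node budget")

  withr_seed(seed)
  mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
  genes <- sprintf("G%04d", seq_len(n_gene))
  n_tf <- max(1L, round(tf_fraction * n_gene))
  tfs <- sample(genes, n_tf)

  biomarkers <- mirnas[seq_len(n_biomarkers)]
  tf_pool <- tfs
  nontf_pool <- setdiff(genes, tfs)

  ## private single-line genes (non-TF so TFP stays controlled by the
  ## shared set) and TF-enriched shared targets per biomarker
  mg_src <- character(); mg_tgt <- character()
  private_genes <- character()
  truth_bio <- list()
  pool <- nontf_pool
  for (b in biomarkers) {
    priv <- pool[seq_len(single_line_boost)]
    pool <- setdiff(pool, priv)
    ## tf_target_boost is the TF share of the biomarker's whole target set;
    ## all TF targets live in the shared part (privates are non-TF so the
    ## single-line count stays exact)
    n_tf_shared <- round(tf_target_boost *
                           (single_line_boost + n_shared_targets))
    if (n_tf_shared > n_shared_targets)
      stop("tf_target_boost too large for n_shared_targets")
    sh_tf <- tf_pool[seq_len(min(n_tf_shared, length(tf_pool)))]
    sh_non <- pool[seq_len(n_shared_targets - length(sh_tf))]
    pool <- setdiff(pool, sh_non)
    tgts <- c(priv, sh_tf, sh_non)
    mg_src <- c(mg_src, rep(b, length(tgts)))
    mg_tgt <- c(mg_tgt, tgts)
    private_genes <- c(private_genes, priv)
    truth_bio[[b]] <- list(nsr = length(priv),
                           tf_fraction = length(sh_tf) / length(tgts),
                           n_targets = length(tgts))
  }

  ## planted FFLs on dedicated miRNAs / TFs / genes
  ffl_mirnas <- mirnas[n_mirna - seq_len(n_ffl) + 1L]
  if (length(intersect(ffl_mirnas, biomarkers)))
    stop("planted structure exceeds the miRNA node budget")
  ffl_tfs <- tf_pool[tf_pool %in% setdiff(tf_pool, mg_tgt)]
  if (length(ffl_tfs) < n_ffl)
    stop("planted structure exceeds the TF node budget")
  ffl_tfs <- ffl_tfs[seq_len(n_ffl)]
  ffl_genes <- pool[seq_len(n_ffl)]
  pool <- setdiff(pool, ffl_genes)
  classes <- rep(c("TF-FFL", "miRNA-FFL", "composite"), n_ffl_per_class)
  tm_src <- character(); tm_tgt <- character()
  tg_src <- character(); tg_tgt <- character()
  planted_ffls <- data.frame(tf = ffl_tfs, mirna = ffl_mirnas,
                             gene = ffl_genes, ffl_class = classes,
                             stringsAsFactors = FALSE)
  for (i in seq_len(n_ffl)) {
    t <- ffl_tfs[i]; m <- ffl_mirnas[i]; g <- ffl_genes[i]
    cl <- classes[i]
    if (cl %in% c("TF-FFL", "composite")) {
      tm_src <- c(tm_src, t); tm_tgt <- c(tm_tgt, m)
    }
    if (cl %in% c("miRNA-FFL", "composite")) {
      mg_src <- c(mg_src, m); mg_tgt <- c(mg_tgt, t)  # miRNA->TF edge
    }
    tg_src <- c(tg_src, t); tg_tgt <- c(tg_tgt, g)
    mg_src <- c(mg_src, m); mg_tgt <- c(mg_tgt, g)
  }

  ## cover every shared biomarker target with one extra miRNA so the true
  ## NSR of a planted biomarker is exactly its private single-line count
  bg_mirnas <- setdiff(mirnas, c(biomarkers, ffl_mirnas))
  if (!length(bg_mirnas) && n_biomarkers > 0L && n_shared_targets > 0L)
    stop("planted structure exceeds the miRNA node budget")
  shared_targets <- setdiff(unique(mg_tgt[mg_src %in% biomarkers]),
                            private_genes)
  cover_src <- character(); cover_tgt <- character()
  for (g in shared_targets) {
    m <- bg_mirnas[1L + (match(g, shared_targets) %% length(bg_mirnas))]
    cover_src <- c(cover_src, m); cover_tgt <- c(cover_tgt, g)
  }
  mg_src <- c(mg_src, cover_src); mg_tgt <- c(mg_tgt, cover_tgt)

  ## background edges, avoiding collisions that would corrupt the truth:
  ## private single-line genes stay private; planted FFL wiring may not be
  ## extended by edges among its (tf, mirna, gene) triples
  forbidden_pairs <- c(
    paste(planted_ffls$mirna, planted_ffls$tf),    # would turn TF-FFL composite
    paste(mg_src, mg_tgt))
  bg_gene_pool <- setdiff(genes, c(private_genes, ffl_genes))
  if (length(bg_mirnas) && length(bg_gene_pool) && n_background_edges > 0L) {
    got <- 0L; tries <- 0L
    while (got < n_background_edges && tries < 50L * n_background_edges) {
      tries <- tries + 1L
      s <- sample(bg_mirnas, 1L); g <- sample(bg_gene_pool, 1L)
      if (paste(s, g) %in% forbidden_pairs) next
      mg_src <- c(mg_src, s); mg_tgt <- c(mg_tgt, g)
      forbidden_pairs <- c(forbidden_pairs, paste(s, g))
      got <- got + 1L
    }
  }
  bg_tfs <- setdiff(tfs, ffl_tfs)
  if (length(bg_tfs) && n_background_tf_edges > 0L) {
    forbidden_tm <- c(paste(tm_src, tm_tgt),
                      paste(planted_ffls$tf, planted_ffls$mirna))
    got <- 0L; tries <- 0L
    while (got < n_background_tf_edges && tries < 50L * n_background_tf_edges) {
      tries <- tries + 1L
      s <- sample(bg_tfs, 1L); m <- sample(mirnas, 1L)
      if (paste(s, m) %in% forbidden_tm) next
      tm_src <- c(tm_src, s); tm_tgt <- c(tm_tgt, m)
      forbidden_tm <- c(forbidden_tm, paste(s, m))
      got <- got + 1L
    }
    forbidden_tg <- paste(tg_src, tg_tgt)
    got <- 0L; tries <- 0L
    while (got < n_background_tf_edges && tries < 50L * n_background_tf_edges) {
      tries <- tries + 1L
      s <- sample(bg_tfs, 1L); g <- sample(setdiff(genes, ffl_genes), 1L)
      if (s == g || paste(s, g) %in% forbidden_tg) next
      tg_src <- c(tg_src, s); tg_tgt <- c(tg_tgt, g)
      forbidden_tg <- c(forbidden_tg, paste(s, g))
      got <- got + 1L
    }
  }

  mirna_gene <- edge_table(mg_src, mg_tgt, "miRNA",
                           ifelse(mg_tgt %in% tfs, "TF", "gene"),
                           "targets", evidence = "validated_strong",
                           origin = "synthetic")
  tf_mirna <- edge_table(tm_src, tm_tgt, "TF", "miRNA", "regulates",
                         evidence = "validated_strong", origin = "synthetic")
  tf_gene <- edge_table(tg_src, tg_tgt, "TF",
                        ifelse(tg_tgt %in% tfs, "TF", "gene"),
                        "regulates", evidence = "validated_strong",
                        origin = "synthetic")

  list(mirna_gene = mirna_gene, tf_mirna = tf_mirna, tf_gene = tf_gene,
       tf_catalog = tfs,
       truth = list(biomarker_mirnas = truth_bio,
                    planted_ffls = planted_ffls,
                    seed = seed))
}

#' Simulate a PPI network with planted dense modules
#'
#' Planted modules are disjoint near-cliques: within-module edges appear
#' with probability `p_within`, all other pairs with `p_background`
#' (`p_within` should be much larger). Edges carry confidence scores drawn
#' uniformly from `confidence_range`, emulating a scored PPI export.
#'
#' @param n_nodes total proteins.
#' @param p_background background edge probability.
#' @param module_sizes vector of planted module sizes (each >= 4; must sum
#'   to at most `n_nodes` — modules are disjoint by construction).
#' @param p_within within-module edge probability.
#' @param confidence_range interval for edge confidence scores.
#' @param seed RNG seed.
#' @return list with `ppi` (edge table, relation `interacts`) and `truth`
#'   (`modules`: list of member id vectors; seed).
#' @export
gen_ppi_with_modules <- function(n_nodes = 400L, p_background = 0.01,
                                 module_sizes = c(15L, 12L, 10L),
                                 p_within = 0.9,
                                 confidence_range = c(0.4, 1),
                                 seed = 1L) {
  if (any(module_sizes < 4L)) stop("module sizes must be >= 4")
  if (sum(module_sizes) > n_nodes)
    stop("planted modules overlap the node budget (must be disjoint)")
  if (p_within <= p_background)
    stop("p_within must exceed p_background")
  withr_seed(seed)
  nodes <- sprintf("P%04d", seq_len(n_nodes))
  membership <- rep(0L, n_nodes)
  at <- 1L
  modules <- vector("list", length(module_sizes))
  for (k in seq_along(module_sizes)) {
    idx <- at:(at + module_sizes[k] - 1L)
    membership[idx] <- k
    modules[[k]] <- nodes[idx]
    at <- at + module_sizes[k]
  }
  pairs <- utils::combn(n_nodes, 2L)
  same <- membership[pairs[1L, ]] != 0L &
    membership[pairs[1L, ]] == membership[pairs[2L, ]]
  p <- ifelse(same, p_within, p_background)
  keep <- stats::runif(ncol(pairs)) < p
  src <- nodes[pairs[1L, keep]]
  tgt <- nodes[pairs[2L, keep]]
  conf <- stats::runif(sum(keep), confidence_range[1], confidence_range[2])
  ppi <- edge_table(src, tgt, "gene", "gene", "interacts",
                    evidence = "physical", origin = "synthetic",
                    score = conf)
  list(ppi = ppi,
       truth = list(modules = modules, seed = seed))
}

## seed helper: set the RNG reproducibly without leaking state decisions
## into callers (no restore: generators are expected to own the stream)
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
}
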