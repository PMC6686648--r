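test_that("best-hit filtering keeps the minimal-E hit with documented ties", {
  hits <- data.frame(
    qseqid = c("q1", "q1", "q2", "q3", "q3", "q4"),
    sseqid = c("gA", "gB", "gC", "gD", "gE", "gF"),
    evalue = c(1e-9, 1e-5, 1e-6, 1e-9, 1e-9, 1e-20),
    bitscore = c(50, 80, 40, 50, 60, 90),
    stringsAsFactors = FALSE
  )
  ann <- best_hit_filter(hits)
  expect_equal(ann$gene_id[ann$node_id == "q1"], "gA")      # minimum E wins
  expect_true(is.na(ann$gene_id[ann$node_id == "q2"]))      # 1e-6 > 1e-7
  expect_equal(ann$gene_id[ann$node_id == "q3"], "gE")      # bitscore tie-break
  expect_equal(ann$gene_id[ann$node_id == "q4"], "gF")
  # subject-label tie-break when evalue and bitscore tie
  tie <- data.frame(qseqid = "q", sseqid = c("zZ", "aA"), evalue = 1e-9,
                    bitscore = 50, stringsAsFactors = FALSE)
  expect_equal(best_hit_filter(tie)$gene_id, "aA")
  expect_error(best_hit_filter(transform(hits, evalue = -evalue)), "negative")
})

test_that("best-hit filtering is order-independent and anti-monotone in the threshold", {
  set.seed(13)
  hits <- data.frame(
    qseqid = sample(paste0("q", 1:8), 60, replace = TRUE),
    sseqid = sample(paste0("g", 1:10), 60, replace = TRUE),
    evalue = 10^runif(60, -12, 0),
    bitscore = runif(60, 20, 90),
    stringsAsFactors = FALSE
  )
  a1 <- best_hit_filter(hits)
  a2 <- best_hit_filter(hits[sample(nrow(hits)), ])
  expect_identical(a1[order(a1$node_id), ], a2[order(a2$node_id), ])
  for (thr in 10^c(-12, -9, -7, -4)) {
    loose <- best_hit_filter(hits, max_evalue = thr * 100)
    tight <- best_hit_filter(hits, max_evalue = thr)
    expect_true(all(which(!is.na(tight$gene_id)) %in%
                    which(!is.na(loose$gene_id))))
  }
})

test_that("mini translated search finds embedded coding segments and not noise", {
  models <- generate_gene_models(10, rng_seed = 42)
  prot <- gene_proteins(models)
  expect_gte(length(prot), 9L)
  node <- substr(models[[1]]$isoform_seqs[1], 10, 160)
  hits <- mini_translated_search(c(nodeA = node), prot)
  top <- best_hit_filter(hits)
  expect_equal(top$gene_id[top$node_id == "nodeA"], models[[1]]$gene_id)
  expect_lt(top$evalue[top$node_id == "nodeA"], 1e-7)
  # a reverse-complemented node hits through the negative frames
  hits_rc <- mini_translated_search(c(nodeB = revcomp(node)), prot)
  top_rc <- best_hit_filter(hits_rc)
  expect_equal(top_rc$gene_id, models[[1]]$gene_id)
  # random sequence scores near the null against an unrelated proteome
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  h2 <- mini_translated_search(c(rand = rnd),
                               prot[names(prot) != models[[1]]$gene_id])
  if (nrow(h2) > 0) expect_gt(min(h2$evalue), 1e-7)
  # empty protein set gives an empty hit list
  expect_equal(nrow(mini_translated_search(c(n = node),
                                           character(0))), 0L)
  expect_warning(mini_translated_search(c(tiny = "AC", n = node), prot),
                 "shorter than 3")
})

test_that("graph annotation takes unions over component nodes", {
  asm <- structure(list(
    params = assembly_params(5, 1),
    nodes = data.frame(node_id = c("n1", "n2", "n3", "n4"),
                       sequence = c("AAAAA", "CCCCC", "GGGGG", "TTTTT"),
                       component_id = c(1L, 1L, 2L, 3L),
                       n_kmers = 1L, stringsAsFactors = FALSE),
    edges = data.frame(from = character(0), to = character(0)),
    membership = data.table::data.table(kmer = character(0),
                                        node_id = character(0)),
    counts = NULL
  ), class = "splicing_assembly")
  ann <- data.frame(node_id = c("n1", "n2", "n3", "n4"),
                    gene_id = c("geneA", "geneA", "geneB", NA),
                    stringsAsFactors = FALSE)
  ga <- graph_annotation(asm, ann)
  expect_equal(ga[["1"]], "geneA")
  expect_equal(ga[["2"]], "geneB")
  expect_equal(ga[["3"]], character(0))
  # multiple genes in one graph are all retained
  ann2 <- ann; ann2$gene_id[2] <- "geneC"
  expect_setequal(graph_annotation(asm, ann2)[["1"]], c("geneA", "geneC"))
  expect_error(graph_annotation(asm, data.frame(node_id = "zz",
                                                gene_id = "g")), "unknown")
})

test_that("annotated nodes map back to their true source gene", {
  models <- generate_gene_models(8, rng_seed = 5)
  man <- truth_manifest(vapply(models, `[[`, character(1), "gene_id"),
                        baseline_mean = 40)
  des <- library_design(size_factors = rep(1, 12))
  cts <- simulate_counts(man, des, 0.05, 6)
  sim <- simulate_reads(models, cts, read_length = 100, error_rate = 0,
                        adapter_fraction = 0, rng_seed = 7)
  reads <- lapply(sim, function(l) c(l$mate1$seq, l$mate2$seq))
  asm <- sweep_assemblies(reads, list(assembly_params(25, 2)))[[1]]
  truth <- annotate_nodes_by_truth(asm, models)
  ann <- annotate_assembly(asm, gene_proteins(models))
  both <- !is.na(ann$gene_id) & !is.na(truth$gene_id)
  expect_gt(sum(both), 0L)
  agreement <- mean(ann$gene_id[both] == truth$gene_id[both])
  expect_gte(agreement, 0.95)
})

test_that("the shipped example hit table annotates at the E-value threshold", {
  f <- system.file("extdata", "example_hits.tsv", package = "facpred")
  hits <- read_blast_tab(f)
  ann <- best_hit_filter(hits)
  expect_equal(ann$gene_id[ann$node_id == "n1"], "Hcf")
  expect_equal(ann$gene_id[ann$node_id == "n3"], "AMPKalpha")
  expect_true(is.na(ann$gene_id[ann$node_id == "n5"]))  # E = 1.3 > 1e-7
})

test_that("tabular hits round-trip through the 12-column format", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  df <- data.frame(q = "n1", s = "gA", pid = 98.5, len = 50L, mm = 1L,
                   go = 0L, qs = 1L, qe = 150L, ss = 1L, se = 50L,
                   ev = 1e-20, bs = 95.3)
  write.table(df, f, sep = "\t", col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  hits <- read_blast_tab(f)
  expect_equal(hits$qseqid, "n1")
  expect_equal(hits$evalue, 1e-20)
  ann <- best_hit_filter(hits)
  expect_equal(ann$gene_id, "gA")
})
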