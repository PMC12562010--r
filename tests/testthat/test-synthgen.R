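test_that("toy genome is seeded, sized and alphabet-clean", {
  cfg <- synth_config(n_genes = 6L, gene_span = 100L, n_chroms = 2L,
                      seed = 3L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(names(g1$genome), c("1", "2"))
  expect_identical(unname(nchar(g1$genome)), c(300L, 300L))
  expect_false(any(grepl("[^ACGT]", g1$genome)))
  expect_identical(nrow(g1$loci), 6L)
  expect_true(all(g1$loci$end - g1$loci$start + 1L == 100L))
  # a different seed changes the sequence
  expect_false(identical(
    g1$genome, simulate_genome(synth_config(n_genes = 6L, gene_span = 100L,
                                            n_chroms = 2L, seed = 4L))$genome))
})

test_that("synthetic knowledge graph has the configured structure", {
  cfg <- synth_config(n_genes = 10L, diseases_per_gene = 2L,
                      n_pathways = 3L, seed = 8L)
  kg <- simulate_kg(cfg)
  cnt <- edge_counts(kg$graph)
  expect_identical(unname(cnt["Disease-Gene (associated with)"]), 20L)
  expect_identical(unname(cnt["Protein-Gene (associated with)"]), 10L)
  expect_identical(unname(cnt["Pathway-Gene (interacts with)"]), 10L)
  # basic mode emits only the five core node types
  expect_true(all(kg$graph$nodes$node_type %in%
                    c("gene", "protein", "variant", "pathway", "disease")))
  # full mode adds the remaining seven
  kg_full <- simulate_kg(synth_config(n_genes = 10L, graph_mode = "full",
                                      seed = 8L))
  expect_setequal(unique(kg_full$graph$nodes$node_type),
                  setdiff(node_type_vocabulary(), "variant"))
  # fixed seed -> identical edge multiset
  kg2 <- simulate_kg(cfg)
  expect_identical(kg$graph$edges, kg2$graph$edges)
})

test_that("co-expression generator round-trips through the classifier", {
  cfg0 <- synth_config(n_genes = 4L, seed = 12L)
  pairs <- data.frame(protein_a = sprintf("p%d", 1:30),
                      protein_b = sprintf("q%d", 1:30))
  for (f in c(0, 0.5, 1)) {
    cfg <- synth_config(n_genes = 4L, transient_fraction = f, seed = 12L)
    coex <- simulate_coexpression(pairs, cfg)
    labels <- vapply(coex$profiles, function(pr)
      classify_ppi_temporal(pr$timecourse), character(1))
    planted <- vapply(coex$profiles, `[[`, character(1), "temporal_label")
    expect_identical(unname(labels), unname(planted))
    if (f == 0) expect_true(all(labels == "permanent"))
    if (f == 1) expect_true(all(labels == "transient"))
  }
  # empty pair list -> empty tables
  e <- simulate_coexpression(pairs[0, ], cfg0)
  expect_identical(nrow(e$timecourse), 0L)
  expect_length(e$profiles, 0L)
  # tissue correlations populate all five bins over enough pairs
  coex <- simulate_coexpression(pairs, cfg0)
  bins <- bin_tissue_coexpression(coex$tissue$tissue_r)
  expect_setequal(unique(bins), c("negative", "none", "low_positive",
                                  "medium_positive", "high_positive"))
})

test_that("simulated variants match the genome and exercise the filters", {
  cfg <- synth_config(n_genes = 6L, variants_per_gene = 20L, seed = 31L)
  gen <- simulate_genome(cfg)
  kg <- simulate_kg(cfg)
  v <- simulate_variants(gen, kg, cfg)
  expect_identical(nrow(v), 120L)
  expect_setequal(unique(v$var_class),
                  c("snv", "insertion", "deletion", "indel"))
  # reference alleles are read off the genome
  nonins <- v[v$var_class != "insertion", ]
  for (i in seq_len(nrow(nonins))) {
    expect_identical(substr(gen$genome[[nonins$chrom[i]]], nonins$pos[i],
                            nonins$pos[i] + nchar(nonins$ref[i]) - 1L),
                     nonins$ref[i])
  }
  # pathogenic variants carry a disease of their own gene
  path <- v[v$clinical_label == "pathogenic", ]
  for (i in seq_len(nrow(path))) {
    gene_dis <- strsplit(kg$genes$diseases[kg$genes$gene == path$gene[i]],
                         ";")[[1]]
    expect_true(path$diseases[i] %in% gene_dis)
  }
  # every context window extracts cleanly at a small W
  ctx <- extract_context_table(gen$genome, v, 21L)
  expect_true(all(nchar(ctx) == 21L))
  # with clean settings nothing is filtered; injected noise is counted
  expect_identical(nrow(filter_clinvar_records(v)), nrow(v))
  cfgb <- synth_config(n_genes = 6L, variants_per_gene = 20L,
                       bad_review_fraction = 0.3, seed = 31L)
  vb <- simulate_variants(gen, kg, cfgb)
  fb <- filter_clinvar_records(vb)
  n_bad <- sum(!(vb$review_status %in%
                   c("practice guideline", "reviewed by expert panel",
                     "criteria provided, multiple submitters, no conflicts",
                     "criteria provided, single submitter")))
  expect_gt(n_bad, 0L)
  expect_identical(unname(attr(fb, "drop_counts")["review_status"]), n_bad)
  expect_identical(nrow(fb), nrow(vb) - n_bad)
})

test_that("planted signal aligns pathogenic variants with their gene direction", {
  cfg <- synth_config(n_genes = 6L, variants_per_gene = 12L,
                      embed_dim = 24L, alpha = 0.9, seed = 17L)
  ds <- simulate_dataset(cfg)
  emb <- ds$embeddings
  # determinism
  expect_identical(plant_signal(ds$graph, ds$variants, cfg), emb)
  vids <- variant_id(ds$variants$chrom, ds$variants$pos, ds$variants$ref,
                     ds$variants$alt)
  gene_node <- setNames(ds$kg$genes$gene_id, ds$kg$genes$gene)
  dot <- vapply(seq_len(nrow(ds$variants)), function(i) {
    sum(emb$variant[vids[i], ] * emb$gene[gene_node[[ds$variants$gene[i]]], ])
  }, numeric(1))
  path <- ds$variants$clinical_label == "pathogenic"
  expect_gt(mean(dot[path]), 0.85)          # ~ sqrt(alpha) alignment
  expect_lt(mean(abs(dot[!path])), 0.2)     # benign uncorrelated
  # alpha = 0 removes the alignment entirely
  cfg0 <- synth_config(n_genes = 6L, variants_per_gene = 12L,
                       embed_dim = 24L, alpha = 0, seed = 17L)
  ds0 <- simulate_dataset(cfg0)
  dot0 <- vapply(seq_len(nrow(ds0$variants)), function(i) {
    sum(ds0$embeddings$variant[vids[i], ] *
          ds0$embeddings$gene[gene_node[[ds0$variants$gene[i]]], ])
  }, numeric(1))
  expect_lt(mean(abs(dot0[path])), 0.2)
  # all rows are unit-normalised
  expect_equal(unname(sqrt(rowSums(emb$variant^2))),
               rep(1, nrow(emb$variant)), tolerance = 1e-9)
})

test_that("direct mode plants a linearly separable disease-direction signal", {
  cfg <- synth_config(n_genes = 6L, variants_per_gene = 12L,
                      embed_dim = 24L, alpha = 1, signal_mode = "direct",
                      seed = 19L)
  ds <- simulate_dataset(cfg)
  vids <- variant_id(ds$variants$chrom, ds$variants$pos, ds$variants$ref,
                     ds$variants$alt)
  y <- as.integer(ds$variants$clinical_label == "pathogenic")
  X <- ds$embeddings$variant[vids, ]
  # a linear probe separates the classes near-perfectly at alpha = 1
  probe <- suppressWarnings(
    glm.fit(cbind(1, X), y, family = binomial()))
  acc <- mean((probe$fitted.values >= 0.5) == y)
  expect_gt(acc, 0.95)
})

test_that("simulated datasets satisfy the pipeline preconditions end to end", {
  ds <- small_dataset(seed = 23)
  expect_identical(rownames(ds$features), node_order(ds$graph))
  expect_gt(nrow(ds$pairs), 0L)
  expect_true(all(ds$pairs$label %in% 0:1))
  # every pair endpoint exists in the graph
  expect_true(all(c(ds$pairs$variant_id, ds$pairs$disease_id) %in%
                    ds$graph$nodes$node_id))
  # full run directory round-trips through the readers
  dir <- withr::local_tempdir()
  write_run_dir(ds, dir)
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, ds$genome)
  g2 <- read_edge_list(file.path(dir, "edges.tsv"))
  expect_identical(edge_counts(g2), edge_counts(ds$graph))
  v2 <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_identical(nrow(v2), nrow(ds$variants))
  X2 <- read_embedding_tsv(file.path(dir, "embeddings.tsv"))
  expect_equal(X2, ds$features, ignore_attr = TRUE, tolerance = 1e-12)
  tc <- read_timecourse_coexpression(
    file.path(dir, "timecourse_coexpression.tsv"))
  expect_true(all(tc$r >= -1 & tc$r <= 1))
})
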