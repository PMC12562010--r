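test_that("ClinVar-style filtering applies each rule and reports drops", {
  tab <- rbind(
    make_variant_row(clinical_label = "likely pathogenic"),
    make_variant_row(review_status = "no assertion criteria provided"),
    make_variant_row(origin = "somatic"),
    make_variant_row(assembly = "GRCh37"),
    make_variant_row(gene = " "),
    make_variant_row(chrom = "MT"),
    make_variant_row())  # the only survivor
  out <- filter_clinvar_records(tab)
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "drop_counts"),
                   c(label = 1L, review_status = 1L, origin = 1L,
                     assembly = 1L, gene = 1L, chromosome = 1L))
  # a mitochondrial record and soft labels are dropped
  expect_identical(nrow(filter_clinvar_records(
    make_variant_row(chrom = "MT"))), 0L)
  expect_identical(nrow(filter_clinvar_records(
    make_variant_row(clinical_label = "likely pathogenic"))), 0L)
  expect_error(filter_clinvar_records(tab[, -1]), "required field")
})

test_that("pair construction counts positives and negatives per the rules", {
  g <- gene_graph()  # GENEA: d1, d2; GENEB: d2
  v <- rbind(
    make_variant_row(pos = 5L, clinical_label = "pathogenic",
                     diseases = "disease one;disease two"),
    make_variant_row(pos = 9L, alt = "G"))
  g2 <- attach_variants(g, v)
  pairs <- build_pairs(g2, v)
  expect_identical(sum(pairs$label == 1L), 2L)
  expect_identical(sum(pairs$label == 0L), 2L)  # benign GENEA -> d1, d2
  # benign variant in a gene without disease edges yields nothing, warned
  g3 <- hetero_graph(rbind(g$nodes, data.frame(node_id = "g9",
                                               node_type = "gene",
                                               name = "GENEC")), g$edges)
  v3 <- make_variant_row(pos = 13L, gene = "GENEC")
  g3 <- attach_variants(g3, v3)
  expect_warning(p3 <- build_pairs(g3, v3), "no pairs")
  expect_identical(nrow(p3), 0L)
  expect_identical(attr(p3, "n_benign_skipped"), 1L)
  expect_identical(nrow(build_pairs(g2, v[0, ])), 0L)
})

test_that("random split has floor-based sizes with remainder to train", {
  mk <- function(n) data.frame(variant_id = sprintf("v%03d", 1:n),
                               disease_id = "d", label = rep_len(0:1, n),
                               gene = "G")
  s100 <- random_split(mk(100), seed = 1)
  expect_identical(vapply(s100, nrow, 1L),
                   c(train = 70L, validation = 15L, test = 15L))
  s101 <- random_split(mk(101), seed = 1)
  expect_identical(vapply(s101, nrow, 1L),
                   c(train = 71L, validation = 15L, test = 15L))
  # determinism and disjointness
  expect_identical(random_split(mk(50), seed = 9), random_split(mk(50), seed = 9))
  sp <- random_split(mk(50), seed = 2)
  ks <- lapply(sp, function(p) paste(p$variant_id, p$disease_id))
  expect_identical(length(unique(unlist(ks))), 50L)
  expect_error(random_split(mk(2), seed = 1), "degenerate")
})

test_that("per-gene balanced split reserves eval variants then matches classes", {
  # one gene, 5 benign + 3 pathogenic, one disease each
  g <- gene_graph()
  v <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      make_variant_row(pos = 4L * i + 1L))),
    do.call(rbind, lapply(6:8, function(i)
      make_variant_row(pos = 4L * i + 1L, clinical_label = "pathogenic",
                       diseases = "disease one"))))
  g2 <- attach_variants(g, v)
  sp <- per_gene_balanced_split(v, g2, seed = 3)
  # benign pairs double (GENEA links 2 diseases), pathogenic are 1 each:
  # after reserving 1 pathogenic + 1 benign, 4 benign (8 pairs) and
  # 2 pathogenic (2 pairs) remain -> 2 positives + 2 negatives in training
  expect_identical(sum(sp$train$label == 1L), sum(sp$train$label == 0L))
  expect_identical(sum(sp$train$label == 1L), 2L)
  # reserved variants are of different classes
  val_lab <- unique(sp$validation$label)
  test_lab <- unique(sp$test$label)
  expect_identical(length(val_lab), 1L)
  expect_false(identical(val_lab, test_lab))
  expect_identical(per_gene_balanced_split(v, g2, seed = 3), sp)

  # single-variant gene goes to training with a warning
  v1 <- make_variant_row(pos = 9L, gene = "GENEB", alt = "G")
  g4 <- attach_variants(g, v1)
  expect_warning(per_gene_balanced_split(v1, g4, seed = 1),
                 "single variant")
})

test_that("per-gene balance holds for every two-class gene on a synthetic set", {
  ds <- small_dataset(seed = 21)
  sp <- per_gene_balanced_split(ds$variants, ds$graph, seed = 4)
  pathogenic_of <- setNames(ds$variants$clinical_label,
                            variant_id(ds$variants$chrom, ds$variants$pos,
                                       ds$variants$ref, ds$variants$alt))
  for (g in unique(sp$train$gene)) {
    tp <- sp$train[sp$train$gene == g, ]
    expect_identical(sum(tp$label == 1L), sum(tp$label == 0L), label = g)
  }
  # partitions disjoint on (variant, disease)
  ks <- lapply(sp[c("train", "validation", "test")],
               function(p) paste(p$variant_id, p$disease_id))
  expect_identical(anyDuplicated(unlist(ks)), 0L)
})

test_that("date split uses the cutoff, 80/20 pre-split, and reports undated", {
  g <- gene_graph()
  v <- rbind(
    do.call(rbind, lapply(1:10, function(i) make_variant_row(
      pos = 4L * i + 1L,
      submission_date = sprintf("20%d-05-01", 18 + (i %% 4))))),
    make_variant_row(pos = 61L, submission_date = "2023-02-01"),
    make_variant_row(pos = 65L, submission_date = ""))
  g2 <- attach_variants(g, v)
  sp <- date_split(v, g2, cutoff_year = 2022, seed = 2)
  expect_identical(attr(sp, "n_undated"), 1L)
  # 10 pre-cutoff variants x 2 diseases = 20 pairs -> 16 train / 4 val
  expect_identical(nrow(sp$train), 16L)
  expect_identical(nrow(sp$validation), 4L)
  expect_identical(nrow(sp$test), 2L)  # the 2023 benign variant, 2 diseases
  expect_error(date_split(v[1:10, ], g2, cutoff_year = 2024, seed = 1),
               "empty test")
})

test_that("training reduces loss, selects on validation, and is reproducible", {
  ds <- small_dataset(seed = 5)
  sp <- random_split(ds$pairs, seed = 5)
  ctl <- patho_control(epochs = 10L, patience = 10L, seed = 5,
                       encoder_dims = c(24L, 12L), decoder_dims = c(12L, 6L))
  fit <- patho_fit(ds$graph, ds$features, sp, model = "gcn", control = ctl)
  expect_s3_class(fit, "patho_fit")
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  # fixed seed => bit-identical history and evaluation
  fit2 <- patho_fit(ds$graph, ds$features, sp, model = "gcn", control = ctl)
  expect_identical(fit$history, fit2$history)
  expect_identical(evaluate(fit)$rates, evaluate(fit2)$rates)
  # zero epochs returns the initial state untouched
  ctl0 <- patho_control(epochs = 0L, seed = 5, encoder_dims = c(24L, 12L),
                        decoder_dims = c(12L, 6L))
  fit0 <- patho_fit(ds$graph, ds$features, sp, model = "gcn", control = ctl0)
  expect_identical(fit0$params,
                   init_patho_params(ncol(ds$features), c(24L, 12L),
                                     c(12L, 6L), seed = 5))
  expect_identical(nrow(fit0$history), 0L)
})

test_that("the training adjacency never contains Disease-Variant edges", {
  ds <- small_dataset(seed = 6)
  sp <- random_split(ds$pairs, seed = 6)
  ctl <- patho_control(epochs = 3L, seed = 6, encoder_dims = c(16L, 8L),
                       decoder_dims = c(8L, 4L))
  fit <- patho_fit(ds$graph, ds$features, sp, model = "gcn", control = ctl)
  expect_false("Disease-Variant (associated with)" %in%
                 active_edges(fit$graph)$edge_type)
  # ... while the underlying store still holds them (mask, not removal)
  expect_gt(sum(fit$graph$edges$edge_type ==
                  "Disease-Variant (associated with)"), 0L)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  ds <- small_dataset(seed = 9)
  sp <- random_split(ds$pairs, seed = 9)
  ctl <- patho_control(epochs = 5L, seed = 9, encoder_dims = c(16L, 8L),
                       decoder_dims = c(8L, 4L))
  fit <- patho_fit(ds$graph, ds$features, sp, model = "gcn", control = ctl)
  expect_named(coef(fit), c("W0", "b0", "W1", "b1", "L1", "c1", "L2", "c2",
                            "L3", "c3"))
  p <- predict(fit)
  expect_identical(length(p), nrow(sp$test))
  expect_true(all(p > 0 & p < 1))
  cls <- predict(fit, type = "class")
  expect_true(all(cls %in% 0:1))
  expect_identical(residuals(fit), sp$train$label - fitted(fit))
  expect_output(print(fit), "pathogenicity model")
  expect_output(print(summary(fit)), "balanced accuracy")
  rep <- evaluate(fit)
  expect_true(all(!is.na(rep$rates[c("balanced_accuracy")])))
  expect_error(evaluate(fit, pairs = sp$test[0, ]), "empty pair list")
  # baselines fit through the same interface
  fb <- patho_fit(ds$graph, ds$features, sp, model = "baseline_variant",
                  control = ctl)
  expect_identical(length(predict(fb)), nrow(sp$test))
})
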