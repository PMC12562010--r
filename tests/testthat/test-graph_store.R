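test_that("graph construction enforces vocabularies and collapses duplicates", {
  g <- protein_graph()
  expect_s3_class(g, "hetero_graph")
  expect_error(hetero_graph(
    data.frame(node_id = "x", node_type = "widget", name = "x")),
    "unknown node type")
  expect_error(hetero_graph(
    g$nodes, rbind(g$edges, data.frame(src = "P1", dst = "P2",
                                       edge_type = "Protein-Protein (magic)"))),
    "unknown edge type")
  expect_error(hetero_graph(
    g$nodes, data.frame(src = "P1", dst = "pw1",
                        edge_type = "Disease-Gene (associated with)")),
    "incompatible")
  # duplicate same-type same-pair edges collapse, opposite orientation too
  dup <- rbind(g$edges, data.frame(src = "P2", dst = "P1",
                                   edge_type = "Protein-Protein (permanent PPI)"))
  expect_identical(nrow(hetero_graph(g$nodes, dup)$edges), nrow(g$edges))
})

test_that("split_protein_nodes rewires Gene-named edges and keeps PPI edges", {
  g <- split_protein_nodes(protein_graph())
  # one gene node added per protein, joined by a Protein-Gene edge
  expect_identical(sum(g$nodes$node_type == "gene"), 2L)
  expect_identical(unname(edge_counts(g)["Protein-Gene (associated with)"]), 2L)
  ntype <- setNames(g$nodes$node_type, g$nodes$node_id)
  for (i in seq_len(nrow(g$edges))) {
    et <- g$edges$edge_type[i]
    endpoint_types <- ntype[c(g$edges$src[i], g$edges$dst[i])]
    if (grepl("Gene", et) && !grepl("Protein", et)) {
      expect_false("protein" %in% endpoint_types, label = et)
    }
  }
  # PPI edge still joins the two protein nodes
  ppi <- g$edges[g$edges$edge_type == "Protein-Protein (permanent PPI)", ]
  expect_setequal(c(ppi$src, ppi$dst), c("P1", "P2"))
  # identity on empty graph; counting on edgeless proteins
  expect_identical(nrow(split_protein_nodes(hetero_graph())$nodes), 0L)
  bare <- hetero_graph(data.frame(node_id = c("a", "b"),
                                  node_type = "protein", name = c("A", "B")))
  sb <- split_protein_nodes(bare)
  expect_identical(nrow(sb$nodes), 4L)
  expect_identical(nrow(sb$edges), 2L)
})

test_that("attach_variants adds variant, disease nodes and edges per the rules", {
  g <- gene_graph()
  v <- rbind(
    make_variant_row(pos = 5L, clinical_label = "pathogenic",
                     diseases = "disease one;disease three"),
    make_variant_row(pos = 9L, alt = "G"))
  g2 <- attach_variants(g, v)
  # 2 variant nodes, 1 new disease ("disease three"), 2 Variant-Gene edges,
  # 2 Disease-Variant edges (benign contributes none)
  expect_identical(sum(g2$nodes$node_type == "variant"), 2L)
  expect_identical(sum(g2$nodes$node_type == "disease"), 3L)
  cnt <- edge_counts(g2)
  expect_identical(unname(cnt["Variant-Gene (associated with)"]), 2L)
  expect_identical(unname(cnt["Disease-Variant (associated with)"]), 2L)
  # disease matching folds case/whitespace
  g3 <- attach_variants(g, make_variant_row(
    pos = 5L, clinical_label = "pathogenic", diseases = "  DISEASE One "))
  expect_identical(sum(g3$nodes$node_type == "disease"), 2L)
  # idempotence
  expect_identical(attach_variants(g2, v)$edges, g2$edges)
  expect_identical(nrow(attach_variants(g, v[0, ])$nodes), nrow(g$nodes))
  expect_error(attach_variants(g, make_variant_row(gene = "NOPE")), "NOPE")
})

test_that("PPI temporal classification follows the majority rule", {
  expect_identical(classify_ppi_temporal(numeric()), "unlabeled")
  expect_identical(classify_ppi_temporal(c(0.05, 0.02, 0.5)), "transient")
  expect_identical(classify_ppi_temporal(c(0.05, 0.5)), "permanent")  # tie
  expect_identical(classify_ppi_temporal(c(0.5, 0.6, 0.09)), "permanent")
  expect_error(classify_ppi_temporal(c(0.2, 1.5)), "outside")
  # permutation invariance
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- runif(sample(1:7, 1), -1, 1)
      expect_identical(classify_ppi_temporal(x),
                       classify_ppi_temporal(sample(x)))
    }
  })
})

test_that("tissue co-expression binning uses the configured thresholds", {
  expect_identical(bin_tissue_coexpression(0), "none")
  expect_identical(bin_tissue_coexpression(0.95), "high_positive")
  expect_identical(bin_tissue_coexpression(-0.5), "negative")
  expect_identical(bin_tissue_coexpression(c(-0.1, 0.1, 0.4, 0.7)),
                   c("negative", "low_positive", "medium_positive",
                     "high_positive"))
  expect_error(bin_tissue_coexpression(1.2), "outside")
  # custom thresholds move the bin edges
  expect_identical(bin_tissue_coexpression(0.5, c(-0.2, 0.2, 0.6, 0.8)),
                   "low_positive")
})

test_that("edge masking hides a type without touching the store", {
  g <- gene_graph()
  v <- rbind(
    make_variant_row(pos = 5L, clinical_label = "pathogenic",
                     diseases = "disease one"),
    make_variant_row(pos = 9L, alt = "G", clinical_label = "pathogenic",
                     diseases = "disease two"))
  g2 <- attach_variants(g, v)
  dv <- "Disease-Variant (associated with)"
  masked <- mask_edges(g2, dv)
  expect_identical(nrow(active_edges(masked)),
                   nrow(active_edges(g2)) - 2L)
  expect_identical(sum(active_edges(masked)$edge_type == dv), 0L)
  # conservation: masked view + masked-out records = full multiset
  hidden <- masked$edges[masked$edges$edge_type %in% masked$masked_types, ]
  expect_identical(nrow(active_edges(masked)) + nrow(hidden),
                   nrow(g2$edges))
  # masking an absent type changes nothing; mask-unmask is the identity
  expect_identical(active_edges(mask_edges(g2, "Drug-Protein (target)")),
                   active_edges(g2))
  expect_identical(active_edges(unmask_edges(masked)), active_edges(g2))
  expect_error(mask_edges(g2, "No-Such (edge)"), "unknown edge type")
  # adjacency drops masked pairs
  expect_lt(sum(adjacency_matrix(masked)), sum(adjacency_matrix(g2)))
})

test_that("edge-list round-trip is exact on ids, types and counts", {
  g <- attach_variants(gene_graph(), make_variant_row(
    pos = 5L, clinical_label = "pathogenic", diseases = "disease one"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_setequal(g2$nodes$node_id, g$nodes$node_id)
  ord <- function(e) e[order(e$src, e$dst, e$edge_type), ]
  expect_equal(ord(g2$edges), ord(g$edges), ignore_attr = TRUE)
  expect_identical(edge_counts(g2), edge_counts(g))

  # unknown node type token rejected with line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("src_id\tsrc_type\tdst_id\tdst_type\tedge_type",
               "a\twidget\tb\tgene\tDisease-Gene (associated with)"), bad)
  expect_error(read_edge_list(bad), "unknown node_type token at line 2")

  # empty file with header gives an empty graph
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("src_id\tsrc_type\tdst_id\tdst_type\tedge_type", empty)
  ge <- read_edge_list(empty)
  expect_identical(nrow(ge$nodes), 0L)
  expect_identical(nrow(ge$edges), 0L)
})

test_that("ppi_edge_records emits a temporal edge plus a co-expression edge", {
  pairs <- data.frame(protein_a = "P1", protein_b = "P2")
  profiles <- list("P1|P2" = list(timecourse = c(0.05, 0.03, 0.7),
                                  tissue_r = 0.85))
  rec <- ppi_edge_records(pairs, profiles)
  expect_identical(rec$edge_type,
                   c("Protein-Protein (transient PPI)",
                     "Protein-Protein (high positive co-expression PPI)"))
  # missing profile -> unlabeled, no co-expression edge
  rec2 <- ppi_edge_records(pairs, list())
  expect_identical(rec2$edge_type, "Protein-Protein (unlabeled PPI)")
})
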