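## ---------------------------------------------------------------------------
## Seeded synthetic-data generators
##
## Produce every input the pipeline consumes -- toy genome, typed knowledge
## graph, co-expression profiles, ClinVar-style variant table, and node
## embeddings with a tunable planted variant-disease signal -- so the whole
## method is testable at desk scale without any external download.
## ---------------------------------------------------------------------------

#' Synthetic-data configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 50 genes with 2 diseases each, 40 variants per gene at a
#' pathogenic fraction of 0.5, a protein-protein interaction density of 0.1
#' with 5 co-expression experiments, 64-dimensional embeddings and a planted
#' signal strength of `alpha = 0.9` in relational mode.
#'
#' @param n_genes Number of genes.
#' @param diseases_per_gene Diseases linked to each gene.
#' @param variants_per_gene Variants simulated per gene.
#' @param pathogenic_fraction Probability a variant is pathogenic.
#' @param n_pathways Number of pathway nodes grouping the genes.
#' @param ppi_density Probability that a protein pair interacts.
#' @param n_experiments Time-course co-expression experiments per PPI.
#' @param transient_fraction Fraction of PPIs generated as transient.
#' @param embed_dim Embedding width.
#' @param alpha Planted signal strength in \[0, 1\]; 0 removes all label
#'   signal from the embeddings.
#' @param signal_mode `"relational"` plants the pathogenicity direction in
#'   the gene embeddings, reachable only through the graph; `"direct"`
#'   plants disease directions straight into variant embeddings.
#' @param signal_share In direct mode, the shared-component weight of the
#'   disease directions (makes the planted classes linearly separable).
#' @param graph_mode `"basic"` emits only gene/protein/variant/pathway/
#'   disease nodes; `"full"` adds stub nodes of the remaining types.
#' @param gene_span Bases of toy chromosome allocated per gene.
#' @param n_chroms Number of toy chromosomes.
#' @param bad_review_fraction Fraction of variants given a disallowed review
#'   status (to exercise the filtering rules).
#' @param undated_fraction Fraction of variants without a submission date.
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so a fixed seed gives bit-identical outputs.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_genes = 50L, diseases_per_gene = 2L,
                         variants_per_gene = 40L, pathogenic_fraction = 0.5,
                         n_pathways = 10L, ppi_density = 0.1,
                         n_experiments = 5L, transient_fraction = 0.5,
                         embed_dim = 64L, alpha = 0.9,
                         signal_mode = c("relational", "direct"),
                         signal_share = 0.5,
                         graph_mode = c("basic", "full"),
                         gene_span = 400L, n_chroms = 2L,
                         bad_review_fraction = 0,
                         undated_fraction = 0.1, seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  graph_mode <- match.arg(graph_mode)
  stopifnot(n_genes >= 1L, diseases_per_gene >= 1L, variants_per_gene >= 1L,
            alpha >= 0, alpha <= 1, pathogenic_fraction >= 0,
            pathogenic_fraction <= 1, embed_dim >= 1L, n_experiments >= 1L,
            gene_span >= 20L)
  structure(list(n_genes = as.integer(n_genes),
                 diseases_per_gene = as.integer(diseases_per_gene),
                 variants_per_gene = as.integer(variants_per_gene),
                 pathogenic_fraction = pathogenic_fraction,
                 n_pathways = as.integer(n_pathways),
                 ppi_density = ppi_density,
                 n_experiments = as.integer(n_experiments),
                 transient_fraction = transient_fraction,
                 embed_dim = as.integer(embed_dim), alpha = alpha,
                 signal_mode = signal_mode, signal_share = signal_share,
                 graph_mode = graph_mode, gene_span = as.integer(gene_span),
                 n_chroms = as.integer(n_chroms),
                 bad_review_fraction = bad_review_fraction,
                 undated_fraction = undated_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% 2147483647L)
  expr
}

.gene_names <- function(config) sprintf("GENE%02d", seq_len(config$n_genes))

#' Simulate a toy genome with gene loci
#'
#' Uniform-random A/C/G/T chromosomes, `gene_span` bases allocated per gene,
#' genes laid out contiguously across `n_chroms` chromosomes.
#'
#' @param config A [synth_config()].
#' @return List with `genome` (named character vector) and `loci`
#'   (data.frame `gene`, `chrom`, `start`, `end`).
#' @export
simulate_genome <- function(config) {
  .with_seed(config$seed + 101L, {
    genes <- .gene_names(config)
    per_chrom <- ceiling(config$n_genes / config$n_chroms)
    chrom_of <- as.character(((seq_len(config$n_genes) - 1L) %/% per_chrom) + 1L)
    slot <- ((seq_len(config$n_genes) - 1L) %% per_chrom)
    start <- slot * config$gene_span + 1L
    end <- start + config$gene_span - 1L
    genome <- character()
    for (ch in unique(chrom_of)) {
      len <- max(end[chrom_of == ch])
      genome[[ch]] <- paste(sample(c("A", "C", "G", "T"), len,
                                   replace = TRUE), collapse = "")
    }
    list(genome = genome,
         loci = data.frame(gene = genes, chrom = chrom_of, start = start,
                           end = end, stringsAsFactors = FALSE))
  })
}

#' Simulate co-expression profiles for PPI pairs
#'
#' For a `transient_fraction` of pairs the per-experiment time-course
#' correlations fall below the transient threshold (0.1) in a strict
#' majority of experiments; for the remainder in at most half, so
#' [classify_ppi_temporal()] recovers each pair's generated label exactly.
#' Tissue correlations are drawn uniformly over the five co-expression bins.
#'
#' @param ppi_pairs data.frame with `protein_a`, `protein_b`.
#' @param config A [synth_config()].
#' @return List with `profiles` (named list keyed `"<a>|<b>"`, each with
#'   `timecourse`, `tissue_r` and the generated `temporal_label`),
#'   `timecourse` and `tissue` data.frames in the on-disk TSV layouts.
#' @export
simulate_coexpression <- function(ppi_pairs, config) {
  ppi_pairs <- as.data.frame(ppi_pairs, stringsAsFactors = FALSE)
  .with_seed(config$seed + 202L, {
    n_exp <- config$n_experiments
    profiles <- list()
    tc_rows <- list(); ti_rows <- list()
    bins <- list(c(-1, -0.11), c(-0.09, 0.09), c(0.11, 0.39), c(0.41, 0.69),
                 c(0.71, 1))
    for (i in seq_len(nrow(ppi_pairs))) {
      a <- ppi_pairs$protein_a[i]; b <- ppi_pairs$protein_b[i]
      transient <- stats::runif(1) < config$transient_fraction
      max_perm_low <- floor(n_exp / 2)  # tie counts as permanent
      n_low <- if (transient) {
        sample((max_perm_low + 1L):n_exp, 1L)
      } else {
        sample(0:max_perm_low, 1L)
      }
      lows <- stats::runif(n_low, -1, 0.09)
      highs <- stats::runif(n_exp - n_low, 0.11, 1)
      tc <- sample(c(lows, highs))
      bin <- bins[[sample.int(5L, 1L)]]
      tr <- stats::runif(1, bin[1L], bin[2L])
      profiles[[paste(a, b, sep = "|")]] <-
        list(timecourse = tc, tissue_r = tr,
             temporal_label = if (transient) "transient" else "permanent")
      tc_rows[[i]] <- data.frame(gene_a = a, gene_b = b,
                                 experiment_id = paste0("exp", seq_len(n_exp)),
                                 r = tc, stringsAsFactors = FALSE)
      ti_rows[[i]] <- data.frame(gene_a = a, gene_b = b, tissue_r = tr,
                                 stringsAsFactors = FALSE)
    }
    list(profiles = profiles,
         timecourse = do.call(rbind, c(list(data.frame(
           gene_a = character(), gene_b = character(),
           experiment_id = character(), r = numeric())), tc_rows)),
         tissue = do.call(rbind, c(list(data.frame(
           gene_a = character(), gene_b = character(),
           tissue_r = numeric())), ti_rows)))
  })
}

#' Simulate the typed knowledge graph
#'
#' Genes are linked 1:1 to proteins, to `diseases_per_gene` diseases each,
#' and round-robin to pathways; protein pairs interact with probability
#' `ppi_density` and receive temporal and tissue co-expression edge types
#' from [simulate_coexpression()]. In `"full"` mode one stub node per
#' remaining node type is added with a representative edge so all 12 types
#' are exercised; `"basic"` mode emits only the five core types.
#'
#' @param config A [synth_config()].
#' @return List with `graph` (a `hetero_graph`, no variants yet), `genes`
#'   (data.frame `gene`, `gene_id`, `protein_id`, `diseases`), `ppi_pairs`
#'   and `coexpression` (the [simulate_coexpression()] output).
#' @export
simulate_kg <- function(config) {
  genes <- .gene_names(config)
  gene_ids <- paste0("gene:", genes)
  prot_ids <- paste0("prot:", genes)
  k <- config$diseases_per_gene
  disease_names <- sprintf("disease %03d", seq_len(config$n_genes * k))
  disease_ids <- sprintf("disease:d%03d", seq_len(config$n_genes * k))
  pathway_ids <- sprintf("pathway:pw%02d", seq_len(config$n_pathways))

  nodes <- rbind(
    data.frame(node_id = gene_ids, node_type = "gene", name = genes,
               stringsAsFactors = FALSE),
    data.frame(node_id = prot_ids, node_type = "protein",
               name = paste(genes, "protein"), stringsAsFactors = FALSE),
    data.frame(node_id = disease_ids, node_type = "disease",
               name = disease_names, stringsAsFactors = FALSE),
    data.frame(node_id = pathway_ids, node_type = "pathway",
               name = sprintf("pathway %02d", seq_len(config$n_pathways)),
               stringsAsFactors = FALSE)
  )

  dg <- data.frame(
    src = rep(disease_ids, 1L),
    dst = rep(gene_ids, each = k),
    edge_type = "Disease-Gene (associated with)", stringsAsFactors = FALSE)
  pg <- data.frame(src = prot_ids, dst = gene_ids,
                   edge_type = "Protein-Gene (associated with)",
                   stringsAsFactors = FALSE)
  pw <- data.frame(
    src = pathway_ids[((seq_along(gene_ids) - 1L) %% config$n_pathways) + 1L],
    dst = gene_ids, edge_type = "Pathway-Gene (interacts with)",
    stringsAsFactors = FALSE)

  ppi_pairs <- .with_seed(config$seed + 303L, {
    cmb <- utils::combn(prot_ids, 2L)
    keep <- stats::runif(ncol(cmb)) < config$ppi_density
    data.frame(protein_a = cmb[1L, keep], protein_b = cmb[2L, keep],
               stringsAsFactors = FALSE)
  })
  coex <- simulate_coexpression(ppi_pairs, config)
  ppi_edges <- ppi_edge_records(ppi_pairs, coex$profiles)

  edges <- rbind(dg, pg, pw, ppi_edges)

  if (config$graph_mode == "full") {
    stubs <- data.frame(
      node_id = c("phen:stub", "drug:stub", "mf:stub", "bp:stub", "cc:stub",
                  "exp:stub", "anat:stub"),
      node_type = c("phenotype", "drug", "molecular_function",
                    "biological_process", "cellular_component", "exposure",
                    "anatomy"),
      name = c("stub phenotype", "stub drug", "stub molecular function",
               "stub biological process", "stub cellular component",
               "stub exposure", "stub anatomy"), stringsAsFactors = FALSE)
    nodes <- rbind(nodes, stubs)
    edges <- rbind(edges, data.frame(
      src = c(disease_ids[1L], "drug:stub", "mf:stub", "bp:stub", "cc:stub",
              "exp:stub", "anat:stub"),
      dst = c("phen:stub", prot_ids[1L], gene_ids[1L], gene_ids[1L],
              gene_ids[1L], disease_ids[1L], gene_ids[1L]),
      edge_type = c("Disease-Phenotype (phenotype present)",
                    "Drug-Protein (target)",
                    "Molecular function-Gene (interacts with)",
                    "Bioprocess-Gene (interacts with)",
                    "Cellular component-Gene (interacts with)",
                    "Exposure-Disease (linked to)",
                    "Anatomy-Gene (expression present)"),
      stringsAsFactors = FALSE))
  }

  gene_diseases <- vapply(seq_along(genes), function(i) {
    paste(disease_names[(i - 1L) * k + seq_len(k)], collapse = ";")
  }, character(1))

  list(graph = hetero_graph(nodes, edges),
       genes = data.frame(gene = genes, gene_id = gene_ids,
                          protein_id = prot_ids, diseases = gene_diseases,
                          stringsAsFactors = FALSE),
       ppi_pairs = ppi_pairs, coexpression = coex)
}

.random_date <- function(n, years = 2019:2024) {
  sprintf("%d-%02d-%02d", sample(years, n, replace = TRUE),
          sample(12L, n, replace = TRUE), sample(28L, n, replace = TRUE))
}

.bad_review_statuses <- c("no assertion criteria provided",
                          "criteria provided, conflicting interpretations")

#' Simulate a ClinVar-style variant table
#'
#' Per gene, `variants_per_gene` variants at distinct loci within the gene
#' territory with reference alleles read from the toy genome (so reference
#' checks pass). Classes cycle through snv (70%), insertion, deletion and
#' indel (10% each); pathogenic variants (probability
#' `pathogenic_fraction`) are assigned one disease drawn from their gene's
#' diseases. Labels, review statuses, origins, assemblies and submission
#' dates are populated so every filtering rule and the date split are
#' exercisable; `bad_review_fraction` injects disallowed review statuses
#' and `undated_fraction` blanks submission dates.
#'
#' @param genome_obj Output of [simulate_genome()].
#' @param kg Output of [simulate_kg()].
#' @param config A [synth_config()].
#' @return A variant table data.frame (see [read_variant_table()]).
#' @export
simulate_variants <- function(genome_obj, kg, config) {
  loci <- genome_obj$loci
  genome <- genome_obj$genome
  class_cycle <- c(rep("snv", 7L), "insertion", "deletion", "indel")
  .with_seed(config$seed + 404L, {
    rows <- list()
    for (i in seq_len(nrow(loci))) {
      g <- loci$gene[i]
      chrom <- loci$chrom[i]
      n <- config$variants_per_gene
      # interior positions, spaced so multi-base ref segments never collide
      cand <- seq(loci$start[i] + 5L, loci$end[i] - 8L, by = 4L)
      pos <- sort(sample(cand, n))
      cls <- class_cycle[((seq_len(n) - 1L) %% length(class_cycle)) + 1L]
      pathogenic <- stats::runif(n) < config$pathogenic_fraction
      gene_dis <- .split_diseases(kg$genes$diseases[kg$genes$gene == g])
      ref <- character(n); alt <- character(n)
      for (j in seq_len(n)) {
        base_at <- function(p, len = 1L) substr(genome[[chrom]], p, p + len - 1L)
        if (cls[j] == "snv") {
          ref[j] <- base_at(pos[j])
          alt[j] <- sample(setdiff(c("A", "C", "G", "T"), ref[j]), 1L)
        } else if (cls[j] == "insertion") {
          ref[j] <- ""
          alt[j] <- paste(sample(c("A", "C", "G", "T"),
                                 sample(3L, 1L), replace = TRUE),
                          collapse = "")
        } else if (cls[j] == "deletion") {
          ref[j] <- base_at(pos[j], sample(3L, 1L))
          alt[j] <- ""
        } else {
          ref[j] <- base_at(pos[j], sample(3L, 1L))
          alt[j] <- paste(sample(c("A", "C", "G", "T"),
                                 sample(3L, 1L), replace = TRUE),
                          collapse = "")
        }
      }
      review <- ifelse(stats::runif(n) < config$bad_review_fraction,
                       sample(.bad_review_statuses, n, replace = TRUE),
                       sample(.allowed_review_status, n, replace = TRUE))
      dates <- .random_date(n)
      dates[stats::runif(n) < config$undated_fraction] <- ""
      diseases <- ifelse(pathogenic,
                         vapply(seq_len(n), function(j)
                           sample(gene_dis, 1L), character(1)),
                         "")
      rows[[i]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, var_class = cls,
        gene = g,
        clinical_label = ifelse(pathogenic, "pathogenic", "benign"),
        review_status = review, origin = "germline", assembly = "GRCh38",
        submission_date = dates, diseases = diseases,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

.unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  l2_normalize(m)
}

#' Plant a recoverable variant-disease signal into node embeddings
#'
#' Generates per-type embedding matrices for every node of the
#' variant-attached graph. In `"relational"` mode each gene receives a
#' random unit direction that becomes its own embedding; a pathogenic
#' variant's embedding is the unit-normalised mixture
#' `sqrt(alpha) * u_gene + sqrt(1 - alpha) * noise`, while benign variants
#' and all remaining nodes are isotropic random unit vectors — the
#' pathogenicity direction is therefore reachable only by comparing a
#' variant against its gene through the graph. In `"direct"` mode each
#' disease receives a direction sharing a common component (weight
#' `signal_share`), the disease node embeds its own direction, and
#' pathogenic variants mix in the mean direction of their associated
#' diseases, which makes the classes separable from the raw embeddings
#' alone.
#'
#' With `alpha = 0` variant embeddings are statistically independent of the
#' labels in both modes.
#'
#' @param graph Variant-attached `hetero_graph`.
#' @param variants The attached variant table.
#' @param config A [synth_config()].
#' @return Named list of embedding matrices, one per node type present,
#'   directly usable as `providers` in [assemble_initial_features()].
#' @export
plant_signal <- function(graph, variants, config) {
  stopifnot(inherits(graph, "hetero_graph"))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  d <- config$embed_dim
  alpha <- config$alpha
  .with_seed(config$seed + 505L, {
    out <- list()
    ntab <- graph$nodes
    gene_ids <- ntab$node_id[ntab$node_type == "gene"]
    dis_ids <- ntab$node_id[ntab$node_type == "disease"]
    var_ids <- ntab$node_id[ntab$node_type == "variant"]

    gene_dirs <- .unit_rows(length(gene_ids), d)
    rownames(gene_dirs) <- gene_ids

    p0 <- drop(.unit_rows(1L, d))
    dis_dirs <- .unit_rows(length(dis_ids), d)
    if (config$signal_mode == "direct") {
      dis_dirs <- l2_normalize(sqrt(config$signal_share) *
                                 matrix(p0, length(dis_ids), d, byrow = TRUE) +
                               sqrt(1 - config$signal_share) * dis_dirs)
    }
    rownames(dis_dirs) <- dis_ids

    gene_node_of <- stats::setNames(
      ntab$node_id[ntab$node_type == "gene"],
      ntab$name[ntab$node_type == "gene"])
    dis_node_of <- stats::setNames(
      dis_ids, .norm_disease_key(ntab$name[match(dis_ids, ntab$node_id)]))

    vid <- variant_id(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
    V <- .unit_rows(length(var_ids), d)
    rownames(V) <- var_ids
    for (i in seq_len(nrow(variants))) {
      if (!identical(variants$clinical_label[i], "pathogenic")) next
      id <- vid[i]
      if (!(id %in% var_ids)) next
      direction <- if (config$signal_mode == "relational") {
        gene_dirs[gene_node_of[[variants$gene[i]]], ]
      } else {
        ds <- dis_node_of[.norm_disease_key(.split_diseases(
          variants$diseases[i]))]
        l2_normalize(colMeans(dis_dirs[ds, , drop = FALSE]))
      }
      V[id, ] <- l2_normalize(sqrt(alpha) * direction +
                                sqrt(1 - alpha) * V[id, ])
    }

    out$gene <- gene_dirs
    out$disease <- dis_dirs
    out$variant <- V
    for (tp in setdiff(unique(ntab$node_type),
                       c("gene", "disease", "variant"))) {
      ids <- ntab$node_id[ntab$node_type == tp]
      m <- .unit_rows(length(ids), d)
      rownames(m) <- ids
      out[[tp]] <- m
    }
    out
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' One-call orchestrator: toy genome, knowledge graph, variant table,
#' variant attachment, planted-signal embeddings, assembled feature matrix
#' and labelled pairs.
#'
#' @param config A [synth_config()].
#' @return List with `config`, `genome`, `loci`, `kg`, `variants`, `graph`
#'   (variants attached), `embeddings`, `features`, `pairs`.
#' @export
simulate_dataset <- function(config = synth_config()) {
  gen <- simulate_genome(config)
  kg <- simulate_kg(config)
  variants <- simulate_variants(gen, kg, config)
  graph <- attach_variants(kg$graph, variants)
  emb <- plant_signal(graph, variants, config)
  features <- assemble_initial_features(graph, emb)
  pairs <- build_pairs(graph, variants)
  list(config = config, genome = gen$genome, loci = gen$loci, kg = kg,
       variants = variants, graph = graph, embeddings = emb,
       features = features, pairs = pairs)
}

#' Materialise a simulated dataset as a run directory
#'
#' Writes the FASTA/TSV files the ingestion functions read: `genome.fa`,
#' `nodes.tsv`, `edges.tsv`, `variants.tsv`, `timecourse_coexpression.tsv`,
#' `tissue_coexpression.tsv` and `embeddings.tsv`.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_run_dir <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_node_table(dataset$graph$nodes, file.path(dir, "nodes.tsv"))
  write_edge_list(dataset$graph, file.path(dir, "edges.tsv"))
  write_variant_table(dataset$variants, file.path(dir, "variants.tsv"))
  .write_tsv(dataset$kg$coexpression$timecourse,
             file.path(dir, "timecourse_coexpression.tsv"))
  .write_tsv(dataset$kg$coexpression$tissue,
             file.path(dir, "tissue_coexpression.tsv"))
  write_embedding_tsv(dataset$features, file.path(dir, "embeddings.tsv"))
  invisible(dir)
}
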