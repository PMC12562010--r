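## ---------------------------------------------------------------------------
## Typed heterogeneous knowledge-graph store
##
## Nodes carry one of 12 closed types; edges carry a type from the controlled
## vocabulary below.  Adjacency semantics are undirected; parallel edges of
## *different* types between the same node pair are allowed, duplicates of the
## same type are collapsed.  A set of masked edge types is carried with the
## graph: every adjacency view excludes masked types while the underlying
## store keeps them (used to hide Disease-Variant label edges at train time).
## ---------------------------------------------------------------------------

.node_types <- c(
  "gene", "protein", "variant", "disease", "phenotype", "drug", "pathway",
  "molecular_function", "biological_process", "cellular_component",
  "exposure", "anatomy"
)

.edge_types <- c(
  "Drug-Drug (synergistic interaction)",
  "Anatomy-Gene (expression present)",
  "Protein-Protein (transient PPI)",
  "Variant-Gene (associated with)",
  "Protein-Protein (permanent PPI)",
  "Disease-Variant (associated with)",
  "Protein-Protein (low positive co-expression PPI)",
  "Disease-Phenotype (phenotype present)",
  "Protein-Protein (no co-expression PPI)",
  "Bioprocess-Gene (interacts with)",
  "Protein-Protein (medium positive co-expression PPI)",
  "Bioprocess-Bioprocess (parent-child)",
  "Disease-Gene (associated with)",
  "Protein-Protein (negative co-expression PPI)",
  "Cellular component-Gene (interacts with)",
  "Disease-Disease (parent-child)",
  "Molecular function-Gene (interacts with)",
  "Drug-Effect/Phenotype (side effect)",
  "Protein-Protein (unlabeled PPI)",
  "Pathway-Gene (interacts with)",
  "Protein-Protein (high positive co-expression PPI)",
  "Phenotype-Phenotype (parent-child)",
  "Contraindication (contraindication)",
  "Anatomy-Anatomy (parent-child)",
  "Protein-Gene (associated with)",
  "Molecular function-Molecular function (parent-child)",
  "Anatomy-Gene (expression absent)",
  "Drug-Protein (target)",
  "Indication (indication)",
  "Cellular component-Cellular component (parent-child)",
  "Drug-Protein (enzyme)",
  "Pathway-Pathway (parent-child)",
  "Exposure-Exposure (parent-child)",
  "Phenotype-Gene (associated with)",
  "Drug-Protein (transporter)",
  "Off-label use (off-label use)",
  "Exposure-Disease (linked to)",
  "Exposure-Bioprocess (interacts with)",
  "Disease-Phenotype (phenotype absent)",
  "Exposure-Gene (interacts with)",
  "Drug-Protein (carrier)",
  "Exposure-Molecular function (interacts with)",
  "Exposure-Cellular component (interacts with)"
)

.token_to_node_type <- c(
  "Gene" = "gene", "Protein" = "protein", "Variant" = "variant",
  "Disease" = "disease", "Phenotype" = "phenotype",
  "Effect/Phenotype" = "phenotype", "Drug" = "drug", "Pathway" = "pathway",
  "Molecular function" = "molecular_function",
  "Bioprocess" = "biological_process",
  "Cellular component" = "cellular_component",
  "Exposure" = "exposure", "Anatomy" = "anatomy"
)

# endpoint node types per edge type, parsed from the "X-Y (...)" name; the
# three drug-condition relation names carry no endpoint tokens and are fixed
.edge_type_endpoint_table <- local({
  special <- list(
    "Contraindication (contraindication)"  = c("drug", "disease"),
    "Indication (indication)"              = c("drug", "disease"),
    "Off-label use (off-label use)"        = c("drug", "disease")
  )
  out <- lapply(.edge_types, function(et) {
    if (!is.null(special[[et]])) return(special[[et]])
    head_part <- sub(" \\(.*$", "", et)
    toks <- strsplit(head_part, "-", fixed = TRUE)[[1]]
    unname(.token_to_node_type[toks])
  })
  names(out) <- .edge_types
  out
})

#' Controlled vocabularies of the knowledge graph
#'
#' The closed set of 12 node types and the edge-type vocabulary (the PrimeKG
#' style relation set plus the two variant-integration relations
#' `"Variant-Gene (associated with)"` and `"Disease-Variant (associated with)"`
#' and the `"Protein-Gene (associated with)"` link created by protein-node
#' splitting).
#'
#' @return Character vector of type names.
#' @export
edge_type_vocabulary <- function() .edge_types

#' @rdname edge_type_vocabulary
#' @export
node_type_vocabulary <- function() .node_types

#' Endpoint node types of an edge type
#'
#' @param edge_type An edge-type string from [edge_type_vocabulary()].
#' @return Length-2 character vector of node types (unordered semantics).
#' @export
edge_type_endpoints <- function(edge_type) {
  ep <- .edge_type_endpoint_table[[edge_type]]
  if (is.null(ep)) {
    stop("unknown edge type: '", edge_type, "' (not in the controlled vocabulary)",
         call. = FALSE)
  }
  ep
}

.check_edge_types <- function(types) {
  bad <- setdiff(unique(types), .edge_types)
  if (length(bad)) {
    stop("unknown edge type: '", bad[[1L]],
         "' (not in the controlled vocabulary)", call. = FALSE)
  }
  invisible(TRUE)
}

.empty_nodes <- function() {
  data.frame(node_id = character(), node_type = character(),
             name = character(), stringsAsFactors = FALSE)
}
.empty_edges <- function() {
  data.frame(src = character(), dst = character(),
             edge_type = character(), stringsAsFactors = FALSE)
}

#' Construct a heterogeneous knowledge graph
#'
#' Builds a typed undirected multigraph. Node ids must be unique, node and
#' edge types must come from the controlled vocabularies, edge endpoints must
#' exist and be type-compatible with the edge type. Duplicate edges of the
#' same type between the same (unordered) pair are collapsed.
#'
#' @param nodes data.frame with columns `node_id`, `node_type`, `name`.
#' @param edges data.frame with columns `src`, `dst`, `edge_type`.
#' @param masked_types character vector of edge types excluded from adjacency
#'   views (the store itself keeps them).
#' @return An object of class `hetero_graph`.
#' @export
hetero_graph <- function(nodes = NULL, edges = NULL, masked_types = character()) {
  nodes <- if (is.null(nodes)) .empty_nodes() else
    as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- if (is.null(edges)) .empty_edges() else
    as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "node_type", "name") %in% names(nodes)),
            all(c("src", "dst", "edge_type") %in% names(edges)))
  nodes <- nodes[, c("node_id", "node_type", "name")]
  edges <- edges[, c("src", "dst", "edge_type")]
  for (j in seq_along(nodes)) nodes[[j]] <- as.character(nodes[[j]])
  for (j in seq_along(edges)) edges[[j]] <- as.character(edges[[j]])

  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id: '", nodes$node_id[duplicated(nodes$node_id)][1L],
         "'", call. = FALSE)
  }
  bad_nt <- setdiff(unique(nodes$node_type), .node_types)
  if (length(bad_nt)) {
    stop("unknown node type: '", bad_nt[[1L]], "'", call. = FALSE)
  }
  .check_edge_types(edges$edge_type)
  .check_edge_types(masked_types)

  missing_ep <- setdiff(unique(c(edges$src, edges$dst)), nodes$node_id)
  if (length(missing_ep)) {
    stop("edge endpoint not in node set: '", missing_ep[[1L]], "'", call. = FALSE)
  }
  if (nrow(edges)) {
    ntype <- stats::setNames(nodes$node_type, nodes$node_id)
    # a protein node satisfies a "gene" endpoint: in a pre-split PrimeKG-style
    # graph the protein node stands for its gene until split_protein_nodes()
    compatible <- function(have, want) {
      have == want | (want == "gene" & have == "protein")
    }
    for (i in seq_len(nrow(edges))) {
      ep <- .edge_type_endpoint_table[[edges$edge_type[i]]]
      got <- c(ntype[[edges$src[i]]], ntype[[edges$dst[i]]])
      ok <- (compatible(got[1L], ep[1L]) && compatible(got[2L], ep[2L])) ||
        (compatible(got[1L], ep[2L]) && compatible(got[2L], ep[1L]))
      if (!ok) {
        stop("edge type '", edges$edge_type[i], "' is incompatible with ",
             "endpoint types (", got[1L], ", ", got[2L], ")", call. = FALSE)
      }
    }
    # collapse same-type duplicates on the unordered pair
    a <- pmin(edges$src, edges$dst)
    b <- pmax(edges$src, edges$dst)
    key <- paste(a, b, edges$edge_type, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 masked_types = unique(as.character(masked_types))),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("Heterogeneous knowledge graph\n")
  cat("  nodes:", nrow(x$nodes), "(",
      paste(names(sort(table(x$nodes$node_type), decreasing = TRUE)),
            collapse = ", "), ")\n")
  cat("  edges:", nrow(x$edges), "in", length(unique(x$edges$edge_type)),
      "types\n")
  if (length(x$masked_types)) {
    cat("  masked types:", paste(x$masked_types, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Mask or unmask edge types in a graph's adjacency views
#'
#' Masking hides every edge of the given type(s) from [active_edges()] and
#' [adjacency_matrix()] without touching the underlying edge store, so that
#' masking then unmasking restores the original views exactly.
#'
#' @param graph A `hetero_graph`.
#' @param edge_types Character vector of edge types to mask.
#' @return The graph with updated `masked_types`.
#' @export
mask_edges <- function(graph, edge_types) {
  stopifnot(inherits(graph, "hetero_graph"))
  .check_edge_types(edge_types)
  graph$masked_types <- union(graph$masked_types, edge_types)
  graph
}

#' @rdname mask_edges
#' @param all If `TRUE` remove every mask, otherwise only `edge_types`.
#' @export
unmask_edges <- function(graph, edge_types = NULL, all = is.null(edge_types)) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (all) graph$masked_types <- character() else {
    .check_edge_types(edge_types)
    graph$masked_types <- setdiff(graph$masked_types, edge_types)
  }
  graph
}

#' Edges visible under the current mask
#'
#' @param graph A `hetero_graph`.
#' @return data.frame of edges whose type is not masked.
#' @export
active_edges <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  graph$edges[!(graph$edges$edge_type %in% graph$masked_types), , drop = FALSE]
}

#' Per-type edge counts
#'
#' @param graph A `hetero_graph`.
#' @param masked Count all stored edges (`FALSE`, default) or only the
#'   unmasked view (`TRUE`).
#' @return Named integer vector.
#' @export
edge_counts <- function(graph, masked = FALSE) {
  e <- if (masked) active_edges(graph) else graph$edges
  if (!nrow(e)) return(stats::setNames(integer(), character()))
  tab <- table(e$edge_type)
  stats::setNames(as.integer(tab), names(tab))
}

#' Canonical node ordering
#'
#' All matrix views (features, adjacency, encoder output) index nodes in this
#' order: node ids sorted by `node_id` with the C collation, so the ordering is
#' independent of insertion order and locale.
#'
#' @param graph A `hetero_graph`.
#' @return Character vector of node ids.
#' @export
node_order <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  sort(graph$nodes$node_id, method = "radix")
}

#' Symmetric binary adjacency of the unmasked view
#'
#' Parallel edges of different types between a pair contribute a single 1 (the
#' encoder treats all unmasked relations homogeneously); masked types are
#' excluded entirely. Rows/columns follow [node_order()].
#'
#' @param graph A `hetero_graph`.
#' @return A sparse symmetric `Matrix::sparseMatrix` with 0/1 entries and no
#'   diagonal.
#' @export
adjacency_matrix <- function(graph) {
  ids <- node_order(graph)
  n <- length(ids)
  e <- active_edges(graph)
  if (!nrow(e)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), dimnames = list(ids, ids)))
  }
  idx <- stats::setNames(seq_len(n), ids)
  i <- idx[e$src]; j <- idx[e$dst]
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), dimnames = list(ids, ids),
                            use.last.ij = TRUE)
  A@x[] <- 1
  A
}

## ---------------------------------------------------------------------------
## Graph augmentation rules
## ---------------------------------------------------------------------------

#' Split protein nodes into gene/protein pairs
#'
#' In a PrimeKG-style graph a single protein node stands for both the gene and
#' its product. This rewrites each protein node into a (gene, protein) pair
#' joined by a `"Protein-Gene (associated with)"` edge and reroutes incident
#' edges by the tokens in their type name: types naming `Protein` (all PPI
#' subtypes, Drug-Protein) stay on the protein node, types naming `Gene`
#' (Anatomy-Gene, Pathway-Gene, Disease-Gene, ...) move to the new gene node.
#' The new gene node keeps the protein's display name (the gene symbol) and
#' gets id `paste0(node_id, ":gene")`.
#'
#' @param graph A `hetero_graph` containing protein-typed nodes.
#' @return The augmented `hetero_graph`.
#' @export
split_protein_nodes <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  prot <- graph$nodes[graph$nodes$node_type == "protein", , drop = FALSE]
  if (!nrow(prot)) return(graph)
  gene_ids <- paste0(prot$node_id, ":gene")
  clash <- intersect(gene_ids, graph$nodes$node_id)
  if (length(clash)) {
    stop("cannot split protein nodes: derived gene id already present: '",
         clash[[1L]], "'", call. = FALSE)
  }
  gene_of <- stats::setNames(gene_ids, prot$node_id)

  edges <- graph$edges
  if (nrow(edges)) {
    .check_edge_types(edges$edge_type)
    names_gene <- grepl("Gene", edges$edge_type, fixed = TRUE)
    names_prot <- grepl("Protein", edges$edge_type, fixed = TRUE)
    # "Protein" wins for PPI/Drug-Protein/Protein-Gene; pure Gene types move
    move <- names_gene & !names_prot
    src_is_prot <- edges$src %in% prot$node_id
    dst_is_prot <- edges$dst %in% prot$node_id
    edges$src[move & src_is_prot] <- gene_of[edges$src[move & src_is_prot]]
    edges$dst[move & dst_is_prot] <- gene_of[edges$dst[move & dst_is_prot]]
  }
  new_nodes <- data.frame(node_id = gene_ids, node_type = "gene",
                          name = prot$name, stringsAsFactors = FALSE)
  link <- data.frame(src = prot$node_id, dst = gene_ids,
                     edge_type = "Protein-Gene (associated with)",
                     stringsAsFactors = FALSE)
  hetero_graph(rbind(graph$nodes, new_nodes), rbind(edges, link),
               graph$masked_types)
}

.norm_disease_key <- function(x) tolower(trimws(x))

.split_diseases <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  parts[nzchar(parts)]
}

#' Stable variant node id
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @return `"var:<chrom>:<pos>:<ref>:<alt>"`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste("var", chrom, pos, ref, alt, sep = ":")
}

#' Attach variants to the knowledge graph
#'
#' Adds one variant node per record plus a `Variant-Gene` edge to its gene
#' (matched by gene symbol against gene-node names). Each pathogenic variant
#' is additionally connected to every disease it is associated with through a
#' `Disease-Variant` edge; disease names are matched case-insensitively after
#' whitespace trimming and a new disease node is created when no match exists.
#' Benign (and other-labelled) variants get no disease edge. Re-running with
#' the same variant table is a no-op (idempotent).
#'
#' @param graph A `hetero_graph` containing gene nodes.
#' @param variants A variant table (see [read_variant_table()]): columns
#'   `chrom`, `pos`, `ref`, `alt`, `var_class`, `gene`, `clinical_label`,
#'   `diseases` (semicolon-separated names, possibly empty).
#' @return The augmented `hetero_graph`.
#' @export
attach_variants <- function(graph, variants) {
  stopifnot(inherits(graph, "hetero_graph"))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!nrow(variants)) return(graph)
  need <- c("chrom", "pos", "ref", "alt", "var_class", "gene",
            "clinical_label", "diseases")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table misses column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  genes <- graph$nodes[graph$nodes$node_type == "gene", , drop = FALSE]
  gene_id_of <- stats::setNames(genes$node_id, genes$name)
  absent <- setdiff(unique(variants$gene), names(gene_id_of))
  if (length(absent)) {
    stop("variant references gene absent from graph: '", absent[[1L]], "'",
         call. = FALSE)
  }

  dis <- graph$nodes[graph$nodes$node_type == "disease", , drop = FALSE]
  dis_id_of <- stats::setNames(dis$node_id, .norm_disease_key(dis$name))

  vid <- variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  new_var <- !(vid %in% graph$nodes$node_id)
  var_nodes <- if (any(new_var)) {
    data.frame(node_id = vid[new_var], node_type = "variant",
               name = vid[new_var], stringsAsFactors = FALSE)
  } else .empty_nodes()
  vg_edges <- data.frame(src = vid, dst = unname(gene_id_of[variants$gene]),
                         edge_type = "Variant-Gene (associated with)",
                         stringsAsFactors = FALSE)

  dis_nodes <- .empty_nodes()
  dv_edges <- .empty_edges()
  for (i in seq_len(nrow(variants))) {
    if (!identical(variants$clinical_label[i], "pathogenic")) next
    for (dn in .split_diseases(variants$diseases[i])) {
      key <- .norm_disease_key(dn)
      if (is.na(dis_id_of[key])) {
        new_id <- paste0("disease:", gsub("[^a-z0-9]+", "_", key))
        dis_id_of[key] <- new_id
        dis_nodes <- rbind(dis_nodes, data.frame(
          node_id = new_id, node_type = "disease", name = dn,
          stringsAsFactors = FALSE))
      }
      dv_edges <- rbind(dv_edges, data.frame(
        src = dis_id_of[[key]], dst = vid[i],
        edge_type = "Disease-Variant (associated with)",
        stringsAsFactors = FALSE))
    }
  }
  hetero_graph(rbind(graph$nodes, var_nodes, dis_nodes),
               rbind(graph$edges, vg_edges, dv_edges),
               graph$masked_types)
}

## ---------------------------------------------------------------------------
## PPI temporal typing and co-expression binning
## ---------------------------------------------------------------------------

.check_corr_range <- function(r) {
  if (length(r) && (any(!is.finite(r)) || any(r < -1) || any(r > 1))) {
    stop("correlation value outside [-1, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Transient/permanent classification of a protein-protein interaction
#'
#' Each experiment votes transient when the time-course co-expression of the
#' two coding genes is below `threshold` (default 0.1), otherwise permanent.
#' The edge label is the strict majority over experiments; an exact tie is
#' resolved to permanent; no experiments means unlabeled.
#'
#' @param timecourse Numeric vector of per-experiment correlations in
#'   \[-1, 1\] (possibly empty).
#' @param threshold Per-experiment transient threshold.
#' @return `"transient"`, `"permanent"` or `"unlabeled"`.
#' @export
classify_ppi_temporal <- function(timecourse, threshold = 0.1) {
  timecourse <- as.numeric(timecourse)
  .check_corr_range(timecourse)
  if (!length(timecourse)) return("unlabeled")
  n_trans <- sum(timecourse < threshold)
  if (n_trans > length(timecourse) / 2) "transient" else "permanent"
}

#' Tissue co-expression level binning
#'
#' Maps a cross-tissue co-expression value onto the five co-expression edge
#' labels. Thresholds are configuration values; the defaults place
#' `r <= -0.1` in `negative`, `(-0.1, 0.1)` in `none`, `[0.1, 0.4)` in
#' `low_positive`, `[0.4, 0.7)` in `medium_positive` and `r >= 0.7` in
#' `high_positive`.
#'
#' @param r Correlation in \[-1, 1\] (vectorised).
#' @param thresholds Numeric vector `c(negative, none, low, medium)` of upper
#'   bin edges.
#' @return Character vector of bin labels.
#' @export
bin_tissue_coexpression <- function(r, thresholds = c(-0.1, 0.1, 0.4, 0.7)) {
  r <- as.numeric(r)
  .check_corr_range(r)
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds))
  labs <- c("negative", "none", "low_positive", "medium_positive",
            "high_positive")
  out <- character(length(r))
  out[r <= thresholds[1L]] <- labs[1L]
  out[r >  thresholds[1L] & r < thresholds[2L]] <- labs[2L]
  out[r >= thresholds[2L] & r < thresholds[3L]] <- labs[3L]
  out[r >= thresholds[3L] & r < thresholds[4L]] <- labs[4L]
  out[r >= thresholds[4L]] <- labs[5L]
  out
}

.coexpression_edge_type <- c(
  negative        = "Protein-Protein (negative co-expression PPI)",
  none            = "Protein-Protein (no co-expression PPI)",
  low_positive    = "Protein-Protein (low positive co-expression PPI)",
  medium_positive = "Protein-Protein (medium positive co-expression PPI)",
  high_positive   = "Protein-Protein (high positive co-expression PPI)"
)
.temporal_edge_type <- c(
  transient = "Protein-Protein (transient PPI)",
  permanent = "Protein-Protein (permanent PPI)",
  unlabeled = "Protein-Protein (unlabeled PPI)"
)

#' Typed PPI edges from co-expression profiles
#'
#' Turns a set of interacting protein pairs plus their co-expression profiles
#' into typed edge records: one temporal edge (transient / permanent /
#' unlabeled) per pair and, when a cross-tissue correlation is present, a
#' second parallel edge carrying the co-expression bin.
#'
#' @param pairs data.frame with columns `protein_a`, `protein_b` (node ids).
#' @param profiles Named list keyed `"<a>|<b>"` of lists with elements
#'   `timecourse` (numeric vector) and `tissue_r` (scalar or `NULL`), as
#'   produced by [simulate_coexpression()].
#' @param thresholds Passed to [bin_tissue_coexpression()].
#' @return data.frame of edge records (`src`, `dst`, `edge_type`).
#' @export
ppi_edge_records <- function(pairs, profiles, thresholds = c(-0.1, 0.1, 0.4, 0.7)) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- .empty_edges()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$protein_a[i]; b <- pairs$protein_b[i]
    prof <- profiles[[paste(a, b, sep = "|")]]
    tc <- if (is.null(prof)) numeric() else prof$timecourse
    lab <- classify_ppi_temporal(tc)
    out <- rbind(out, data.frame(src = a, dst = b,
                                 edge_type = .temporal_edge_type[[lab]],
                                 stringsAsFactors = FALSE))
    if (!is.null(prof) && !is.null(prof$tissue_r) && !is.na(prof$tissue_r)) {
      bin <- bin_tissue_coexpression(prof$tissue_r, thresholds)
      out <- rbind(out, data.frame(src = a, dst = b,
                                   edge_type = .coexpression_edge_type[[bin]],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Edge-list / node-table I/O (UTF-8, tab-delimited, header row required)
## ---------------------------------------------------------------------------

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("malformed table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read / write a typed edge list
#'
#' The on-disk format is a UTF-8 TSV with header
#' `src_id  src_type  dst_id  dst_type  edge_type`; nodes are the union of
#' endpoints (ids must agree in type across rows). A write-then-read
#' round-trip reproduces node set, edge multiset and types exactly, up to the
#' display names which an edge list alone does not carry (pair with
#' [read_node_table()] to preserve names).
#'
#' @param path File path.
#' @return For `read_edge_list`, a `hetero_graph` (names default to ids).
#' @export
read_edge_list <- function(path) {
  df <- .read_tsv(path, c("src_id", "src_type", "dst_id", "dst_type",
                          "edge_type"))
  bad_row <- which(apply(df[, c("src_id", "dst_id", "edge_type")], 1L,
                         function(r) any(!nzchar(r))))
  if (length(bad_row)) {
    stop("malformed row at line ", bad_row[[1L]] + 1L, " in '", path, "'",
         call. = FALSE)
  }
  bad_type <- which(!(df$src_type %in% .node_types) |
                    !(df$dst_type %in% .node_types))
  if (length(bad_type)) {
    stop("unknown node_type token at line ", bad_type[[1L]] + 1L, " in '",
         path, "'", call. = FALSE)
  }
  ids <- c(df$src_id, df$dst_id)
  types <- c(df$src_type, df$dst_type)
  first <- !duplicated(ids)
  conflict <- tapply(types, ids, function(t) length(unique(t)) > 1L)
  if (any(conflict)) {
    stop("node '", names(conflict)[conflict][1L],
         "' appears with conflicting types in '", path, "'", call. = FALSE)
  }
  nodes <- data.frame(node_id = ids[first], node_type = types[first],
                      name = ids[first], stringsAsFactors = FALSE)
  edges <- data.frame(src = df$src_id, dst = df$dst_id,
                      edge_type = df$edge_type, stringsAsFactors = FALSE)
  hetero_graph(nodes, edges)
}

#' @rdname read_edge_list
#' @param graph A `hetero_graph`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "hetero_graph"))
  ntype <- stats::setNames(graph$nodes$node_type, graph$nodes$node_id)
  df <- data.frame(src_id = graph$edges$src,
                   src_type = unname(ntype[graph$edges$src]),
                   dst_id = graph$edges$dst,
                   dst_type = unname(ntype[graph$edges$dst]),
                   edge_type = graph$edges$edge_type,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read / write a node table (`node_id`, `node_type`, `name`)
#'
#' @param path File path.
#' @return For `read_node_table`, a data.frame of nodes.
#' @export
read_node_table <- function(path) {
  df <- .read_tsv(path, c("node_id", "node_type", "name"))
  bad <- which(!(df$node_type %in% .node_types))
  if (length(bad)) {
    stop("unknown node_type token at line ", bad[[1L]] + 1L, " in '", path,
         "'", call. = FALSE)
  }
  df
}

#' @rdname read_node_table
#' @param nodes data.frame of nodes.
#' @export
write_node_table <- function(nodes, path) {
  .write_tsv(nodes[, c("node_id", "node_type", "name")], path)
  invisible(path)
}

#' Read co-expression tables
#'
#' `read_timecourse_coexpression` expects columns
#' `gene_a  gene_b  experiment_id  r`; `read_tissue_coexpression` expects
#' `gene_a  gene_b  tissue_r`. Correlations are validated to lie in \[-1, 1\].
#'
#' @param path File path.
#' @return data.frame with `r`/`tissue_r` numeric.
#' @export
read_timecourse_coexpression <- function(path) {
  df <- .read_tsv(path, c("gene_a", "gene_b", "experiment_id", "r"))
  df$r <- as.numeric(df$r)
  .check_corr_range(df$r)
  df
}

#' @rdname read_timecourse_coexpression
#' @export
read_tissue_coexpression <- function(path) {
  df <- .read_tsv(path, c("gene_a", "gene_b", "tissue_r"))
  df$tissue_r <- as.numeric(df$tissue_r)
  .check_corr_range(df$tissue_r)
  df
}
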