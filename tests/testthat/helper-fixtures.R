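# Shared fixtures and independent oracles, all built in code.

# deterministic toy chromosome
toy_chrom <- function(len = 200L, seed = 42L) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
}

# a small pre-split graph: proteins carrying mixed Gene-/Protein-named edges
protein_graph <- function() {
  nodes <- data.frame(
    node_id = c("P1", "P2", "pw1", "d1"),
    node_type = c("protein", "protein", "pathway", "disease"),
    name = c("GENEA", "GENEB", "pathway one", "disease one"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    src = c("P1", "pw1", "d1"),
    dst = c("P2", "P1", "P2"),
    edge_type = c("Protein-Protein (permanent PPI)",
                  "Pathway-Gene (interacts with)",
                  "Disease-Gene (associated with)"),
    stringsAsFactors = FALSE)
  hetero_graph(nodes, edges)
}

# post-split graph with genes/diseases ready for variant attachment
gene_graph <- function() {
  nodes <- data.frame(
    node_id = c("g1", "g2", "d1", "d2"),
    node_type = c("gene", "gene", "disease", "disease"),
    name = c("GENEA", "GENEB", "disease one", "disease two"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    src = c("d1", "d2", "d2"),
    dst = c("g1", "g1", "g2"),
    edge_type = "Disease-Gene (associated with)",
    stringsAsFactors = FALSE)
  hetero_graph(nodes, edges)
}

make_variant_row <- function(chrom = "1", pos = 10L, ref = "A", alt = "T",
                             var_class = "snv", gene = "GENEA",
                             clinical_label = "benign",
                             review_status = "practice guideline",
                             origin = "germline", assembly = "GRCh38",
                             submission_date = "2021-06-01", diseases = "") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             var_class = var_class, gene = gene,
             clinical_label = clinical_label, review_status = review_status,
             origin = origin, assembly = assembly,
             submission_date = submission_date, diseases = diseases,
             stringsAsFactors = FALSE)
}

## ---- independent windowing/extraction oracles (character-vector based) ----

# enumerate every feasible placement and take the one closest to the ideal
# centred placement
oracle_window <- function(center, W, len) {
  starts <- seq_len(len - W + 1L)
  ideal <- center - W %/% 2L
  s <- starts[which.min(abs(starts - ideal))]
  c(s, s + W - 1L)
}

oracle_snv <- function(chrom, pos, alt, W) {
  v <- strsplit(chrom, "")[[1L]]
  w <- oracle_window(pos, W, length(v))
  out <- v[w[1L]:w[2L]]
  out[pos - w[1L] + 1L] <- alt
  paste(out, collapse = "")
}

oracle_insertion <- function(chrom, pos, payload, W) {
  v <- strsplit(chrom, "")[[1L]]
  p <- strsplit(payload, "")[[1L]]
  w <- oracle_window(pos, W, length(v))
  win <- v[w[1L]:w[2L]]
  mid <- W %/% 2L
  full <- c(win[seq_len(mid)], p, win[setdiff(seq_len(W), seq_len(mid))])
  drop_left <- length(p) %/% 2L
  paste(full[(drop_left + 1L):(drop_left + W)], collapse = "")
}

oracle_deletion <- function(chrom, pos, ref, W) {
  v <- strsplit(chrom, "")[[1L]]
  L <- nchar(ref)
  s <- pos; e <- pos + L - 1L
  w <- oracle_window((s + e) %/% 2L, W + L, length(v))
  keep <- setdiff(w[1L]:w[2L], s:e)
  paste(v[keep], collapse = "")
}

oracle_indel <- function(chrom, pos, ref, alt, W) {
  if (!nzchar(alt)) return(oracle_deletion(chrom, pos, ref, W))
  v <- strsplit(chrom, "")[[1L]]
  a <- strsplit(alt, "")[[1L]]
  L <- nchar(ref)
  s <- pos; e <- pos + L - 1L
  w <- oracle_window((s + e) %/% 2L, W + L, length(v))
  left <- v[setdiff(w[1L]:w[2L], s:length(v))]
  right <- v[setdiff(w[1L]:w[2L], 1:e)]
  full <- c(left, a, right)
  # keep the W-slice that puts the leading alt base at 0-based floor(W/2),
  # clamped to the available sequence
  drop_left <- length(left) + length(a) %/% 2L - W %/% 2L
  drop_left <- max(0L, min(length(full) - W, drop_left))
  paste(full[(drop_left + 1L):(drop_left + W)], collapse = "")
}

# small relational fixture shared by model-level tests (kept light)
small_dataset <- function(seed = 7L, alpha = 0.9) {
  cfg <- synth_config(n_genes = 8L, variants_per_gene = 10L,
                      embed_dim = 16L, n_pathways = 2L, alpha = alpha,
                      seed = seed)
  simulate_dataset(cfg)
}
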