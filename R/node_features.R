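## ---------------------------------------------------------------------------
## Initial node feature vectors
##
## Every node receives a fixed-width numeric embedding before the encoder
## runs: variants and proteins from text templates, drugs/diseases from
## multi-feature descriptions averaged per node, everything else from its
## display name.  Providers are pluggable; the package ships a deterministic
## feature-hashing embedder so the pipeline never needs pretrained models.
## ---------------------------------------------------------------------------

#' Textual description of a variant node
#'
#' @param var_class,chrom,pos,ref,alt Variant fields (all required).
#' @return The template string
#'   `"<variant type> located on chromosome <chromosome number> at position
#'   <variant position> with reference allele <reference allele> and
#'   alternative allele <alternative allele>"`.
#' @export
build_variant_text <- function(var_class, chrom, pos, ref, alt) {
  args <- list(var_class = var_class, chrom = chrom, pos = pos,
               ref = ref, alt = alt)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || length(args[[nm]]) != 1L || is.na(args[[nm]])) {
      stop("variant text template: missing field '", nm, "'", call. = FALSE)
    }
  }
  paste0(var_class, " located on chromosome ", chrom, " at position ", pos,
         " with reference allele ", ref, " and alternative allele ", alt)
}

#' Textual description of a protein node
#'
#' @param gene_symbol Gene symbol (nonempty; surrounding whitespace trimmed).
#' @return `"Protein encoded by gene <gene symbol>"`.
#' @export
build_protein_text <- function(gene_symbol) {
  gene_symbol <- trimws(gene_symbol)
  if (length(gene_symbol) != 1L || is.na(gene_symbol) || !nzchar(gene_symbol)) {
    stop("protein text template: empty gene symbol", call. = FALSE)
  }
  paste0("Protein encoded by gene ", gene_symbol)
}

#' Text source(s) for one node
#'
#' Drug and disease nodes with entries in the description table return their
#' full feature list (embedded separately and averaged); disease/drug nodes
#' without descriptions, and every other plain node type, return the display
#' name. Protein nodes use [build_protein_text()]; variant nodes use their
#' variant-template text when available in `variant_texts`, else the name.
#'
#' @param node One node row (list with `node_id`, `node_type`, `name`).
#' @param descriptions Optional data.frame `node_id`, `feature_index`, `text`.
#' @param variant_texts Optional named character vector keyed by variant
#'   node id.
#' @return Character vector (length > 1 only for multi-feature nodes).
#' @export
node_text <- function(node, descriptions = NULL, variant_texts = NULL) {
  node <- as.list(node)
  if (node$node_type %in% c("drug", "disease") && !is.null(descriptions)) {
    rows <- descriptions[descriptions$node_id == node$node_id, , drop = FALSE]
    if (nrow(rows)) {
      return(rows$text[order(as.integer(rows$feature_index))])
    }
  }
  if (node$node_type == "protein") return(build_protein_text(node$name))
  if (node$node_type == "variant" && !is.null(variant_texts) &&
      !is.na(variant_texts[node$node_id])) {
    return(unname(variant_texts[[node$node_id]]))
  }
  node$name
}

#' Element-wise mean of feature embeddings
#'
#' @param vectors List of equal-width numeric vectors (nonempty).
#' @return Numeric vector, the arithmetic mean.
#' @export
average_feature_embeddings <- function(vectors) {
  if (!length(vectors)) stop("no vectors to average", call. = FALSE)
  widths <- lengths(vectors)
  if (length(unique(widths)) != 1L) {
    stop("width mismatch in feature embeddings: ",
         paste(unique(widths), collapse = " vs "), call. = FALSE)
  }
  Reduce(`+`, vectors) / length(vectors)
}

#' L2-normalise embedding rows
#'
#' Scales every nonzero row of an embedding matrix to unit Euclidean norm;
#' all-zero rows are returned unchanged (division-by-zero guard). Idempotent.
#'
#' @param x Numeric matrix (rows = nodes) or a single vector.
#' @return Object of the same shape.
#' @export
l2_normalize <- function(x) {
  if (is.null(dim(x))) {
    if (any(!is.finite(x))) stop("non-finite embedding entries", call. = FALSE)
    nrm <- sqrt(sum(x^2))
    return(if (nrm > 0) x / nrm else x)
  }
  if (any(!is.finite(x))) stop("non-finite embedding entries", call. = FALSE)
  nrm <- sqrt(rowSums(x^2))
  scale_by <- ifelse(nrm > 0, 1 / nrm, 1)
  x * scale_by
}

## -- deterministic feature-hashing embedder ---------------------------------

# multiplicative byte hash kept below 2^26 so all arithmetic stays exact in
# doubles (no platform-dependent overflow)
.token_hash <- function(bytes, seed) {
  h <- (1469598103 + seed * 40503) %% 67108864
  for (b in bytes) {
    h <- (h * 131 + b) %% 67108864
  }
  h
}

.tokenize_text <- function(x) {
  toks <- strsplit(tolower(trimws(x)), "[^a-z0-9/<>.-]+")[[1L]]
  toks[nzchar(toks)]
}

.tokenize_dna <- function(x, k = 6L) {
  n <- nchar(x)
  if (n < k) return(if (n > 0) x else character())
  substring(x, 1:(n - k + 1L), k:n)
}

#' Deterministic feature-hashing embedder
#'
#' A pretrained-model stand-in satisfying the provider contract: tokenises
#' the input (lower-cased words for text, overlapping 6-mers for DNA), hashes
#' each token with the seed into one of `dim` buckets with a +/-1 sign,
#' accumulates, and scales by `1/sqrt(token count)` (so k repeats of one
#' token embed to `sqrt(k)` times the single-token vector). Identical
#' `(input, dim, seed)` always yields the identical vector.
#'
#' @param input Text or DNA sequence (single string).
#' @param dim Output width (>= 1).
#' @param seed Integer hashing seed.
#' @param mode `"text"` or `"dna"`.
#' @return Numeric vector of length `dim`.
#' @export
hash_embedder <- function(input, dim = 64L, seed = 0L, mode = c("text", "dna")) {
  mode <- match.arg(mode)
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  toks <- if (mode == "dna") .tokenize_dna(input) else .tokenize_text(input)
  v <- numeric(dim)
  if (!length(toks)) {
    warning("empty input to hash_embedder; returning zero vector")
    return(v)
  }
  for (t in toks) {
    h <- .token_hash(utf8ToInt(t), seed)
    bucket <- (h %% dim) + 1L
    sign <- if ((h %/% dim) %% 2 == 0) 1 else -1
    v[bucket] <- v[bucket] + sign
  }
  v / sqrt(length(toks))
}

#' Construct a hashing provider
#'
#' Wraps [hash_embedder()] into a provider closure with fixed width, seed and
#' tokenisation mode, suitable for [assemble_initial_features()].
#'
#' @param dim Output width.
#' @param seed Hashing seed.
#' @param mode `"text"` or `"dna"`.
#' @return Function `f(input) -> numeric(dim)` with attribute `width`.
#' @export
hash_provider <- function(dim = 64L, seed = 0L, mode = c("text", "dna")) {
  mode <- match.arg(mode)
  dim <- as.integer(dim)
  f <- function(input) hash_embedder(input, dim = dim, seed = seed, mode = mode)
  attr(f, "width") <- dim
  f
}

#' Assemble the initial feature matrix for a graph
#'
#' Produces one embedding row per node in [node_order()]: each node's text
#' source(s) from [node_text()] go through the provider mapped to its node
#' type, multi-feature nodes are averaged, every row is L2-normalised, and
#' per-type widths are reconciled by zero-padding on the right to the common
#' maximum width so the encoder consumes a single matrix.
#'
#' Precomputed embeddings (e.g. from [plant_signal()] or an external model)
#' may be supplied per type as an id-indexed matrix instead of a provider
#' function.
#'
#' @param graph A `hetero_graph`.
#' @param providers Named list mapping every node type present in the graph
#'   to either a provider function (see [hash_provider()]) or a numeric
#'   matrix with rownames = node ids.
#' @param descriptions Optional description table for drug/disease nodes.
#' @param variant_texts Optional named character vector of variant texts (or
#'   DNA context sequences when the variant provider is a DNA embedder).
#' @return Numeric matrix, rows named by node id in canonical order, with
#'   attribute `type_width` recording per-type pre-padding widths.
#' @export
assemble_initial_features <- function(graph, providers, descriptions = NULL,
                                      variant_texts = NULL) {
  stopifnot(inherits(graph, "hetero_graph"))
  types_present <- unique(graph$nodes$node_type)
  unmapped <- setdiff(types_present, names(providers))
  if (length(unmapped)) {
    stop("no provider mapped for node type '", unmapped[[1L]], "'",
         call. = FALSE)
  }
  ids <- node_order(graph)
  ntype <- stats::setNames(graph$nodes$node_type, graph$nodes$node_id)
  nname <- stats::setNames(graph$nodes$name, graph$nodes$node_id)

  per_type <- list()
  type_width <- integer()
  for (tp in types_present) {
    prov <- providers[[tp]]
    tids <- ids[ntype[ids] == tp]
    if (is.matrix(prov)) {
      miss <- setdiff(tids, rownames(prov))
      if (length(miss)) {
        stop("precomputed embeddings for type '", tp, "' miss node '",
             miss[[1L]], "'", call. = FALSE)
      }
      m <- prov[tids, , drop = FALSE]
    } else {
      rows <- lapply(tids, function(id) {
        txt <- node_text(list(node_id = id, node_type = tp,
                              name = nname[[id]]),
                         descriptions, variant_texts)
        average_feature_embeddings(lapply(txt, prov))
      })
      m <- do.call(rbind, rows)
      rownames(m) <- tids
    }
    m <- l2_normalize(m)
    per_type[[tp]] <- m
    type_width[[tp]] <- ncol(m)
  }

  width <- max(type_width)
  X <- matrix(0, nrow = length(ids), ncol = width, dimnames = list(ids, NULL))
  for (tp in names(per_type)) {
    m <- per_type[[tp]]
    X[rownames(m), seq_len(ncol(m))] <- m
  }
  if (any(!is.finite(X))) stop("non-finite assembled features", call. = FALSE)
  attr(X, "type_width") <- type_width
  X
}

#' Read / write an embedding matrix as TSV
#'
#' Serialised as a UTF-8 TSV with a `node_id` column followed by `dim`
#' numeric columns `e1..edim`.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix with rownames = node ids.
#' @export
read_embedding_tsv <- function(path) {
  df <- .read_tsv(path, "node_id")
  ids <- df$node_id
  m <- as.matrix(df[, setdiff(names(df), "node_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(!is.finite(m))) stop("non-finite entries in '", path, "'",
                               call. = FALSE)
  m
}

#' @rdname read_embedding_tsv
#' @param x Numeric matrix with rownames.
#' @export
write_embedding_tsv <- function(x, path) {
  df <- data.frame(node_id = rownames(x), x, stringsAsFactors = FALSE)
  names(df) <- c("node_id", paste0("e", seq_len(ncol(x))))
  .write_tsv(df, path)
  invisible(path)
}
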