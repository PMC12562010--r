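## ---------------------------------------------------------------------------
## Genomic context-window extraction
##
## All coordinates are 1-based inclusive (ClinVar/VCF convention).  Every
## extraction returns exactly W characters and is a pure function of its
## inputs.  The alternative allele is substituted into the reference window
## before the sequence is handed to an embedding provider.
## ---------------------------------------------------------------------------

.check_dna_alphabet <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a multi-record FASTA file into named character sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that upper-cases and
#' enforces the \{A,C,G,T,N\} alphabet; names are truncated at the first
#' whitespace as is conventional for chromosome headers.
#'
#' @param path FASTA file path (wrapped lines allowed).
#' @return Named character vector, one element per record.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  for (i in seq_along(seqs)) .check_dna_alphabet(seqs[[i]], names(seqs)[i])
  seqs
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Resolve a context window around a position
#'
#' Places a window of length `W` so that `center` sits at 0-based offset
#' `floor(W/2)`; when that placement overflows one chromosome end by `n`
#' positions, the window is shifted by exactly `n` toward the other side so
#' that it falls completely within chromosome limits.
#'
#' @param center 1-based position, `1 <= center <= chrom_len`.
#' @param W Window length, `1 <= W <= chrom_len`.
#' @param chrom_len Chromosome length.
#' @return Integer vector `c(start, end)`, 1-based inclusive,
#'   `end - start + 1 == W`.
#' @export
resolve_window <- function(center, W, chrom_len) {
  center <- as.integer(center); W <- as.integer(W)
  chrom_len <- as.integer(chrom_len)
  if (W < 1L) stop("window length must be >= 1", call. = FALSE)
  if (W > chrom_len) {
    stop("infeasible window: W = ", W, " exceeds chromosome length ",
         chrom_len, call. = FALSE)
  }
  if (center < 1L || center > chrom_len) {
    stop("center position ", center, " outside chromosome [1, ", chrom_len,
         "]", call. = FALSE)
  }
  start <- center - W %/% 2L
  if (start < 1L) start <- 1L
  if (start + W - 1L > chrom_len) start <- chrom_len - W + 1L
  c(start = start, end = start + W - 1L)
}

.check_ref <- function(chrom_seq, pos, ref, chrom_name = "") {
  got <- substr(chrom_seq, pos, pos + nchar(ref) - 1L)
  if (!identical(got, ref)) {
    stop("reference allele mismatch at position ", pos,
         if (nzchar(chrom_name)) paste0(" on ", chrom_name),
         ": expected '", ref, "', chromosome has '", got, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Context window for a single-nucleotide variant
#'
#' Resolves a window of length `W` around `pos` and substitutes the
#' alternative allele at the variant's offset within the window.
#'
#' @param chrom_seq Chromosome sequence (single string).
#' @param pos 1-based variant position.
#' @param ref,alt Single-base reference and alternative alleles.
#' @param W Window length.
#' @return String of length `W`.
#' @export
extract_snv <- function(chrom_seq, pos, ref, alt, W) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  .check_ref(chrom_seq, pos, ref)
  win <- resolve_window(pos, W, nchar(chrom_seq))
  s <- substr(chrom_seq, win[1L], win[2L])
  off <- pos - win[1L] + 1L
  substr(s, off, off) <- alt
  s
}

# keep floor(W/2) bases left of the alt block when the raw sequence allows,
# so the alt block's leading base lands where an SNV substitution would; any
# shortfall is balanced by the complementary right trim
.truncate_around_alt <- function(left_part, alt, right_part, W) {
  total <- nchar(left_part) + nchar(alt) + nchar(right_part)
  excess <- total - W
  stopifnot(excess >= 0L)
  trim_left <- nchar(left_part) + nchar(alt) %/% 2L - W %/% 2L
  trim_left <- max(0L, min(excess, trim_left))
  s <- paste0(left_part, alt, right_part)
  substr(s, trim_left + 1L, trim_left + W)
}

#' Context window for an insertion
#'
#' Resolves a reference window of length `W` centred at the insertion point
#' (the payload is anchored after `pos`), inserts the payload at the window
#' midpoint, then truncates the result back to length `W`: `floor(k/2)` bases
#' are removed from the left and the remaining `ceil(k/2)` from the right for
#' a payload of length `k`.
#'
#' @param chrom_seq Chromosome sequence.
#' @param pos 1-based position after which the payload is inserted.
#' @param payload Inserted sequence (nonempty). A VCF-style anchored record
#'   (ref `"A"`, alt `"AGG"`) should be normalised to payload `"GG"` first,
#'   see [normalize_variant()].
#' @param W Window length.
#' @return String of length `W`.
#' @export
extract_insertion <- function(chrom_seq, pos, payload, W) {
  if (!nzchar(payload)) {
    stop("empty insertion payload", call. = FALSE)
  }
  win <- resolve_window(pos, W, nchar(chrom_seq))
  s <- substr(chrom_seq, win[1L], win[2L])
  mid <- as.integer(W) %/% 2L
  .truncate_around_alt(substr(s, 1L, mid), payload,
                       substr(s, mid + 1L, W), W)
}

#' Context window for a deletion
#'
#' Resolves a reference window of length `W + L` (L the deleted-segment
#' length) centred at `floor((s+e)/2)`, the midpoint of the deleted segment
#' `[s, e]`, and excises the segment, leaving exactly `W` bases.
#'
#' @param chrom_seq Chromosome sequence.
#' @param pos 1-based start of the deleted segment.
#' @param ref Deleted segment; must match the chromosome at `pos`.
#' @param W Window length.
#' @return String of length `W`.
#' @export
extract_deletion <- function(chrom_seq, pos, ref, W) {
  if (!nzchar(ref)) stop("empty deletion segment", call. = FALSE)
  .check_ref(chrom_seq, pos, ref)
  L <- nchar(ref)
  s_pos <- as.integer(pos); e_pos <- s_pos + L - 1L
  win <- resolve_window((s_pos + e_pos) %/% 2L, W + L, nchar(chrom_seq))
  if (s_pos < win[1L] || e_pos > win[2L]) {
    stop("deleted segment [", s_pos, ", ", e_pos,
         "] not contained in resolved window", call. = FALSE)
  }
  paste0(substr(chrom_seq, win[1L], s_pos - 1L),
         substr(chrom_seq, e_pos + 1L, win[2L]))
}

#' Context window for an indel (deletion followed by insertion)
#'
#' Performs the deletion construction (extended window of length `W + L`
#' centred on the replaced segment, segment excised), inserts the alternative
#' sequence at the excision point, and truncates to `W` with the same
#' centre-preserving rule as [extract_insertion()]. With `nchar(ref) ==
#' nchar(alt) == 1` this reduces exactly to [extract_snv()], and with empty
#' `alt` to [extract_deletion()].
#'
#' @param chrom_seq Chromosome sequence.
#' @param pos 1-based start of the replaced segment.
#' @param ref Replaced reference segment (nonempty, must match chromosome).
#' @param alt Replacement sequence (may be empty).
#' @param W Window length.
#' @return String of length `W`.
#' @export
extract_indel <- function(chrom_seq, pos, ref, alt, W) {
  if (!nzchar(ref)) stop("empty reference segment", call. = FALSE)
  if (!nzchar(alt)) return(extract_deletion(chrom_seq, pos, ref, W))
  .check_ref(chrom_seq, pos, ref)
  L <- nchar(ref)
  s_pos <- as.integer(pos); e_pos <- s_pos + L - 1L
  win <- resolve_window((s_pos + e_pos) %/% 2L, W + L, nchar(chrom_seq))
  if (s_pos < win[1L] || e_pos > win[2L]) {
    stop("replaced segment [", s_pos, ", ", e_pos,
         "] not contained in resolved window", call. = FALSE)
  }
  .truncate_around_alt(substr(chrom_seq, win[1L], s_pos - 1L), alt,
                       substr(chrom_seq, e_pos + 1L, win[2L]), W)
}

#' Normalise an anchored VCF-style record to the internal dialect
#'
#' VCF represents insertions/deletions with a shared anchor base (e.g. ref
#' `"A"`, alt `"AGG"` for an insertion after `pos`). The internal dialect
#' stores insertions as an empty ref plus a payload anchored after `pos`, and
#' deletions as the deleted segment with empty alt.
#'
#' @param pos,ref,alt Anchored VCF fields.
#' @return List with elements `pos`, `ref`, `alt`, `var_class`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = pos, ref = ref, alt = alt, var_class = "snv"))
  }
  if (nchar(ref) >= 1L && nchar(alt) > nchar(ref) &&
      substr(alt, 1L, nchar(ref)) == ref) {
    return(list(pos = pos + nchar(ref) - 1L, ref = "",
                alt = substr(alt, nchar(ref) + 1L, nchar(alt)),
                var_class = "insertion"))
  }
  if (nchar(alt) >= 1L && nchar(ref) > nchar(alt) &&
      substr(ref, 1L, nchar(alt)) == alt) {
    return(list(pos = pos + nchar(alt), ref = substr(ref, nchar(alt) + 1L,
                                                     nchar(ref)),
                alt = "", var_class = "deletion"))
  }
  list(pos = pos, ref = ref, alt = alt, var_class = "indel")
}

#' Context window for any variant record
#'
#' Dispatches on `var_class` (`snv`, `insertion`, `deletion`, `indel`) to the
#' class-specific extraction.
#'
#' @param chrom_seq Chromosome sequence.
#' @param variant One row of a variant table (list or 1-row data.frame with
#'   `pos`, `ref`, `alt`, `var_class`).
#' @param W Window length (required; the package sets no silent default).
#' @return String of length `W`.
#' @export
extract_context <- function(chrom_seq, variant, W) {
  v <- as.list(variant)
  pos <- as.integer(v$pos)
  switch(as.character(v$var_class),
    snv       = extract_snv(chrom_seq, pos, v$ref, v$alt, W),
    insertion = extract_insertion(chrom_seq, pos, v$alt, W),
    deletion  = extract_deletion(chrom_seq, pos, v$ref, W),
    indel     = extract_indel(chrom_seq, pos, v$ref, v$alt, W),
    stop("unknown variant class: '", v$var_class, "'", call. = FALSE)
  )
}

#' Context windows for a whole variant table
#'
#' @param genome Named character vector of chromosome sequences.
#' @param variants Variant table (see [read_variant_table()]).
#' @param W Window length.
#' @return Character vector of length `nrow(variants)`, named by variant id.
#' @export
extract_context_table <- function(genome, variants, W) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  out <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    chrom <- as.character(variants$chrom[i])
    if (is.null(genome[[chrom]])) {
      stop("chromosome '", chrom, "' not in genome", call. = FALSE)
    }
    out[i] <- extract_context(genome[[chrom]], variants[i, ], W)
  }
  names(out) <- variant_id(variants$chrom, variants$pos, variants$ref,
                           variants$alt)
  out
}

## ---------------------------------------------------------------------------
## Variant-table I/O
## ---------------------------------------------------------------------------

.variant_columns <- c("chrom", "pos", "ref", "alt", "var_class", "gene",
                      "clinical_label", "review_status", "origin", "assembly",
                      "submission_date", "diseases")

#' Read / write a variant table
#'
#' A ClinVar-style UTF-8 TSV with header columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `var_class` (one of snv/insertion/deletion/indel), `gene`,
#' `clinical_label`, `review_status`, `origin`, `assembly`,
#' `submission_date` (ISO date or empty) and `diseases`
#' (semicolon-separated names, possibly empty). Insertions use the internal
#' dialect: empty `ref`, payload in `alt`, anchored after `pos`.
#'
#' @param path File path.
#' @return data.frame with `pos` integer, everything else character.
#' @export
read_variant_table <- function(path) {
  df <- .read_tsv(path, .variant_columns)
  df$pos <- as.integer(df$pos)
  bad <- which(is.na(df$pos) |
               !(df$var_class %in% c("snv", "insertion", "deletion", "indel")))
  if (length(bad)) {
    stop("malformed row at line ", bad[[1L]] + 1L, " in '", path, "'",
         call. = FALSE)
  }
  df
}

#' @rdname read_variant_table
#' @param variants Variant table.
#' @export
write_variant_table <- function(variants, path) {
  .write_tsv(as.data.frame(variants)[, .variant_columns], path)
  invisible(path)
}
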