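AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

blosum62_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

aa_indices <- function(seq, what) {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("illegal residue(s) in %s: %s", what,
                 paste(bad, collapse = "")))
  }
  match(chars, rownames(blosum62()))
}

#' Local protein alignment
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1; a gap of length L costs 11 + L). Percent identity is computed
#' over all alignment columns including internal gaps (end gaps do not exist
#' in a local alignment). Traceback is deterministic: score ties prefer
#' diagonal over up over left.
#'
#' @param query,target Uppercase amino-acid sequences (20 canonical residues
#'   plus `X`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 / 1).
#' @return List: `score`, `identity` (percent), `aln_length`, `matches`, and
#'   1-based `query_start`/`query_end`/`target_start`/`target_end`.
#' @examples
#' local_align("MKVLATTPWE", "MKVLATTPWE")$identity # 100
#' @export
local_align <- function(query, target, gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  cpp_sw_align(aa_indices(query, "query"), aa_indices(target, "target"),
               blosum62(), gap_open, gap_extend)
}

#' Read a protein FASTA with genome-of-origin mapping
#'
#' The genome of each protein is taken from a `genome_id=<id>` token in the
#' record description, or from `genome_map` (named vector protein id ->
#' genome id) when supplied.
#'
#' @param path FASTA file (gzip transparent).
#' @param genome_map Optional named character vector overriding the
#'   description tokens.
#' @return Data frame: `protein_id`, `genome_id`, `sequence`.
#' @export
read_protein_fasta <- function(path, genome_map = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  full <- names(aa)
  ids <- vapply(strsplit(full, "\\s+"), `[`, "", 1)
  genome <- if (!is.null(genome_map)) {
    unname(genome_map[ids])
  } else {
    m <- regmatches(full, regexpr("genome_id=\\S+", full))
    g <- rep(NA_character_, length(full))
    g[grepl("genome_id=", full)] <- sub("genome_id=", "", m)
    g
  }
  data.frame(protein_id = ids, genome_id = genome,
             sequence = toupper(as.character(aa)),
             stringsAsFactors = FALSE, row.names = NULL)
}

kmer_set <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Search a protein catalog for a query gene
#'
#' Catalog entries sharing at least one exact 5-mer with the query are
#' aligned with [local_align()]; hits reaching `min_identity` percent over
#' an alignment covering at least half the query length are returned, ranked
#' by descending identity, then score, then target id. The word prefilter
#' cannot discard a full-length homolog at >= 95% identity for realistic
#' lengths (pigeonhole over 5-mer windows).
#'
#' @param query One-row data frame (or list) with `protein_id` and
#'   `sequence`.
#' @param catalog Data frame of `protein_id`, `sequence` rows (see
#'   [read_protein_fasta()]).
#' @param min_identity Percent identity cutoff (default 95; relax to 50 for
#'   distant homolog surveys).
#' @param min_coverage Minimum alignment length as a fraction of query
#'   length (default 0.5).
#' @return Data frame of hits: `query_id`, `target_id`, `identity`,
#'   `aln_length`, `matches`, `score`.
#' @export
search_catalog <- function(query, catalog, min_identity = 95,
                           min_coverage = 0.5) {
  if (NROW(catalog) == 0) stop("catalog is empty")
  qseq <- query$sequence
  qwords <- kmer_set(qseq)
  hits <- lapply(seq_len(nrow(catalog)), function(i) {
    tseq <- catalog$sequence[i]
    if (!any(kmer_set(tseq) %in% qwords)) return(NULL)
    aln <- local_align(qseq, tseq)
    if (aln$identity < min_identity ||
        aln$aln_length < min_coverage * nchar(qseq)) return(NULL)
    data.frame(query_id = query$protein_id, target_id = catalog$protein_id[i],
               identity = aln$identity, aln_length = aln$aln_length,
               matches = aln$matches, score = aln$score,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(query_id = character(0), target_id = character(0),
                      identity = numeric(0), aln_length = integer(0),
                      matches = integer(0), score = numeric(0)))
  }
  hits <- hits[order(-hits$identity, -hits$score, hits$target_id), ]
  rownames(hits) <- NULL
  hits
}

#' Species-level profile of gene-encoding genomes
#'
#' Resolves alignment hits to their genomes of origin and species clusters
#' and reports, per species, the number and fraction of member genomes
#' contributing at least one hit, ranked by descending encoding-genome
#' count, then fraction, then species id.
#'
#' @param hits Hit table from [search_catalog()].
#' @param genome_of Named character vector mapping protein id -> genome id
#'   (not needed if hits' targets are already genome ids).
#' @param clusters A `species_clusters` data frame.
#' @return Data frame: `species_id`, `n_encoding`, `n_genomes`, `fraction`.
#' @export
dominant_species <- function(hits, genome_of, clusters) {
  empty <- data.frame(species_id = character(0), n_encoding = integer(0),
                      n_genomes = integer(0), fraction = numeric(0))
  if (NROW(hits) == 0) return(empty)
  genomes <- unname(genome_of[hits$target_id])
  if (anyNA(genomes)) {
    stop("hit target(s) not resolvable to a genome: ",
         paste(unique(hits$target_id[is.na(genomes)]), collapse = ", "))
  }
  species_of <- setNames(clusters$cluster_id, clusters$genome_id)
  sp <- species_of[genomes]
  if (anyNA(sp)) {
    stop("genome(s) not in any cluster: ",
         paste(unique(genomes[is.na(sp)]), collapse = ", "))
  }
  enc <- tapply(genomes, sp, function(g) length(unique(g)))
  n_gen <- table(clusters$cluster_id)
  out <- data.frame(species_id = names(enc),
                    n_encoding = as.integer(enc),
                    n_genomes = as.integer(n_gen[names(enc)]),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_encoding / out$n_genomes
  out <- out[order(-out$n_encoding, -out$fraction, out$species_id), ]
  rownames(out) <- NULL
  out
}

#' Classify cross-host gene sharing
#'
#' Given the ranked species profiles of a gene in two host catalogs and the
#' shared-species pairing between the catalogs, a gene is `NOT_SHARED` when
#' host B has no hit, `SHARED_CONSERVED_LOCATION` when the dominant host-B
#' species is the shared-species partner of the dominant host-A species,
#' and `SHARED_DIFFERENT_LOCATION` otherwise.
#'
#' @param gene_id Gene label.
#' @param rank_a,rank_b [dominant_species()] tables for host A and host B
#'   (`rank_a` non-empty).
#' @param shared Shared-species pairs (`id_a`, `id_b`) from
#'   [shared_species()].
#' @return List: `gene_id`, `category`, `dominant_host_a`,
#'   `dominant_host_b` (`NA` when not shared).
#' @export
classify_gene_sharing <- function(gene_id, rank_a, rank_b, shared) {
  stopifnot(NROW(rank_a) >= 1)
  top_a <- rank_a$species_id[1]
  if (NROW(rank_b) == 0) {
    return(list(gene_id = gene_id, category = "NOT_SHARED",
                dominant_host_a = top_a, dominant_host_b = NA_character_))
  }
  top_b <- rank_b$species_id[1]
  partner <- shared$id_b[match(top_a, shared$id_a)]
  category <- if (!is.na(partner) && identical(partner, top_b)) {
    "SHARED_CONSERVED_LOCATION"
  } else {
    "SHARED_DIFFERENT_LOCATION"
  }
  list(gene_id = gene_id, category = category, dominant_host_a = top_a,
       dominant_host_b = top_b)
}

#' Write alignment hits as TSV
#'
#' BLAST outfmt-6-like columns.
#'
#' @param hits Hit table.
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
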