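#' @title MinHash genome sketches
#' @description
#' A sketch is the bottom-s MinHash of a genome's canonical k-mers: every
#' k-mer and its reverse complement are reduced to their lexicographic
#' minimum, hashed with a fixed seeded 64-bit mixing hash, and the `s`
#' smallest distinct hash values are retained. Two sketches estimate the
#' Jaccard similarity of the underlying k-mer sets, from which the Mash
#' distance (and hence average nucleotide identity) is derived.
#' @name sketching
NULL

DEFAULT_SKETCH_SEED <- 42L

#' Sketch a set of nucleotide sequences
#'
#' @param sequences Character vector or `Biostrings::DNAStringSet` of
#'   nucleotide sequences (all records of one genome). k-mers containing
#'   non-ACGT symbols are skipped.
#' @param genome_id Identifier stored in the sketch.
#' @param k K-mer length; odd, between 11 and 31 (default 21).
#' @param s Sketch size (default 1000).
#' @param seed Hash seed; sketches are only comparable at equal seeds.
#' @return An object of class `minhash_sketch`: list with `genome_id`, `k`,
#'   `s`, `seed`, `hashes` (ascending numeric) and `genome_length`.
#' @examples
#' sk <- sketch_sequences(paste(sample(c("A","C","G","T"), 5000,
#'                        replace = TRUE), collapse = ""), "g1")
#' length(sk$hashes) <= sk$s
#' @export
sketch_sequences <- function(sequences, genome_id, k = 21L, s = 1000L,
                             seed = DEFAULT_SKETCH_SEED) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  sequences <- as.character(sequences)
  if (length(sequences) == 0 || all(nchar(sequences) == 0)) {
    stop("empty sequence set")
  }
  if (k %% 2 == 0 || k < 11 || k > 31) {
    stop("k must be odd and between 11 and 31")
  }
  if (all(nchar(sequences) < k)) stop("k is longer than every sequence")
  hashes <- cpp_sketch(sequences, as.integer(k), as.integer(s),
                       as.double(seed))
  structure(list(genome_id = as.character(genome_id), k = as.integer(k),
                 s = as.integer(s), seed = as.integer(seed), hashes = hashes,
                 genome_length = sum(nchar(sequences))),
            class = "minhash_sketch")
}

#' Sketch genomes from FASTA files
#'
#' @param paths FASTA file paths (multi-record, gzip transparent).
#' @param genome_ids Identifiers, defaulting to file basenames without
#'   extension.
#' @inheritParams sketch_sequences
#' @return Named list of `minhash_sketch` objects.
#' @export
sketch_fasta <- function(paths, genome_ids = NULL, k = 21L, s = 1000L,
                         seed = DEFAULT_SKETCH_SEED) {
  if (is.null(genome_ids)) genome_ids <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                             basename(paths))
  sketches <- lapply(seq_along(paths), function(i) {
    sketch_sequences(Biostrings::readDNAStringSet(paths[i]), genome_ids[i],
                     k = k, s = s, seed = seed)
  })
  setNames(sketches, genome_ids)
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("minhash_sketch %s: k=%d s=%d |hashes|=%d length=%d bp\n",
              x$genome_id, x$k, x$s, length(x$hashes), x$genome_length))
  invisible(x)
}

check_comparable <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k || a$s != b$s) stop("sketches have mismatched k or s")
  if (a$seed != b$seed) stop("sketches have mismatched hash seed")
}

#' Mash distance between two sketches
#'
#' The Jaccard similarity `j` is estimated as the fraction of the `s`
#' smallest hashes of the merged sketch that occur in both sketches, and
#' converted to a genomic distance `d = -(1/k) * log(2 j / (1 + j))`, clipped
#' to \[0, 1\] (`j = 0` gives `d = 1`). The containment reported alongside
#' (shared hashes over the smaller sketch's size) is the sketch-space proxy
#' for the alignment fraction used by the species-clustering rule.
#'
#' @param a,b `minhash_sketch` objects with equal `k`, `s` and seed.
#' @return One-row data frame: `id_a`, `id_b`, `jaccard`, `mash_distance`,
#'   `containment`.
#' @export
mash_distance <- function(a, b) {
  check_comparable(a, b)
  u <- sort(unique(c(a$hashes, b$hashes)))
  top <- u[seq_len(min(a$s, length(u)))]
  shared_top <- sum(top %in% a$hashes & top %in% b$hashes)
  j <- shared_top / length(top)
  if (j <= 0) {
    d <- 1
  } else {
    d <- -log(2 * j / (1 + j)) / a$k
    d <- min(max(d, 0), 1)
  }
  shared_all <- sum(a$hashes %in% b$hashes)
  containment <- shared_all / min(length(a$hashes), length(b$hashes))
  data.frame(id_a = a$genome_id, id_b = b$genome_id, jaccard = j,
             mash_distance = d, containment = containment,
             stringsAsFactors = FALSE)
}

#' Estimated average nucleotide identity from sketches
#'
#' `ANI = 100 * (1 - mash_distance)`, the identification the 0.001-distance
#' dereplication rule (99.9% ANI) relies on.
#'
#' @inheritParams mash_distance
#' @return Estimated ANI, percent.
#' @export
estimated_ani <- function(a, b) {
  100 * (1 - mash_distance(a, b)$mash_distance)
}

#' Write / read sketches as JSON
#'
#' Hash values are serialized as unsigned decimal strings so files are exact
#' and platform independent.
#'
#' @param sketches Named list of `minhash_sketch` objects.
#' @param path Output / input file.
#' @return `read_sketches` returns the named list of sketches.
#' @export
write_sketches <- function(sketches, path) {
  payload <- lapply(unname(sketches), function(sk) {
    list(genome_id = sk$genome_id, k = sk$k, s = sk$s, seed = sk$seed,
         genome_length = sk$genome_length,
         hashes = format(sk$hashes, scientific = FALSE, trim = TRUE))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  sketches <- lapply(payload, function(p) {
    structure(list(genome_id = p$genome_id, k = as.integer(p$k),
                   s = as.integer(p$s), seed = as.integer(p$seed),
                   hashes = as.numeric(p$hashes),
                   genome_length = as.integer(p$genome_length)),
              class = "minhash_sketch")
  })
  setNames(sketches, vapply(sketches, `[[`, "", "genome_id"))
}
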