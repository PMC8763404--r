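ANNOTATION_SCHEMES <- c("INTERPRO", "KEGG_KO", "COG", "EGGNOG", "GO", "CAZY",
                        "METACYC", "GENOME_PROPERTY")

#' Read a per-genome functional annotation table
#'
#' Tab-delimited, three columns (`genome_id`, `feature_id`, `scheme`), header
#' optional, gzip transparent. Rows summarize InterProScan/eggNOG-style
#' annotation output: one row means "this genome carries this feature";
#' duplicated rows (copy number) are collapsed.
#'
#' @param path File path.
#' @return Data frame with columns `genome_id`, `feature_id`, `scheme`.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("genome_id", "feature_id", "scheme"))
  if (nrow(df) && identical(tolower(unlist(df[1, ], use.names = FALSE)),
                            c("genome_id", "feature_id", "scheme"))) {
    df <- df[-1, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_annotations(df)
}

validate_annotations <- function(df) {
  stopifnot(all(c("genome_id", "feature_id", "scheme") %in% names(df)))
  if (any(!nzchar(df$feature_id))) stop("empty feature_id")
  bad <- setdiff(unique(df$scheme), ANNOTATION_SCHEMES)
  if (length(bad)) stop("unknown annotation scheme(s): ",
                        paste(bad, collapse = ", "))
  unique(df[c("genome_id", "feature_id", "scheme")])
}

# scheme-namespaced feature labels, e.g. "INTERPRO:IPR023990"
namespace_features <- function(df) paste(df$scheme, df$feature_id, sep = ":")

#' Build a species-by-feature fraction matrix
#'
#' The pangenome functional profile: each cell holds the fraction of a
#' species cluster's member genomes annotated with the feature. Copy number
#' is ignored; a genome either carries a feature or not. Unannotated member
#' genomes still count in the denominator. Features are namespaced by scheme
#' (`SCHEME:feature`) so identifiers cannot collide across schemes.
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param clusters A `species_clusters` data frame (or any data frame with
#'   `cluster_id` and `genome_id`).
#' @return A `feature_matrix`: list with `species_ids`, `feature_ids`,
#'   `values` (species x feature matrix of fractions in \[0, 1\]) and
#'   `n_genomes` (named per-species genome counts).
#' @export
build_feature_matrix <- function(annotations, clusters) {
  annotations <- validate_annotations(annotations)
  stray <- setdiff(unique(annotations$genome_id), clusters$genome_id)
  if (length(stray)) {
    stop("annotated genome(s) absent from all clusters: ",
         paste(stray, collapse = ", "))
  }
  species_of <- setNames(clusters$cluster_id, clusters$genome_id)
  n_genomes <- table(clusters$cluster_id)
  species_ids <- sort(unique(clusters$cluster_id))
  features <- sort(unique(namespace_features(annotations)))
  values <- matrix(0, length(species_ids), length(features),
                   dimnames = list(species_ids, features))
  if (nrow(annotations)) {
    counts <- table(species_of[annotations$genome_id],
                    namespace_features(annotations))
    values[rownames(counts), colnames(counts)] <-
      as.matrix(counts) / as.vector(n_genomes[rownames(counts)])
  }
  structure(list(species_ids = species_ids, feature_ids = features,
                 values = values,
                 n_genomes = setNames(as.integer(n_genomes[species_ids]),
                                      species_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d species x %d features (%d genomes)\n",
              length(x$species_ids), length(x$feature_ids),
              sum(x$n_genomes)))
  invisible(x)
}

#' Search pangenomes for a feature
#'
#' Returns species carrying the feature in at least `threshold` of their
#' member genomes (boundary inclusive), ranked by descending number of
#' encoding genomes, then descending fraction, then species id.
#'
#' @param matrix A [build_feature_matrix()] result.
#' @param feature_id Namespaced feature label (e.g. `"INTERPRO:IPR023990"`).
#' @param threshold Minimum genome-carrying fraction (default 0, i.e. any
#'   carrier).
#' @return Data frame: `species_id`, `fraction`, `n_encoding`. Unknown
#'   features yield an empty result with a warning.
#' @export
feature_search <- function(matrix, feature_id, threshold = 0) {
  empty <- data.frame(species_id = character(0), fraction = numeric(0),
                      n_encoding = integer(0), stringsAsFactors = FALSE)
  if (!feature_id %in% matrix$feature_ids) {
    warning("feature not found in matrix: ", feature_id)
    return(empty)
  }
  frac <- matrix$values[, feature_id]
  n_enc <- as.integer(round(frac * matrix$n_genomes))
  keep <- frac >= threshold & frac > 0
  out <- data.frame(species_id = matrix$species_ids[keep],
                    fraction = unname(frac[keep]),
                    n_encoding = n_enc[keep], stringsAsFactors = FALSE)
  out[order(-out$n_encoding, -out$fraction, out$species_id), , drop = FALSE]
}

#' Define a pathway by required features
#'
#' @param name Pathway label.
#' @param required_all Character vector of namespaced feature ids, all of
#'   which a species must carry.
#' @param threshold Genome-carrying fraction each required feature must meet
#'   (default 0.70, the butyrate-producer cut).
#' @return A `pathway_definition` list.
#' @export
pathway_definition <- function(name, required_all, threshold = 0.70) {
  stopifnot(length(required_all) >= 1, threshold > 0, threshold <= 1)
  structure(list(name = name, required_all = unique(required_all),
                 threshold = threshold), class = "pathway_definition")
}

#' Butyrate terminal-pathway definitions
#'
#' The direct pathway requires butyryl-CoA:acetate CoA-transferase
#' (`IPR023990`); the indirect pathway requires both phosphotransbutyrylase
#' (`IPR014079`) and butyrate kinase (`IPR011245`) — species carrying only
#' one of the pair are never called producers. Producer status uses a 70%
#' genome-fraction threshold.
#'
#' @return A `pathway_definition`.
#' @export
bcoat_pathway <- function() {
  pathway_definition("BCOAT", "INTERPRO:IPR023990", 0.70)
}

#' @rdname bcoat_pathway
#' @export
ptb_buk_pathway <- function() {
  pathway_definition("PTB/BUK", c("INTERPRO:IPR011245", "INTERPRO:IPR014079"),
                     0.70)
}

#' Predict species encoding a pathway
#'
#' A species qualifies when every required feature meets the pathway's
#' genome-fraction threshold (inclusive). The reported score is the minimum
#' fraction across required features. Features absent from the matrix count
#' as fraction 0.
#'
#' @param matrix A [build_feature_matrix()] result.
#' @param pathway A [pathway_definition()].
#' @return Data frame: `species_id`, `score`, ordered as [feature_search()].
#' @export
predict_pathway_species <- function(matrix, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  frac <- sapply(pathway$required_all, function(f) {
    if (f %in% matrix$feature_ids) matrix$values[, f]
    else rep(0, length(matrix$species_ids))
  })
  frac <- matrix(frac, ncol = length(pathway$required_all),
                 dimnames = list(matrix$species_ids, pathway$required_all))
  score <- apply(frac, 1, min)
  keep <- score >= pathway$threshold
  n_enc <- as.integer(round(score * matrix$n_genomes))
  out <- data.frame(species_id = matrix$species_ids[keep],
                    score = unname(score[keep]),
                    n_encoding = n_enc[keep], stringsAsFactors = FALSE)
  out[order(-out$n_encoding, -out$score, out$species_id), , drop = FALSE]
}

#' Two-proportion z-test with Yates continuity correction
#'
#' Compares the proportion of pathway-encoding genomes between two species.
#' The statistic is the continuity-corrected difference of proportions under
#' the pooled-proportion null; its square equals the Yates-corrected
#' chi-square of the corresponding 2x2 table. Degenerate pooled proportions
#' (0 or 1) return `z = 0`, `p = 1`.
#'
#' @param count_a,count_b Length-2 vectors `c(encoding, total)`.
#' @return List with `z` (signed) and `p` (two-sided).
#' @export
compare_pathway_proportions <- function(count_a, count_b) {
  x1 <- count_a[1]; n1 <- count_a[2]; x2 <- count_b[1]; n2 <- count_b[2]
  stopifnot(n1 >= 1, n2 >= 1)
  if (x1 > n1 || x2 > n2) stop("encoding count exceeds total")
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) return(list(z = 0, p = 1))
  p1 <- x1 / n1; p2 <- x2 / n2
  correction <- 0.5 * (1 / n1 + 1 / n2)
  num <- max(abs(p1 - p2) - correction, 0)
  z <- sign(p1 - p2) * num / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Write / read a feature matrix as wide TSV
#'
#' Species rows, feature columns; the first column holds species ids, the
#' second per-species genome counts.
#'
#' @param matrix A `feature_matrix`.
#' @param path File path.
#' @return `read_feature_matrix` returns the `feature_matrix`.
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(species_id = matrix$species_ids,
                   n_genomes = matrix$n_genomes,
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$species_id
  structure(list(species_ids = df$species_id, feature_ids = colnames(values),
                 values = values,
                 n_genomes = setNames(as.integer(df$n_genomes),
                                      df$species_id)),
            class = "feature_matrix")
}

#' Write a feature matrix as sparse triplets
#'
#' Columns `species_id`, `feature_id`, `fraction`; zero cells omitted.
#'
#' @inheritParams write_feature_matrix
#' @export
write_feature_triplets <- function(matrix, path) {
  nz <- which(matrix$values > 0, arr.ind = TRUE)
  df <- data.frame(species_id = rownames(matrix$values)[nz[, 1]],
                   feature_id = colnames(matrix$values)[nz[, 2]],
                   fraction = matrix$values[nz], stringsAsFactors = FALSE)
  df <- df[order(df$species_id, df$feature_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
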