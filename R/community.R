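#' Construct a species abundance table
#'
#' Samples in rows, species in columns. `PERCENT` tables hold relative
#' abundances (percent of classified reads, row sums at most 100);
#' `COUNTS` tables hold raw assigned-read counts.
#'
#' @param values Numeric matrix (samples x species) with dimnames.
#' @param mode `"PERCENT"` or `"COUNTS"`.
#' @return An `abundance_table` (list with `values`, `mode`).
#' @export
abundance_table <- function(values, mode = c("PERCENT", "COUNTS")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values need sample row names and species column names")
  }
  if (any(values < 0)) stop("abundances must be >= 0")
  if (mode == "PERCENT" && any(rowSums(values) > 100 + 1e-6)) {
    stop("PERCENT rows must sum to <= 100")
  }
  structure(list(values = values, mode = mode), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table (%s): %d samples x %d species\n", x$mode,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

to_percent <- function(table) {
  if (table$mode == "PERCENT") return(table$values)
  totals <- rowSums(table$values)
  if (any(totals == 0)) stop("sample with zero total count")
  100 * table$values / totals
}

#' Species prevalence and mean abundance
#'
#' A species is present in a sample when its relative abundance reaches
#' `threshold` percent of classified reads (boundary inclusive; default
#' 0.01%). Prevalence is the percentage of samples in which the species is
#' present; mean abundance is the arithmetic mean over all samples, zeros
#' included. Count tables are converted to percent of per-sample totals
#' first.
#'
#' @param table An [abundance_table()].
#' @param threshold Presence threshold, percent (default 0.01).
#' @return Data frame: `species_id`, `prevalence`, `mean_abundance`,
#'   `n_samples`.
#' @export
prevalence_profile <- function(table, threshold = 0.01) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$values) == 0 || ncol(table$values) == 0) {
    stop("empty abundance table")
  }
  pct <- to_percent(table)
  n <- nrow(pct)
  data.frame(species_id = colnames(pct),
             prevalence = 100 * colSums(pct >= threshold) / n,
             mean_abundance = colMeans(pct),
             n_samples = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Centered log-ratio transform with multiplicative zero replacement
#'
#' Zeros in each sample are replaced by the posterior expectation under a
#' uniform prior of strength 0.5 per species (count-zero-multiplicative
#' rule): a zero part receives proportion `0.5 / (N + 0.5 D)` of the sample
#' (N = sample total, D = number of species) and the non-zero parts are
#' scaled multiplicatively so the sample total is preserved. Each row is
#' then transformed as `log(x) - mean(log(x))`; clr rows sum to zero.
#'
#' @param table A `COUNTS`-mode [abundance_table()].
#' @return Numeric matrix of clr values (samples x species).
#' @export
clr_transform <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "COUNTS") stop("clr_transform expects a COUNTS table")
  counts <- table$values
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("sample with all-zero counts")
  D <- ncol(counts)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    N <- totals[i]
    zero <- x == 0
    if (any(zero)) {
      p_zero <- 0.5 / (N + 0.5 * D)
      p <- numeric(D)
      p[zero] <- p_zero
      p[!zero] <- (1 - sum(zero) * p_zero) * x[!zero] / N
      x <- p * N
    }
    lg <- log(x)
    out[i, ] <- lg - mean(lg)
  }
  out
}

#' Aitchison distances between samples
#'
#' Euclidean distances between clr-transformed samples; invariant to
#' per-sample scaling of the underlying composition.
#'
#' @param clr_matrix Matrix of clr rows (see [clr_transform()]).
#' @return Validated distance matrix over the sample ids.
#' @export
aitchison_distance <- function(clr_matrix) {
  m <- as.matrix(dist(clr_matrix, method = "euclidean"))
  as_distance_matrix(m)
}

#' Read a Bracken species report
#'
#' Standard columns: `name`, `taxonomy_id`, `taxonomy_lvl`,
#' `kraken_assigned_reads`, `added_reads`, `new_est_reads`,
#' `fraction_total_reads`.
#'
#' @param path Report file.
#' @return Data frame of the report rows (species level only).
#' @export
read_bracken <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("name", "taxonomy_id", "taxonomy_lvl", "kraken_assigned_reads",
              "added_reads", "new_est_reads", "fraction_total_reads")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing Bracken columns: ",
                            paste(missing, collapse = ", "))
  df[df$taxonomy_lvl == "S", , drop = FALSE]
}

#' Compile Bracken reports into a counts table
#'
#' @param paths Report files, one per sample.
#' @param sample_ids Sample names (default: file basenames).
#' @return A `COUNTS`-mode [abundance_table()] using `new_est_reads`.
#' @export
compile_bracken <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sub("\\.\\w+$", "", basename(paths))
  reports <- lapply(paths, read_bracken)
  species <- sort(unique(unlist(lapply(reports, `[[`, "name"))))
  values <- matrix(0, length(paths), length(species),
                   dimnames = list(sample_ids, species))
  for (i in seq_along(reports)) {
    values[i, reports[[i]]$name] <- reports[[i]]$new_est_reads
  }
  abundance_table(values, "COUNTS")
}

#' Write / read an abundance table as wide TSV
#'
#' First column `sample_id`, remaining columns species.
#'
#' @param table An [abundance_table()].
#' @param path File path.
#' @param mode Mode to assume when reading.
#' @export
write_abundance_tsv <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path, mode = c("COUNTS", "PERCENT")) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  abundance_table(values, match.arg(mode))
}
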