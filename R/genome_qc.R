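#' Genome quality score
#'
#' The CheckM-derived quality score `QS = completeness - 5 * contamination`
#' used to rank and filter genome assemblies. Both inputs are on the 0-100
#' percent scale; the score may be negative for heavily contaminated bins.
#'
#' @param completeness Estimated completeness, percent (0-100).
#' @param contamination Estimated contamination, percent (>= 0).
#' @return Numeric vector of quality scores.
#' @examples
#' quality_score(96.9, 0.64) # 93.7
#' @export
quality_score <- function(completeness, contamination) {
  check_percent(completeness, "completeness", max = 100)
  check_percent(contamination, "contamination")
  completeness - 5 * contamination
}

#' Modified genome quality score
#'
#' Adds a natural-log N50 term to [quality_score()]:
#' `mQS = completeness - 5 * contamination + log(N50)`. Used to select the
#' highest-quality genome as the representative of a species cluster and to
#' order genomes during dereplication; the log term separates genomes with
#' equal CheckM metrics by assembly contiguity.
#'
#' @inheritParams quality_score
#' @param n50 Assembly N50 in base pairs (>= 1).
#' @return Numeric vector of modified quality scores.
#' @examples
#' modified_quality_score(95, 1, 10000) # 90 + log(1e4) = 99.21
#' @export
modified_quality_score <- function(completeness, contamination, n50) {
  if (any(!is.finite(n50)) || any(n50 < 1)) {
    stop("n50 must be >= 1 base pair")
  }
  quality_score(completeness, contamination) + log(n50)
}

check_percent <- function(x, name, max = Inf) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > max)) {
    stop(sprintf("%s must be on the 0-100 percent scale%s", name,
                 if (is.finite(max)) sprintf(" (<= %g)", max) else ""))
  }
  invisible(x)
}

qc_columns <- c("genome_id", "completeness", "contamination", "n50",
                "contig_count", "genome_size", "mean_contig_length")

#' Construct and validate a genome-quality table
#'
#' Bundles per-genome CheckM-style assembly metrics into the table consumed by
#' tier classification, dereplication and species clustering. Percentages are
#' on the 0-100 scale (fractional 0-1 inputs are rejected rather than
#' rescaled).
#'
#' @param df Data frame with columns `genome_id`, `completeness`,
#'   `contamination`, `n50`, `contig_count`, `genome_size`,
#'   `mean_contig_length` and optionally `source` (`"ISOLATE"` or `"MAG"`,
#'   default `"MAG"`).
#' @return The validated data frame with class `genome_quality`.
#' @export
genome_quality <- function(df) {
  missing <- setdiff(qc_columns, names(df))
  if (length(missing)) {
    stop("missing genome-quality columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$genome_id)) stop("duplicate genome_id values")
  check_percent(df$completeness, "completeness", max = 100)
  check_percent(df$contamination, "contamination")
  stopifnot(all(df$n50 >= 1), all(df$contig_count >= 1),
            all(df$genome_size >= 1), all(df$mean_contig_length >= 1),
            all(df$n50 <= df$genome_size))
  if (!"source" %in% names(df)) df$source <- "MAG"
  if (!all(df$source %in% c("ISOLATE", "MAG"))) {
    stop("source must be ISOLATE or MAG")
  }
  recon <- df$mean_contig_length * df$contig_count
  off <- abs(recon - df$genome_size) > 0.01 * df$genome_size
  if (any(off)) {
    stop("mean_contig_length * contig_count deviates >1% from genome_size for: ",
         paste(df$genome_id[off], collapse = ", "))
  }
  class(df) <- c("genome_quality", class(df))
  df
}

#' Assign genome quality tiers
#'
#' Classifies each genome as `HIGH`, `MEDIUM_PLUS` or `FAIL` following
#' MIMAG-style criteria. `HIGH` requires completeness >= 90, contamination
#' < 5, at most 500 contigs, genome size <= 8 Mb, N50 >= 10 kb and mean
#' contig length >= 5 kb. Genomes failing that but with completeness >= 50,
#' contamination < 5 and quality score >= 50 are `MEDIUM_PLUS`; the rest
#' `FAIL`. Every `HIGH` genome also satisfies the `MEDIUM_PLUS` rule.
#'
#' @param q A [genome_quality()] table.
#' @param contamination_inclusive Use `<= 5` instead of the default strict
#'   `< 5` contamination cut.
#' @param structural_criteria Apply the contig-count / genome-size / N50 /
#'   mean-contig-length criteria for the `HIGH` tier (default `TRUE` for
#'   isolates and MAGs alike).
#' @return Factor with levels `HIGH`, `MEDIUM_PLUS`, `FAIL`, one per row.
#' @export
classify_tier <- function(q, contamination_inclusive = FALSE,
                          structural_criteria = TRUE) {
  q <- as_genome_quality(q)
  cont_ok <- if (contamination_inclusive) q$contamination <= 5 else q$contamination < 5
  high <- q$completeness >= 90 & cont_ok
  if (structural_criteria) {
    high <- high & q$contig_count <= 500 & q$genome_size <= 8e6 &
      q$n50 >= 1e4 & q$mean_contig_length >= 5e3
  }
  qs <- quality_score(q$completeness, q$contamination)
  medium <- q$completeness >= 50 & cont_ok & qs >= 50
  factor(ifelse(high, "HIGH", ifelse(medium, "MEDIUM_PLUS", "FAIL")),
         levels = c("HIGH", "MEDIUM_PLUS", "FAIL"))
}

as_genome_quality <- function(q) {
  if (inherits(q, "genome_quality")) q else genome_quality(as.data.frame(q))
}

#' Filter genomes by minimum quality tier
#'
#' @param q A [genome_quality()] table.
#' @param tier Minimum tier to retain: `"HIGH"` or `"MEDIUM_PLUS"`
#'   (`MEDIUM_PLUS` also retains `HIGH` genomes).
#' @param ... Passed to [classify_tier()].
#' @return Character vector of genome ids meeting the tier, input order
#'   preserved.
#' @export
filter_genomes <- function(q, tier = c("HIGH", "MEDIUM_PLUS"), ...) {
  tier <- match.arg(tier)
  if (NROW(q) == 0) return(character(0))
  tiers <- classify_tier(q, ...)
  keep <- if (tier == "HIGH") tiers == "HIGH" else tiers != "FAIL"
  as.character(q$genome_id[keep])
}

#' Read a CheckM-style quality TSV
#'
#' Expects a tab-delimited file with a header row and columns `genome_id`,
#' `completeness`, `contamination`, `n50`, `contig_count`, `genome_size`,
#' `mean_contig_length` and optionally `source`.
#'
#' @param path File path (gzip transparent).
#' @return A [genome_quality()] table.
#' @export
read_quality_tsv <- function(path) {
  genome_quality(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Score and tier a quality table
#'
#' Convenience wrapper adding `qs`, `mqs` and `tier` columns, the layout the
#' command-line `qc` subcommand writes.
#'
#' @inheritParams classify_tier
#' @param ... Passed to [classify_tier()].
#' @return Data frame with the added columns.
#' @export
qc_table <- function(q, ...) {
  q <- as_genome_quality(q)
  out <- as.data.frame(q)
  out$qs <- quality_score(q$completeness, q$contamination)
  out$mqs <- modified_quality_score(q$completeness, q$contamination, q$n50)
  out$tier <- as.character(classify_tier(q, ...))
  out
}
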