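RANK_PREFIXES <- c(DOMAIN = "d__", PHYLUM = "p__", CLASS = "c__",
                   ORDER = "o__", FAMILY = "f__", GENUS = "g__",
                   SPECIES = "s__")

#' Parse a GTDB-style lineage string
#'
#' `"d__...;p__...;c__...;o__...;f__...;g__...;s__..."`; an empty label after
#' its prefix means unassigned at that rank.
#'
#' @param lineage Lineage string.
#' @return Named character vector of labels (prefixes stripped) for ranks
#'   DOMAIN..SPECIES.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (length(parts) != 7 ||
      !all(substr(parts, 1, 3) == unname(RANK_PREFIXES))) {
    stop("malformed GTDB lineage (expect 7 ';'-separated rank-prefixed labels): ",
         lineage)
  }
  setNames(substring(parts, 4), names(RANK_PREFIXES))
}

#' Deepest shared taxonomic rank of two lineages
#'
#' Compares labels from species upward; unassigned (empty) labels never
#' match.
#'
#' @param a,b Lineage strings.
#' @return One of `"SPECIES"`, `"GENUS"`, ..., `"DOMAIN"`, or `NA` when no
#'   rank label is shared.
#' @export
shared_rank <- function(a, b) {
  la <- parse_lineage(a); lb <- parse_lineage(b)
  for (rank in rev(names(RANK_PREFIXES))) {
    if (nzchar(la[[rank]]) && identical(la[[rank]], lb[[rank]])) return(rank)
  }
  NA_character_
}

#' Validate a distance matrix
#'
#' @param m Square numeric matrix with row/column names.
#' @return The matrix, checked for symmetry, zero diagonal, finite
#'   non-negative entries and matching dimnames.
#' @export
as_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("distance matrix needs matching row and column ids")
  }
  if (any(!is.finite(m)) || any(m < 0)) stop("distances must be finite and >= 0")
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero")
  if (any(abs(m - t(m)) > 1e-9)) stop("matrix must be symmetric")
  m
}

#' Functional distance between two pangenome profiles
#'
#' Jaccard distance between feature profiles. `BINARY` treats any fraction
#' > 0 as presence and returns `1 - |A n B| / |A u B|`; `WEIGHTED` is the
#' Ruzicka generalization `1 - sum(min) / sum(max)` over the real-valued
#' genome fractions. Two all-zero profiles have distance 0.
#'
#' @param profile_a,profile_b Named numeric vectors of feature fractions;
#'   features missing from one profile count as 0.
#' @param mode `"BINARY"` (default) or `"WEIGHTED"`.
#' @return Distance in \[0, 1\].
#' @export
functional_distance <- function(profile_a, profile_b,
                                mode = c("BINARY", "WEIGHTED")) {
  mode <- match.arg(mode)
  if (any(profile_a < 0) || any(profile_b < 0)) stop("negative fractions")
  universe <- union(names(profile_a), names(profile_b))
  if (is.null(universe)) {
    stopifnot(length(profile_a) == length(profile_b))
    a <- profile_a; b <- profile_b
  } else {
    a <- setNames(rep(0, length(universe)), universe)
    b <- a
    a[names(profile_a)] <- profile_a
    b[names(profile_b)] <- profile_b
  }
  if (mode == "BINARY") {
    inter <- sum(a > 0 & b > 0)
    uni <- sum(a > 0 | b > 0)
    if (uni == 0) return(0)
    1 - inter / uni
  } else {
    den <- sum(pmax(a, b))
    if (den == 0) return(0)
    1 - sum(pmin(a, b)) / den
  }
}

#' All-pairs functional distances for a feature matrix
#'
#' @param matrix A [build_feature_matrix()] result (or read back from TSV).
#' @inheritParams functional_distance
#' @return Validated distance matrix over the species ids, with the mode
#'   recorded in attribute `"mode"`.
#' @export
functional_distance_matrix <- function(matrix, mode = c("BINARY", "WEIGHTED")) {
  mode <- match.arg(mode)
  v <- matrix$values
  n <- nrow(v)
  d <- base::matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- functional_distance(v[i, ], v[j, ], mode)
    }
  }
  structure(as_distance_matrix(d), mode = mode)
}

#' Cophenetic distances from a species tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j — the taxonomic distance used against functional Jaccard
#' distances. Missing branch lengths are treated as 0 with a warning.
#'
#' @param tree Newick string, file path, or an `ape` `phylo` object.
#' @return Validated distance matrix over the leaf labels.
#' @export
cophenetic_distances <- function(tree) {
  phy <- if (inherits(tree, "phylo")) {
    tree
  } else if (length(tree) == 1 && !grepl("(", tree, fixed = TRUE) &&
             file.exists(tree)) {
    ape::read.tree(tree)
  } else {
    ape::read.tree(text = tree)
  }
  if (is.null(phy)) stop("malformed Newick tree")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths treated as 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < -1e-9)) stop("negative branch lengths")
  phy$edge.length <- pmax(phy$edge.length, 0)
  as_distance_matrix(ape::cophenetic.phylo(phy))
}

#' Closest taxonomic and functional cross-host neighbors
#'
#' For every host-A species, finds the host-B species at minimum taxonomic
#' (cophenetic) distance and the host-B species at minimum functional
#' distance (ties broken by id), records the deepest taxonomic rank the
#' query shares with its closest taxonomic neighbor, and whether the two
#' neighbors are the same taxon.
#'
#' @param host_a_species,host_b_species Character vectors of species ids.
#' @param tax,fun Distance matrices covering the union of the two id sets.
#' @param lineages Named character vector of GTDB lineage strings for all
#'   species.
#' @return Data frame: `query_species`, `closest_tax`, `closest_fun`,
#'   `shared_rank`, `tax_distance`, `fun_distance`, `agree`.
#' @export
assign_neighbors <- function(host_a_species, host_b_species, tax, fun,
                             lineages) {
  tax <- as_distance_matrix(tax); fun <- as_distance_matrix(fun)
  all_ids <- union(host_a_species, host_b_species)
  for (nm in list(c("taxonomic", "tax"), c("functional", "fun"))) {
    m <- get(nm[2])
    miss <- setdiff(all_ids, rownames(m))
    if (length(miss)) stop(sprintf("species missing from %s matrix: %s",
                                   nm[1], paste(miss, collapse = ", ")))
  }
  miss <- setdiff(all_ids, names(lineages))
  if (length(miss)) stop("species missing from lineage map: ",
                         paste(miss, collapse = ", "))
  b <- sort(host_b_species)
  rows <- lapply(host_a_species, function(qa) {
    td <- tax[qa, b]; fd <- fun[qa, b]
    ct <- b[order(td, b)][1]
    cf <- b[order(fd, b)][1]
    data.frame(query_species = qa, closest_tax = ct, closest_fun = cf,
               shared_rank = shared_rank(lineages[[qa]], lineages[[ct]]),
               tax_distance = unname(td[ct]), fun_distance = unname(fd[cf]),
               agree = ct == cf, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Neighbor agreement stratified by shared taxonomic rank
#'
#' Tabulates, per shared-rank stratum of the closest taxonomic neighbor, how
#' often the closest functional species is the same taxon as the closest
#' taxonomic species. Percentages are reported at one decimal (half away
#' from zero). An `OVERALL` row sums every stratum.
#'
#' @param assignments Result of [assign_neighbors()].
#' @return Data frame: `rank`, `n`, `n_agree`, `percent_agree`.
#' @export
agreement_by_rank <- function(assignments) {
  ranks <- c(names(RANK_PREFIXES)[7:1])
  present <- ranks[ranks %in% assignments$shared_rank]
  strata <- lapply(present, function(r) {
    sub <- assignments[assignments$shared_rank %in% r, ]
    data.frame(rank = r, n = nrow(sub), n_agree = sum(sub$agree),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(strata, list(
    data.frame(rank = "OVERALL", n = nrow(assignments),
               n_agree = sum(assignments$agree), stringsAsFactors = FALSE))))
  out$percent_agree <- ifelse(out$n > 0,
                              round_half_up(100 * out$n_agree / out$n, 1), NA)
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries; significance by
#' permuting the id order of the second matrix. The one-sided (greater)
#' p-value is `(1 + #permuted r >= observed r) / (1 + n_perm)`. With
#' `exact = TRUE` all `n!` permutations are enumerated and the p-value is
#' the exact permutation fraction (the identity included).
#'
#' @param a,b Distance matrices with identical ids in identical order.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all permutations (only sensible for small n).
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel <- function(a, b, n_perm = 999, seed = 1, exact = FALSE) {
  a <- as_distance_matrix(a); b <- as_distance_matrix(b)
  if (!identical(rownames(a), rownames(b))) {
    stop("matrices must share ids in the same order")
  }
  n <- nrow(a)
  if (n < 3) stop("need at least 3 ids")
  ut <- upper.tri(a)
  va <- a[ut]
  if (sd(va) == 0 || sd(b[ut]) == 0) stop("zero-variance distance triangle")
  robs <- cor(va, b[ut])
  perm_r <- function(idx) cor(va, b[idx, idx][ut])
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, 0)
    p <- sum(rs >= robs - 1e-12) / length(rs)
    n_perm <- length(rs)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    draw <- function() {
      # the identity permutation is excluded: the observed r is already
      # counted once by the +1 terms
      repeat {
        p <- sample.int(n)
        if (!identical(p, seq_len(n))) return(p)
      }
    }
    rs <- vapply(seq_len(n_perm), function(i) perm_r(draw()), 0)
    p <- (1 + sum(rs >= robs - 1e-12)) / (1 + n_perm)
  }
  list(r = robs, p = p, n_perm = n_perm)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Principal coordinates analysis
#'
#' Classical metric multidimensional scaling (double-centering of squared
#' distances and eigendecomposition) of a distance matrix; axes are ordered
#' by decreasing eigenvalue. Negative eigenvalues (non-Euclidean input) are
#' dropped with a warning and excluded from the explained-variance
#' denominator.
#'
#' @param d Distance matrix.
#' @param n_axes Number of axes to return (default 2).
#' @return List with `coordinates` (ids x axes) and `explained`
#'   (variance fractions per returned axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as_distance_matrix(d)
  if (nrow(d) < 2) stop("need at least 2 ids")
  k <- min(n_axes, nrow(d) - 1)
  fit <- cmdscale(as.dist(d), k = k, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  }
  pos <- fit$eig[fit$eig > 1e-12]
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  explained <- fit$eig[seq_len(ncol(coords))] / sum(pos)
  list(coordinates = coords, explained = explained)
}

#' Shared species between two host catalogs
#'
#' Representatives are matched when their species-rank lineage labels are
#' identical and non-empty, or when their sketches reach the ANI and
#' containment thresholds of the species rule. Each species matches at most
#' one partner; label matches take precedence, remaining candidates are
#' resolved by descending estimated ANI.
#'
#' @param sketches_a,sketches_b Named lists of species-representative
#'   sketches (one per species).
#' @param lineages_a,lineages_b Named character vectors of lineage strings.
#' @param ani_threshold,af_threshold Species-rule thresholds (95 / 0.6).
#' @return Data frame: `id_a`, `id_b`, `ani`, `by_label`.
#' @export
shared_species <- function(sketches_a, lineages_a, sketches_b, lineages_b,
                           ani_threshold = 95, af_threshold = 0.6) {
  ids_a <- names(sketches_a); ids_b <- names(sketches_b)
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    stop("duplicate species ids within a catalog")
  }
  sp_label <- function(lin) {
    unname(vapply(lin, function(x) parse_lineage(x)[["SPECIES"]], ""))
  }
  la <- sp_label(lineages_a[ids_a]); lb <- sp_label(lineages_b[ids_b])
  cand <- list()
  for (i in seq_along(ids_a)) {
    for (j in seq_along(ids_b)) {
      label_match <- nzchar(la[i]) && identical(la[i], lb[j])
      pd <- mash_distance(sketches_a[[i]], sketches_b[[j]])
      ani <- 100 * (1 - pd$mash_distance)
      ani_match <- ani >= ani_threshold && pd$containment >= af_threshold
      if (label_match || ani_match) {
        cand[[length(cand) + 1L]] <-
          data.frame(id_a = ids_a[i], id_b = ids_b[j], ani = ani,
                     by_label = label_match, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      ani = numeric(0), by_label = logical(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$by_label, -cand$ani, cand$id_a, cand$id_b), ]
  used_a <- used_b <- character(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!(cand$id_a[r] %in% used_a) && !(cand$id_b[r] %in% used_b)) {
      keep[r] <- TRUE
      used_a <- c(used_a, cand$id_a[r]); used_b <- c(used_b, cand$id_b[r])
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalog summary percentages
#'
#' Derives the headline percentages of a catalog comparison from its integer
#' counts, rounded half away from zero at the precision conventionally
#' printed: cultured fraction and novel-contribution at one decimal, shared
#' fraction at two decimals, and the increase in cultured diversity
#' (`novel / (cultured - novel)`) at one decimal.
#'
#' @param n_species_total Species in the catalog.
#' @param n_cultured Species with cultured representatives.
#' @param n_novel_cultured Cultured species contributed uniquely by the new
#'   collection.
#' @param n_shared Species shared between the two host catalogs.
#' @param n_combined Species in the combined catalog.
#' @return List of the available counts plus derived percentages
#'   (`pct_cultured`, `pct_novel_contribution`, `pct_diversity_increase`,
#'   `pct_shared`).
#' @export
catalog_summary <- function(n_species_total = NA, n_cultured = NA,
                            n_novel_cultured = NA, n_shared = NA,
                            n_combined = NA) {
  args <- c(n_species_total, n_cultured, n_novel_cultured, n_shared,
            n_combined)
  if (any(args < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!is.na(n_shared) && !is.na(n_combined) && n_shared > n_combined) {
    stop("n_shared exceeds n_combined")
  }
  if (!is.na(n_novel_cultured) && !is.na(n_cultured) &&
      n_novel_cultured > n_cultured) {
    stop("n_novel_cultured exceeds n_cultured")
  }
  pct <- function(num, den, d) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) stop("zero denominator")
    round_half_up(100 * num / den, d)
  }
  out <- list(
    n_species_total = n_species_total, n_cultured = n_cultured,
    n_novel_cultured = n_novel_cultured, n_shared = n_shared,
    n_combined = n_combined,
    pct_cultured = pct(n_cultured, n_species_total, 1),
    pct_novel_contribution = pct(n_novel_cultured, n_cultured, 1),
    pct_diversity_increase = pct(n_novel_cultured,
                                 if (is.na(n_cultured) ||
                                     is.na(n_novel_cultured)) NA
                                 else n_cultured - n_novel_cultured, 1),
    pct_shared = pct(n_shared, n_combined, 2))
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  for (nm in names(x)) {
    if (!is.na(x[[nm]])) cat(sprintf("%-24s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Percentage at printed precision
#'
#' `100 * numerator / denominator`, rounded half away from zero at `digits`
#' decimals — the rounding used for every reported summary percentage.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' percent_of(670, 805) # 83.2
#' @export
percent_of <- function(numerator, denominator, digits = 1) {
  if (denominator == 0) stop("zero denominator")
  round_half_up(100 * numerator / denominator, digits)
}

#' Read lineages from TSV
#'
#' Two columns: id and GTDB lineage string; header optional.
#'
#' @param path File path.
#' @return Named character vector of lineages.
#' @export
read_lineages <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) && grepl("lineage", df[1, 2], ignore.case = TRUE)) {
    df <- df[-1, , drop = FALSE]
  }
  setNames(df[[2]], df[[1]])
}

#' Write / read a distance matrix as TSV
#'
#' Ids in the first row and first column.
#'
#' @param m Distance matrix.
#' @param path File path.
#' @export
write_distance_tsv <- function(m, path) {
  m <- as_distance_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_distance_matrix(m)
}
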