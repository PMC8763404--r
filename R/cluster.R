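#' Dereplicate near-identical genomes
#'
#' Removes conspecific redundancy: genomes are visited in order of
#' descending modified quality score (ties broken by lexicographic id) and a
#' genome is retained only if its Mash distance to every previously retained
#' genome exceeds `threshold`. The default 0.001 corresponds to 99.9%
#' estimated ANI, so byte-identical and near-identical assemblies collapse to
#' their best-quality representative.
#'
#' @param quality A [genome_quality()] table covering every sketch.
#' @param sketches Named list of [sketch_sequences()] results.
#' @param threshold Mash distance above which genomes are considered
#'   distinct (default 0.001).
#' @return Character vector of retained genome ids in acceptance order.
#' @export
dereplicate <- function(quality, sketches, threshold = 0.001) {
  quality <- as_genome_quality(quality)
  ids <- vapply(sketches, `[[`, "", "genome_id")
  names(sketches) <- ids
  missing <- setdiff(ids, quality$genome_id)
  if (length(missing)) {
    stop("no quality record for: ", paste(missing, collapse = ", "))
  }
  ord <- order_by_mqs(quality, ids)
  retained <- character(0)
  for (id in ord) {
    ok <- TRUE
    for (r in retained) {
      if (mash_distance(sketches[[id]], sketches[[r]])$mash_distance <= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) retained <- c(retained, id)
  }
  retained
}

order_by_mqs <- function(quality, ids) {
  q <- quality[match(ids, quality$genome_id), ]
  mqs <- modified_quality_score(q$completeness, q$contamination, q$n50)
  ids[order(-mqs, ids)]
}

#' Cluster genomes into species at an ANI threshold
#'
#' Greedy centroid clustering of a dereplicated genome set: genomes are
#' processed by descending modified quality score and assigned to the first
#' existing cluster whose representative they match at estimated
#' ANI >= `ani_threshold` and sketch containment >= `af_threshold` (the
#' sketch-space stand-in for the alignment-fraction criterion); otherwise
#' they found a new cluster. Genomes sharing >= 95% ANI at 0.6 alignment
#' fraction are thereby considered the same species. The cluster
#' representative is its highest-mQS member.
#'
#' @inheritParams dereplicate
#' @param ani_threshold Species boundary, percent ANI (default 95).
#' @param af_threshold Minimum containment (default 0.6).
#' @param lineages Optional named character vector of GTDB-style lineage
#'   strings, attached to clusters via their representative genome.
#' @return A `species_clusters` data frame: `cluster_id`, `genome_id`,
#'   `is_representative`, `lineage`. Clusters partition the input.
#' @export
cluster_species <- function(sketches, quality, ani_threshold = 95,
                            af_threshold = 0.6, lineages = NULL) {
  if (length(sketches) == 0) stop("empty input")
  quality <- as_genome_quality(quality)
  ids <- vapply(sketches, `[[`, "", "genome_id")
  names(sketches) <- ids
  ord <- order_by_mqs(quality, ids)
  reps <- character(0)     # representative (founder) per cluster, in order
  members <- list()
  for (id in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      pd <- mash_distance(sketches[[id]], sketches[[reps[ci]]])
      ani <- 100 * (1 - pd$mash_distance)
      if (ani >= ani_threshold && pd$containment >= af_threshold) {
        members[[ci]] <- c(members[[ci]], id)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  out <- do.call(rbind, lapply(seq_along(reps), function(ci) {
    data.frame(cluster_id = sprintf("cluster_%04d", ci),
               genome_id = members[[ci]],
               is_representative = members[[ci]] == reps[ci],
               stringsAsFactors = FALSE)
  }))
  out$lineage <- if (is.null(lineages)) NA_character_ else {
    rep_of <- setNames(rep(reps, lengths(members)), out$genome_id)
    unname(lineages[rep_of[out$genome_id]])
  }
  class(out) <- c("species_clusters", class(out))
  out
}

#' @export
print.species_clusters <- function(x, ...) {
  cat(sprintf("species_clusters: %d genomes in %d clusters\n",
              nrow(x), length(unique(x$cluster_id))))
  invisible(x)
}

#' Prior cultured status of an isolate
#'
#' An isolate is called `PREVIOUSLY_UNCULTURED` when it shares < 95%
#' estimated ANI with every genome of a reference (cultured) collection,
#' i.e. no previously cultured representative of its species exists.
#'
#' @param isolate A `minhash_sketch`.
#' @param reference Non-empty list of reference `minhash_sketch` objects.
#' @param ani_threshold Species boundary, percent (default 95).
#' @return `"PREVIOUSLY_CULTURED"` or `"PREVIOUSLY_UNCULTURED"`.
#' @export
prior_cultured_status <- function(isolate, reference, ani_threshold = 95) {
  if (length(reference) == 0) stop("empty reference set")
  best <- max(vapply(reference, function(r) estimated_ani(isolate, r), 0))
  if (best < ani_threshold) "PREVIOUSLY_UNCULTURED" else "PREVIOUSLY_CULTURED"
}

#' Write species clusters as TSV
#'
#' @param clusters A `species_clusters` data frame.
#' @param path Output file.
#' @export
write_clusters_tsv <- function(clusters, path) {
  write.table(as.data.frame(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read species clusters from TSV
#'
#' @param path File with columns `cluster_id`, `genome_id`,
#'   `is_representative`, `lineage`.
#' @return A `species_clusters` data frame.
#' @export
read_clusters_tsv <- function(path) {
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(out) <- c("species_clusters", class(out))
  out
}
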