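#' Synthetic-data configuration
#'
#' Bundles the parameters of the seeded generators that emit every input the
#' pipeline consumes, together with planted ground truth. Divergences are
#' per-site substitution fractions; intra-species divergence must be below
#' inter-species divergence, and the cross-host twin divergence sits between
#' them so that a species' closest taxonomic neighbor in the other host is
#' its twin.
#'
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical outputs.
#' @param n_species_a Number of host-A species (each gets a host-B twin).
#' @param genomes_per_species Genomes per species cluster, both hosts.
#' @param genome_length Genome length, base pairs.
#' @param intra_species_divergence Within-species per-site divergence.
#' @param inter_species_divergence Between-species (within-genus) per-site
#'   divergence.
#' @param twin_divergence Divergence between a host-A species and its
#'   host-B twin.
#' @param n_features Size of the functional feature universe.
#' @param feature_presence Probability a feature belongs to a species' base
#'   profile.
#' @param feature_turnover Fraction of the feature universe toggled between
#'   a species and its cross-host twin.
#' @param planted_disagreement_rate Fraction of host-A species whose closest
#'   functional host-B species is planted to differ from the taxonomic twin.
#' @param shared_species_fraction Fraction of twins labeled as the same
#'   GTDB species (the rest share only the genus label).
#' @param species_per_genus Species pairs per genus.
#' @param n_samples Samples for the abundance generator.
#' @param depth Reads per sample.
#' @param occupancy Probability a species occupies a sample.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_species_a = 50L, genomes_per_species = 3L,
                       genome_length = 20000L,
                       intra_species_divergence = 0.005,
                       inter_species_divergence = 0.1,
                       twin_divergence = 0.02,
                       n_features = 300L, feature_presence = 0.3,
                       feature_turnover = 0.1,
                       planted_disagreement_rate = 0.1,
                       shared_species_fraction = 0.3,
                       species_per_genus = 5L,
                       n_samples = 20L, depth = 1e5, occupancy = 0.5) {
  cfg <- as.list(environment())
  fr <- c(intra_species_divergence, inter_species_divergence,
          twin_divergence, feature_presence, feature_turnover,
          planted_disagreement_rate, shared_species_fraction, occupancy)
  stopifnot(all(fr >= 0), all(fr <= 1),
            intra_species_divergence < inter_species_divergence,
            twin_divergence < inter_species_divergence,
            n_species_a >= 1, genomes_per_species >= 1, genome_length >= 21)
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each site independently at `rate`; substituted base differs
# from the original. Returns the sequence and the realized divergence.
mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
    }
  }
  list(seq = paste(chars, collapse = ""),
       realized = length(hit) / length(chars))
}

#' Simulate a genome pair at controlled divergence
#'
#' The second genome is the first with independent per-site substitutions at
#' the given rate (a substituted base always differs from the original), so
#' the realized divergence is exactly the fraction of differing sites —
#' the analytic ground truth for Mash-distance calibration.
#'
#' @param length Genome length, base pairs (>= 21).
#' @param divergence Substitution rate in \[0, 0.2\].
#' @param seed Integer seed.
#' @return List: `seq_a`, `seq_b`, `realized_divergence`.
#' @export
simulate_genome_pair <- function(length, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.2)
  if (length < 21) stop("length must be at least the default k-mer size (21)")
  with_seed(seed, {
    a <- random_dna(length)
    m <- mutate_dna(a, divergence)
    list(seq_a = a, seq_b = m$seq, realized_divergence = m$realized)
  })
}

#' Simulate a pair of host catalogs with planted ground truth
#'
#' Generates two host catalogs in which every host-A species has a host-B
#' twin: genomes within a species diverge at the intra-species rate, twins
#' at the twin rate, genus mates at the inter-species rate. Functional
#' profiles are planted per species; a twin's profile is the host-A profile
#' with a fixed set of toggled features. For a planted fraction of host-A
#' species an extra host-B genus mate is created whose profile toggles a
#' subset of the twin's toggles, so it is strictly functionally closer to
#' the query than the taxonomic twin — the planted closest-functional
#' disagreements. The species tree is derived from the planted divergence
#' hierarchy, so cophenetic distances and sketch ANI are mutually
#' consistent. Genome quality metrics are drawn uniformly within
#' high-quality-tier bounds.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_catalogs` list: `genomes` (named list of sequences),
#'   `quality` ([genome_quality()] table), `annotations` (data frame),
#'   `tree` (Newick string), `lineages` (named vector over species ids),
#'   `host_a_species`, `host_b_species`, and `truth` (list with
#'   `membership`, `twin`, `closest_fun`, `disagree`, `profiles`).
#' @export
simulate_catalogs <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_catalogs_impl(cfg))
}

simulate_catalogs_impl <- function(cfg) {
  nA <- cfg$n_species_a
  n_dis <- round(cfg$planted_disagreement_rate * nA)
  n_genera <- ceiling(nA / cfg$species_per_genus)
  genus_of <- rep(seq_len(n_genera), each = cfg$species_per_genus)[seq_len(nA)]
  pair_ids <- sprintf("sp%03d", seq_len(nA))
  a_ids <- paste0("A_", pair_ids)
  b_ids <- paste0("B_", pair_ids)
  disagree_idx <- sort(sample.int(nA, n_dis))
  extra_ids <- if (n_dis > 0) paste0("B_", pair_ids[disagree_idx], "x") else character(0)

  n_flip <- max(2L, round(cfg$feature_turnover * cfg$n_features))
  n_flip_extra <- max(1L, n_flip %/% 4L)
  if (n_flip_extra >= n_flip) {
    stop("infeasible configuration: feature turnover too small to plant ",
         "functional disagreements")
  }

  # --- sequences along the planted divergence hierarchy -------------------
  genus_anc <- lapply(seq_len(n_genera),
                      function(i) random_dna(cfg$genome_length))
  species_anc <- lapply(seq_len(nA), function(i) {
    mutate_dna(genus_anc[[genus_of[i]]], cfg$inter_species_divergence / 2)$seq
  })
  rep_seq <- list()
  for (i in seq_len(nA)) {
    rep_seq[[a_ids[i]]] <- mutate_dna(species_anc[[i]],
                                      cfg$twin_divergence / 2)$seq
    rep_seq[[b_ids[i]]] <- mutate_dna(species_anc[[i]],
                                      cfg$twin_divergence / 2)$seq
  }
  for (j in seq_along(disagree_idx)) {
    i <- disagree_idx[j]
    rep_seq[[extra_ids[j]]] <-
      mutate_dna(genus_anc[[genus_of[i]]], cfg$inter_species_divergence / 2)$seq
  }
  species_ids <- c(a_ids, b_ids, extra_ids)

  genomes <- list()
  membership <- list()
  for (sp in species_ids) {
    for (g in seq_len(cfg$genomes_per_species)) {
      gid <- sprintf("%s_g%02d", sp, g)
      genomes[[gid]] <- if (g == 1) rep_seq[[sp]] else
        mutate_dna(rep_seq[[sp]], cfg$intra_species_divergence)$seq
      membership[[gid]] <- sp
    }
  }
  membership <- data.frame(genome_id = names(membership),
                           species_id = unlist(membership, use.names = FALSE),
                           host = substr(unlist(membership, use.names = FALSE),
                                         1, 1),
                           stringsAsFactors = FALSE)

  # --- quality metrics drawn within HIGH-tier bounds ----------------------
  # The reported assembly statistics emulate full-size genomes; the emitted
  # sequences are shorter surrogates sized for sketching, so the two are
  # deliberately decoupled.
  ng <- nrow(membership)
  genome_size <- round(runif(ng, 2e6, 5e6))
  contig_count <- sample(50:200, ng, replace = TRUE)
  mean_len <- genome_size / contig_count
  quality <- genome_quality(data.frame(
    genome_id = membership$genome_id,
    completeness = runif(ng, 90, 100),
    contamination = runif(ng, 0, 4.9),
    n50 = round(2 * mean_len),
    contig_count = contig_count,
    genome_size = genome_size,
    mean_contig_length = mean_len,
    source = "MAG", stringsAsFactors = FALSE))

  # --- planted feature profiles ------------------------------------------
  feats <- sprintf("F%05d", seq_len(cfg$n_features))
  profiles <- matrix(FALSE, length(species_ids), cfg$n_features,
                     dimnames = list(species_ids, feats))
  flips <- list()
  for (i in seq_len(nA)) {
    base <- runif(cfg$n_features) < cfg$feature_presence
    profiles[a_ids[i], ] <- base
    flip <- sample.int(cfg$n_features, n_flip)
    twin <- base
    twin[flip] <- !twin[flip]
    profiles[b_ids[i], ] <- twin
    flips[[i]] <- flip
  }
  for (j in seq_along(disagree_idx)) {
    i <- disagree_idx[j]
    # toggles a strict subset of the twin's toggles: strictly closer to A_i
    sub_flip <- flips[[i]][seq_len(n_flip_extra)]
    extra <- profiles[a_ids[i], ]
    extra[sub_flip] <- !extra[sub_flip]
    profiles[extra_ids[j], ] <- extra
  }

  annotations <- do.call(rbind, lapply(seq_len(nrow(membership)), function(r) {
    sp <- membership$species_id[r]
    present <- feats[profiles[sp, ]]
    if (!length(present)) return(NULL)
    data.frame(genome_id = membership$genome_id[r], feature_id = present,
               scheme = "INTERPRO", stringsAsFactors = FALSE)
  }))

  # --- species tree from the divergence hierarchy -------------------------
  n_sp <- length(species_ids)
  pair_of <- c(seq_len(nA), seq_len(nA), disagree_idx)
  genus_of_sp <- genus_of[pair_of]
  is_extra <- c(rep(FALSE, 2 * nA), rep(TRUE, length(disagree_idx)))
  d <- matrix(0, n_sp, n_sp, dimnames = list(species_ids, species_ids))
  for (i in seq_len(n_sp)) {
    for (j in seq_len(i - 1)) {
      d[i, j] <- d[j, i] <-
        if (genus_of_sp[i] != genus_of_sp[j]) {
          2 * cfg$inter_species_divergence
        } else if (pair_of[i] == pair_of[j] && !is_extra[i] && !is_extra[j]) {
          cfg$twin_divergence
        } else {
          cfg$inter_species_divergence
        }
    }
  }
  phy <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  # averaging introduces float noise around exact heights; clamp at zero
  phy$edge.length <- pmax(phy$edge.length, 0)
  tree <- ape::write.tree(phy)

  # --- lineages -----------------------------------------------------------
  shared_label <- runif(nA) < cfg$shared_species_fraction
  lineages <- character(0)
  for (i in seq_len(nA)) {
    g <- sprintf("Genus%02d", genus_of[i])
    stem <- sprintf("d__Bacteria;p__Phylum01;c__Class01;o__Order01;f__Family%02d;g__%s;s__%s",
                    genus_of[i], g, "%s")
    sA <- sprintf("%s speciesA%03d", g, i)
    sB <- if (shared_label[i]) sA else sprintf("%s speciesB%03d", g, i)
    lineages[a_ids[i]] <- sprintf(stem, sA)
    lineages[b_ids[i]] <- sprintf(stem, sB)
  }
  for (j in seq_along(disagree_idx)) {
    i <- disagree_idx[j]
    g <- sprintf("Genus%02d", genus_of[i])
    lineages[extra_ids[j]] <-
      sprintf("d__Bacteria;p__Phylum01;c__Class01;o__Order01;f__Family%02d;g__%s;s__%s extra%03d",
              genus_of[i], g, g, i)
  }

  closest_fun <- setNames(b_ids, a_ids)
  closest_fun[a_ids[disagree_idx]] <- extra_ids

  structure(list(
    genomes = genomes, quality = quality, annotations = annotations,
    tree = tree, lineages = lineages,
    host_a_species = a_ids, host_b_species = c(b_ids, extra_ids),
    truth = list(membership = membership,
                 twin = setNames(b_ids, a_ids),
                 closest_fun = closest_fun,
                 disagree = a_ids[disagree_idx],
                 shared_label = setNames(shared_label, a_ids),
                 profiles = profiles)),
    class = "sim_catalogs")
}

#' @export
print.sim_catalogs <- function(x, ...) {
  cat(sprintf("sim_catalogs: %d genomes, %d host-A + %d host-B species\n",
              length(x$genomes), length(x$host_a_species),
              length(x$host_b_species)))
  invisible(x)
}

#' Simulate a protein homolog pair at a target identity
#'
#' The homolog is the query with independent residue substitutions at rate
#' `1 - identity / 100` (substituted residues always differ), so the
#' realized identity is known exactly from the mutation mask.
#'
#' @param length Protein length in residues (>= 10).
#' @param target_identity Target percent identity (0, 100].
#' @param seed Integer seed.
#' @return List: `query`, `homolog`, `realized_identity`.
#' @export
simulate_protein_family <- function(length, target_identity, seed = 1L) {
  stopifnot(length >= 10, target_identity > 0, target_identity <= 100)
  aa <- setdiff(AA_ALPHABET, "X")
  with_seed(seed, {
    q <- sample(aa, length, replace = TRUE)
    h <- q
    hit <- which(runif(length) < 1 - target_identity / 100)
    for (i in hit) h[i] <- sample(setdiff(aa, q[i]), 1)
    list(query = paste(q, collapse = ""), homolog = paste(h, collapse = ""),
         realized_identity = 100 * (1 - length(hit) / length))
  })
}

#' Simulate species abundance counts with planted occupancy
#'
#' Species receive log-normal expected abundances; each sample draws
#' multinomial counts at the configured depth over the species present in
#' it (the planted occupancy mask zeroes absent species).
#'
#' @param cfg A [sim_config()] (uses `n_species_a`, `n_samples`, `depth`,
#'   `occupancy`, `seed`).
#' @return List: `table` (a `COUNTS` [abundance_table()]) and `occupancy`
#'   (logical samples x species matrix).
#' @export
simulate_abundance <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_samples >= 1)
  with_seed(cfg$seed + 1L, {
    species <- sprintf("sp%03d", seq_len(cfg$n_species_a))
    samples <- sprintf("sample%03d", seq_len(cfg$n_samples))
    mu <- rlnorm(cfg$n_species_a, meanlog = 0, sdlog = 1)
    occ <- matrix(runif(cfg$n_samples * cfg$n_species_a) < cfg$occupancy,
                  cfg$n_samples, cfg$n_species_a,
                  dimnames = list(samples, species))
    # every sample needs at least one occupant
    for (i in which(rowSums(occ) == 0)) occ[i, sample.int(cfg$n_species_a, 1)] <- TRUE
    counts <- matrix(0, cfg$n_samples, cfg$n_species_a,
                     dimnames = list(samples, species))
    for (i in seq_len(cfg$n_samples)) {
      p <- mu * occ[i, ]
      counts[i, ] <- rmultinom(1, size = cfg$depth, prob = p / sum(p))
    }
    list(table = abundance_table(counts, "COUNTS"), occupancy = occ)
  })
}

#' Write simulated catalogs to disk
#'
#' Emits per-genome FASTA files (`genomes/`), `quality.tsv`,
#' `annotations.tsv`, `tree.nwk`, `lineages.tsv` and `truth.json` — the
#' formats every consuming module reads.
#'
#' @param sim A [simulate_catalogs()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalogs <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_catalogs"))
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  for (gid in names(sim$genomes)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sim$genomes[[gid]], gid)),
      file.path(dir, "genomes", paste0(gid, ".fa")))
  }
  write.table(as.data.frame(sim$quality), file.path(dir, "quality.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$tree, file.path(dir, "tree.nwk"))
  write.table(data.frame(id = names(sim$lineages), lineage = sim$lineages),
              file.path(dir, "lineages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(membership = sim$truth$membership,
         twin = as.list(sim$truth$twin),
         closest_fun = as.list(sim$truth$closest_fun),
         disagree = sim$truth$disagree,
         host_a_species = sim$host_a_species,
         host_b_species = sim$host_b_species),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Self-audit of an emitted catalog directory
#'
#' Re-parses the files written by [write_catalogs()] and checks they are
#' mutually consistent with the recorded truth: every genome has a quality
#' record and a membership entry, every species has a lineage and a tree
#' tip, and annotated genomes exist.
#'
#' @param dir Directory written by [write_catalogs()].
#' @return `TRUE` (invisibly) or an error describing the inconsistency.
#' @export
audit_catalogs <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  quality <- read_quality_tsv(file.path(dir, "quality.tsv"))
  annotations <- read_annotations(file.path(dir, "annotations.tsv"))
  lineages <- read_lineages(file.path(dir, "lineages.tsv"))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  fastas <- list.files(file.path(dir, "genomes"), pattern = "\\.fa$")
  genome_ids <- sub("\\.fa$", "", fastas)
  stopifnot(
    setequal(genome_ids, truth$membership$genome_id),
    setequal(quality$genome_id, truth$membership$genome_id),
    all(annotations$genome_id %in% truth$membership$genome_id),
    setequal(names(lineages),
             c(truth$host_a_species, truth$host_b_species)),
    setequal(tree$tip.label,
             c(truth$host_a_species, truth$host_b_species)))
  invisible(TRUE)
}
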