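mutated_protein <- function(seq, n_subs, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  aa20 <- setdiff(gutbridge:::AA_ALPHABET, "X")
  for (i in sample(length(chars), n_subs)) {
    chars[i] <- sample(setdiff(aa20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

test_that("local alignment handles identity and single substitutions", {
  set.seed(61)
  q <- random_aa(20)
  self <- local_align(q, q)
  expect_equal(self$identity, 100)
  expect_equal(self$aln_length, 20)
  expect_equal(self$matches, 20)
  one_off <- mutated_protein(q, 1, seed = 62)
  aln <- local_align(q, one_off)
  expect_equal(aln$identity, 95)
  expect_error(local_align(q, "MK1VL"), "illegal")
  expect_error(local_align("", q), "non-empty")
})

test_that("alignment scores and identities equal the full-DP oracle", {
  set.seed(63)
  for (case in 1:25) {
    q <- random_aa(60)
    t <- switch(case %% 3 + 1,
                mutated_protein(q, sample(1:20, 1), seed = 100 + case),
                random_aa(60),
                paste0(random_aa(10), substr(q, 11, 50), random_aa(10)))
    mine <- local_align(q, t)
    orc <- oracle_sw(q, t)
    expect_equal(mine$score, orc$score)
    expect_equal(mine$matches, orc$matches)
    expect_equal(mine$aln_length, orc$aln_length)
    expect_equal(mine$identity, orc$identity)
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(64)
  for (case in 1:5) {
    q <- random_aa(50)
    t <- mutated_protein(q, 5, seed = 200 + case)
    mine <- local_align(q, t)
    ref <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 11, gapExtension = 1)
    expect_equal(mine$score, Biostrings::score(ref))
  }
})

test_that("alignment identity is symmetric in query and target", {
  set.seed(65)
  for (case in 1:10) {
    a <- random_aa(40)
    b <- mutated_protein(a, sample(1:15, 1), seed = 300 + case)
    expect_equal(local_align(a, b)$identity, local_align(b, a)$identity)
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

planted_catalog <- function(seed) {
  set.seed(seed)
  q <- random_aa(120)
  near <- mutated_protein(q, 5, seed + 1)   # ~95.8% identity
  mid <- mutated_protein(q, 48, seed + 2)   # ~60% identity
  noise <- random_aa(120)
  list(query = list(protein_id = "query", sequence = q),
       catalog = data.frame(
         protein_id = c("near", "mid", "noise"),
         genome_id = c("gA", "gB", "gC"),
         sequence = c(near, mid, noise), stringsAsFactors = FALSE))
}

test_that("catalog search partitions planted homologs by identity cutoff", {
  pc <- planted_catalog(71)
  hits95 <- search_catalog(pc$query, pc$catalog, min_identity = 95)
  expect_equal(hits95$target_id, "near")
  hits50 <- search_catalog(pc$query, pc$catalog, min_identity = 50)
  expect_setequal(hits50$target_id, c("near", "mid"))
  # ranking: identity descending
  expect_equal(hits50$target_id[1], "near")
  # the query itself is always the top hit
  with_self <- rbind(pc$catalog,
                     data.frame(protein_id = "self", genome_id = "gQ",
                                sequence = pc$query$sequence))
  top <- search_catalog(pc$query, with_self, min_identity = 95)
  expect_equal(top$target_id[1], "self")
  expect_equal(top$identity[1], 100)
})

test_that("the 5-mer prefilter is lossless against brute-force alignment", {
  set.seed(73)
  for (case in 1:8) {
    pc <- planted_catalog(400 + case)
    pre <- search_catalog(pc$query, pc$catalog, min_identity = 95)
    # brute force: align everything with the oracle, apply the same cutoffs
    brute <- Filter(Negate(is.null), lapply(seq_len(nrow(pc$catalog)), function(i) {
      orc <- oracle_sw(pc$query$sequence, pc$catalog$sequence[i])
      if (orc$identity >= 95 &&
          orc$aln_length >= 0.5 * nchar(pc$query$sequence)) {
        pc$catalog$protein_id[i]
      }
    }))
    expect_setequal(pre$target_id, unlist(brute))
  }
})

test_that("dominant species ranks by distinct encoding genomes", {
  clusters <- data.frame(
    cluster_id = rep(c("spA", "spB"), c(10, 5)),
    genome_id = c(sprintf("ga%02d", 1:10), sprintf("gb%02d", 1:5)))
  genome_of <- setNames(c(sprintf("ga%02d", 1:8), "ga01", sprintf("gb%02d", 1:3)),
                        sprintf("p%02d", 1:12))
  hits <- data.frame(query_id = "q", target_id = sprintf("p%02d", 1:12),
                     identity = 99, aln_length = 100, matches = 99,
                     score = 500, stringsAsFactors = FALSE)
  rank <- dominant_species(hits, genome_of, clusters)
  expect_equal(rank$species_id, c("spA", "spB"))
  expect_equal(rank$n_encoding, c(8L, 3L))   # distinct genomes, not hits
  expect_equal(rank$fraction, c(0.8, 0.6))
  expect_equal(nrow(dominant_species(hits[0, ], genome_of, clusters)), 0)
  bad <- hits; bad$target_id[1] <- "unknown"
  expect_error(dominant_species(bad, genome_of, clusters), "not resolvable")
})

test_that("gene sharing categories follow dominant-species pairing", {
  shared <- data.frame(id_a = c("hA", "hB"), id_b = c("mA", "mB"))
  rank_a <- data.frame(species_id = c("hA", "hB"), n_encoding = c(9, 2))
  same <- data.frame(species_id = c("mA", "mB"), n_encoding = c(7, 1))
  moved <- data.frame(species_id = c("mB", "mA"), n_encoding = c(7, 1))
  expect_equal(classify_gene_sharing("g1", rank_a, same, shared)$category,
               "SHARED_CONSERVED_LOCATION")
  expect_equal(classify_gene_sharing("g2", rank_a, moved, shared)$category,
               "SHARED_DIFFERENT_LOCATION")
  off <- classify_gene_sharing("g3", rank_a, same[0, ], shared)
  expect_equal(off$category, "NOT_SHARED")
  expect_true(is.na(off$dominant_host_b))
})

test_that("planted gene-sharing categories are recovered in proportion", {
  set.seed(77)
  shared <- data.frame(id_a = sprintf("h%02d", 1:6),
                       id_b = sprintf("m%02d", 1:6))
  planted <- rep(c("SHARED_CONSERVED_LOCATION", "SHARED_DIFFERENT_LOCATION",
                   "NOT_SHARED"), times = c(17, 10, 7))   # 34 genes
  calls <- vapply(seq_along(planted), function(i) {
    a_top <- sample(shared$id_a, 1)
    rank_a <- data.frame(species_id = a_top, n_encoding = 5)
    rank_b <- switch(planted[i],
      SHARED_CONSERVED_LOCATION =
        data.frame(species_id = shared$id_b[shared$id_a == a_top],
                   n_encoding = 4),
      SHARED_DIFFERENT_LOCATION =
        data.frame(species_id = sample(setdiff(shared$id_b,
                     shared$id_b[shared$id_a == a_top]), 1), n_encoding = 4),
      NOT_SHARED = data.frame(species_id = character(0),
                              n_encoding = integer(0)))
    classify_gene_sharing(sprintf("gene%02d", i), rank_a, rank_b,
                          shared)$category
  }, "")
  expect_equal(as.vector(table(calls)[unique(planted)]),
               as.vector(table(planted)[unique(planted)]))
  expect_equal(calls, planted)
})

test_that("protein FASTA reader extracts genome ids", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 genome_id=gA other=1", "MKVLAT",
               ">p2 genome_id=gB", "MKWLAT"), path)
  prot <- read_protein_fasta(path)
  expect_equal(prot$protein_id, c("p1", "p2"))
  expect_equal(prot$genome_id, c("gA", "gB"))
  prot2 <- read_protein_fasta(path, genome_map = c(p1 = "x", p2 = "y"))
  expect_equal(prot2$genome_id, c("x", "y"))
})
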