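lin <- function(genus = "G", species = "S x", family = "F", phylum = "P") {
  sprintf("d__Bacteria;p__%s;c__C;o__O;f__%s;g__%s;s__%s",
          phylum, family, genus, species)
}

test_that("lineage parsing and shared rank follow GTDB conventions", {
  parsed <- parse_lineage(lin())
  expect_equal(unname(parsed["GENUS"]), "G")
  expect_equal(unname(parsed["DOMAIN"]), "Bacteria")
  expect_error(parse_lineage("d__A;p__B"), "malformed")
  expect_equal(shared_rank(lin(), lin()), "SPECIES")
  expect_equal(shared_rank(lin(species = "S y"), lin(species = "S z")), "GENUS")
  expect_equal(shared_rank(lin(genus = "G1", species = ""),
                           lin(genus = "G2", species = "")), "FAMILY")
  # unassigned (empty) labels never match
  expect_equal(shared_rank(lin(species = ""), lin(species = "")), "GENUS")
})

test_that("binary and weighted functional distances behave as Jaccard", {
  p <- c(a = 0.5, b = 1, c = 0.2)
  expect_equal(functional_distance(p, p), 0)
  expect_equal(functional_distance(c(a = 1, b = 1), c(x = 1, y = 1)), 1)
  # {a,b,c} vs {b,c,d} -> 1 - 2/4
  expect_equal(functional_distance(c(a = 1, b = 1, c = 1),
                                   c(b = 1, c = 1, d = 1)), 0.5)
  expect_equal(functional_distance(numeric(0), numeric(0)), 0)
  expect_error(functional_distance(c(a = -0.1), c(a = 1)), "negative")
  # weighted (Ruzicka) on real-valued fractions
  expect_equal(functional_distance(c(a = 0.5, b = 1), c(a = 1, b = 0.5),
                                   mode = "WEIGHTED"), 1 - 1 / 2)
})

test_that("binary Jaccard distance satisfies the triangle inequality", {
  set.seed(31)
  feats <- letters[1:15]
  for (rep in 1:40) {
    prof <- lapply(1:3, function(i) {
      setNames(as.numeric(runif(15) < 0.5), feats)
    })
    dab <- functional_distance(prof[[1]], prof[[2]])
    dbc <- functional_distance(prof[[2]], prof[[3]])
    dac <- functional_distance(prof[[1]], prof[[3]])
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("cophenetic distances are exact path sums", {
  d <- cophenetic_distances("((A:1,B:1):1,C:2);")
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))
  expect_equal(d, t(d))
  # random 20-leaf tree against the brute-force path-walking oracle
  set.seed(12)
  phy <- ape::rtree(20)
  mine <- cophenetic_distances(phy)
  orc <- oracle_cophenetic(phy)
  expect_equal(mine[rownames(orc), colnames(orc)], orc, tolerance = 1e-12)
  expect_error(cophenetic_distances("((A:1,A:1):1,C:2);"), "duplicate")
  expect_warning(cophenetic_distances("((A,B),C);"), "branch lengths")
})

test_that("neighbor assignment finds taxonomic and functional argmins", {
  ids <- c("qa", "twin", "other")
  tax <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, dimnames = list(ids, ids))
  fun <- tax
  linmap <- c(qa = lin(), twin = lin(), other = lin(genus = "H", species = "H z"))
  asg <- assign_neighbors("qa", c("twin", "other"), tax, fun, linmap)
  expect_equal(asg$closest_tax, "twin")
  expect_equal(asg$closest_fun, "twin")
  expect_equal(asg$shared_rank, "SPECIES")
  expect_true(asg$agree)
  # single host-B species is both neighbors
  asg1 <- assign_neighbors("qa", "other", tax, fun, linmap)
  expect_equal(asg1$closest_tax, "other")
  expect_equal(asg1$closest_fun, "other")
  expect_error(assign_neighbors("qa", "missing", tax, fun, linmap), "missing")
})

test_that("planted cross-host disagreements are recovered exactly", {
  for (seed in c(5, 23)) {
    cfg <- sim_config(seed = seed, n_species_a = 30, genomes_per_species = 2,
                      genome_length = 3000, planted_disagreement_rate = 0.1)
    sim <- simulate_catalogs(cfg)
    clusters <- data.frame(cluster_id = sim$truth$membership$species_id,
                           genome_id = sim$truth$membership$genome_id)
    fm <- build_feature_matrix(sim$annotations, clusters)
    fun <- functional_distance_matrix(fm)
    tax <- cophenetic_distances(sim$tree)
    asg <- assign_neighbors(sim$host_a_species, sim$host_b_species, tax, fun,
                            sim$lineages)
    expect_setequal(asg$query_species[!asg$agree], sim$truth$disagree)
    expect_equal(asg$closest_fun,
                 unname(sim$truth$closest_fun[asg$query_species]))
    expect_equal(asg$closest_tax, unname(sim$truth$twin[asg$query_species]))
  }
})

test_that("agreement table conserves totals and rounds to one decimal", {
  asg <- data.frame(
    query_species = sprintf("q%03d", 1:103),
    closest_tax = "x", closest_fun = "x",
    shared_rank = "SPECIES",
    tax_distance = 0, fun_distance = 0,
    agree = c(rep(TRUE, 102), FALSE), stringsAsFactors = FALSE)
  tab <- agreement_by_rank(asg)
  sp <- tab[tab$rank == "SPECIES", ]
  expect_equal(sp$n, 103)
  expect_equal(sp$percent_agree, 99.0)
  # all-agree case: 100 in every occupied stratum
  asg$agree <- TRUE
  asg$shared_rank <- rep(c("SPECIES", "GENUS"), length.out = 103)
  tab2 <- agreement_by_rank(asg)
  expect_true(all(tab2$percent_agree == 100))
  # strata sum to the total
  expect_equal(sum(tab2$n[tab2$rank != "OVERALL"]),
               tab2$n[tab2$rank == "OVERALL"])
})

test_that("mantel matches exhaustive enumeration and detects self-identity", {
  set.seed(41)
  a <- random_symmetric_distance(5)
  b <- random_symmetric_distance(5)
  exact <- mantel(a, b, exact = TRUE)
  orc <- oracle_mantel_exact(a, b)
  expect_equal(exact$r, orc$r)
  expect_equal(exact$p, orc$p)
  expect_equal(exact$n_perm, 120)
  # identical matrices: r = 1, minimal p
  res <- mantel(a, a, n_perm = 99, seed = 7)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  # positive affine transforms leave r = 1
  res2 <- mantel(a, 0.3 + 2 * a - diag(diag(0.3 + 2 * a)), n_perm = 9, seed = 1)
  expect_equal(res2$r, 1)
  expect_error(mantel(a, b[c(2, 1, 3, 4, 5), c(2, 1, 3, 4, 5)]), "same order")
  # seeded: reproducible
  expect_equal(mantel(a, b, n_perm = 49, seed = 3)$p,
               mantel(a, b, n_perm = 49, seed = 3)$p)
})

test_that("mantel p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(200, {
    a <- random_symmetric_distance(7)
    b <- random_symmetric_distance(7)
    mantel(a, b, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pcoa reproduces Euclidean configurations", {
  # three equidistant points embed exactly in the plane
  ids <- c("a", "b", "c")
  d3 <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(d3) <- 0
  pc3 <- pcoa(d3, 2)
  expect_equal(as.matrix(dist(pc3$coordinates)), d3, tolerance = 1e-9,
               ignore_attr = TRUE)
  # planar points are recovered up to rigid motion: distances match
  set.seed(17)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("p", 1:12), NULL))
  d <- as.matrix(dist(pts))
  pc <- pcoa(d, 2)
  expect_lt(max(abs(as.matrix(dist(pc$coordinates)) - d)), 1e-6)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_true(all(pc$explained >= 0 & pc$explained <= 1))
  expect_equal(sum(pc$explained), 1)
})

test_that("shared species pair by label or by ANI, one partner each", {
  pair <- simulate_genome_pair(3e4, 0.005, seed = 2)   # ~0.5% divergence
  ska <- sketch_sequences(pair$seq_a, "ha1")
  skb <- sketch_sequences(pair$seq_b, "mb1")
  far <- sketch_sequences(simulate_genome_pair(3e4, 0.1, seed = 3)$seq_b, "mb2")
  unl <- lin(species = "")
  # unlabeled close pair matches by the ANI rule
  sh <- shared_species(list(ha1 = ska), c(ha1 = unl),
                       list(mb1 = skb, mb2 = far), c(mb1 = unl, mb2 = unl))
  expect_equal(sh$id_b, "mb1")
  expect_false(sh$by_label)
  expect_gte(sh$ani, 95)
  # identical species label matches regardless of distance
  lab <- lin(species = "G shared")
  sh2 <- shared_species(list(ha1 = far), c(ha1 = lab),
                        list(mb2 = ska), c(mb2 = lab))
  expect_true(sh2$by_label)
  # 10% divergence, no label: unmatched
  sh3 <- shared_species(list(ha1 = ska), c(ha1 = unl),
                        list(mb2 = far), c(mb2 = unl))
  expect_equal(nrow(sh3), 0)
  expect_error(shared_species(list(a = ska, a = ska), c(a = unl, a = unl),
                              list(mb1 = skb), c(mb1 = unl)), "duplicate")
})

test_that("catalog summaries reproduce printed percentages from counts", {
  s <- catalog_summary(n_species_total = 1094, n_cultured = 253,
                       n_novel_cultured = 62)
  expect_equal(s$pct_cultured, 23.1)
  expect_equal(s$pct_novel_contribution, 24.5)
  expect_equal(s$pct_diversity_increase, 32.5)
  s2 <- catalog_summary(n_shared = 103, n_combined = 3997)
  expect_equal(s2$pct_shared, 2.58)
  s3 <- catalog_summary(n_shared = 670, n_combined = 805)
  expect_equal(s3$pct_shared, 83.23)
  expect_error(catalog_summary(n_cultured = 5, n_novel_cultured = 6), "exceeds")
  expect_error(catalog_summary(n_species_total = 0, n_cultured = 0), "zero")
})

test_that("distance matrices validate and serialize", {
  set.seed(2)
  m <- random_symmetric_distance(4)
  expect_silent(as_distance_matrix(m))
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(as_distance_matrix(bad), "symmetric")
  neg <- m; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(as_distance_matrix(neg), "finite")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(m, path)
  expect_equal(read_distance_tsv(path), m, tolerance = 1e-12)
})
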