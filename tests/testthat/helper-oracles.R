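# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exact k-mer sets by string enumeration, full
# dynamic-programming Smith-Waterman without any prefilter, cophenetic
# distances by per-pair path walking, Mantel p-values by exhaustive
# permutation.

# exact canonical k-mer set of a sequence, by enumeration
oracle_canonical_kmers <- function(seq, k = 21) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- substring(seq, 1:(n - k + 1), k:n)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  # revcomp of the k-mer starting at i is the k-mer of rc starting at n-i-k+2
  idx <- n - seq_len(n - k + 1) - k + 2
  rev_k <- substring(rc, idx, idx + k - 1)
  unique(pmin(fwd, rev_k))
}

oracle_exact_jaccard <- function(seq_a, seq_b, k = 21) {
  A <- oracle_canonical_kmers(seq_a, k)
  B <- oracle_canonical_kmers(seq_b, k)
  length(intersect(A, B)) / length(union(A, B))
}

oracle_mash_from_jaccard <- function(j, k = 21) {
  if (j <= 0) return(1)
  min(max(-log(2 * j / (1 + j)) / k, 0), 1)
}

# full-DP Smith-Waterman (Gotoh affine), no prefilter; same documented
# conventions as the implementation: gap of length L costs open + L*extend,
# ties diagonal > up > left, identity over all alignment columns.
oracle_sw <- function(query, target, gap_open = 11, gap_extend = 1) {
  sub <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  m <- length(qc); n <- length(tc)
  go <- gap_open + gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - go, E[i - 1, j] - gap_extend)
      F[i, j] <- max(H[i, j - 1] - go, F[i, j - 1] - gap_extend)
      diag <- H[i - 1, j - 1] + sub[qc[i - 1], tc[j - 1]]
      H[i, j] <- max(0, diag, E[i, j], F[i, j])
    }
  }
  best <- max(H)
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[1]; j <- hit[2]
  matches <- 0L; cols <- 0L; state <- "H"
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] <= 0 || i == 1 || j == 1) break
      diag <- H[i - 1, j - 1] + sub[qc[i - 1], tc[j - 1]]
      if (H[i, j] == diag) {
        cols <- cols + 1L
        if (qc[i - 1] == tc[j - 1]) matches <- matches + 1L
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == E[i, j]) state <- "E" else state <- "F"
    } else if (state == "E") {
      cols <- cols + 1L
      close <- E[i, j] == H[i - 1, j] - go
      i <- i - 1
      if (close) state <- "H"
    } else {
      cols <- cols + 1L
      close <- F[i, j] == H[i, j - 1] - go
      j <- j - 1
      if (close) state <- "H"
    }
  }
  list(score = best, matches = matches, aln_length = cols,
       identity = if (cols > 0) 100 * matches / cols else 0)
}

# cophenetic distance by explicit root-path walking on an ape tree
oracle_cophenetic <- function(phy) {
  ntip <- length(phy$tip.label)
  parent <- integer(max(phy$edge)); elen <- numeric(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- phy$edge.length
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) { node <- parent[node]; nodes <- c(nodes, node) }
    nodes
  }
  depth <- function(node) {
    d <- 0
    while (node != root) { d <- d + elen[node]; node <- parent[node] }
    d
  }
  out <- matrix(0, ntip, ntip,
                dimnames = list(phy$tip.label, phy$tip.label))
  for (a in seq_len(ntip)) {
    pa <- path_to_root(a)
    for (b in seq_len(a - 1)) {
      pb <- path_to_root(b)
      lca <- intersect(pa, pb)[1]
      out[a, b] <- out[b, a] <- depth(a) + depth(b) - 2 * depth(lca)
    }
  }
  out
}

# exhaustive-permutation Mantel p-value (one-sided greater), identity included
oracle_mantel_exact <- function(a, b) {
  n <- nrow(a)
  ut <- upper.tri(a)
  robs <- cor(a[ut], b[ut])
  perms <- gtools_permutations(n)
  rs <- vapply(perms, function(p) cor(a[ut], b[p, p][ut]), 0)
  list(r = robs, p = sum(rs >= robs - 1e-12) / length(rs))
}

gtools_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in gtools_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(sub, n, after = pos)
  }
  out
}

random_aa <- function(n) {
  paste(sample(setdiff(c("A","C","D","E","F","G","H","I","K","L","M","N",
                         "P","Q","R","S","T","V","W","Y"), NULL), n,
               replace = TRUE), collapse = "")
}

random_symmetric_distance <- function(n, ids = paste0("s", seq_len(n))) {
  m <- matrix(runif(n * n), n)
  m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}
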