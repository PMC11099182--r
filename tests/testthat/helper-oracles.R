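# Independent reference implementations used to cross-check the package.

# Agglomerative clustering via Lance-Williams updates on a shrinking
# distance matrix (the package recomputes cluster distances from the
# original pair matrix instead). Same declared tie rule: clusters ordered
# by smallest member, ties merge the smallest (i, j). Strict cutoff.
oracle_agglomerate <- function(d, cutoff, linkage = "complete") {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  dm <- d
  diag(dm) <- Inf
  repeat {
    k <- length(members)
    if (k < 2) break
    best_d <- Inf; best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (dm[i, j] < best_d - 1e-12) { best_d <- dm[i, j]; best <- c(i, j) }
    }
    if (best_d >= cutoff) break
    i <- best[1]; j <- best[2]
    upd <- if (linkage == "complete") pmax(dm[i, ], dm[j, ])
           else pmin(dm[i, ], dm[j, ])
    dm[i, ] <- upd; dm[, i] <- upd; dm[i, i] <- Inf
    dm <- dm[-j, -j, drop = FALSE]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    members[[j]] <- NULL
    ord <- order(vapply(members, min, 0L))
    members <- members[ord]
    dm <- dm[ord, ord, drop = FALSE]
  }
  members
}

# Brute-force weighted KS running-sum walk over the full ranked list.
oracle_es <- function(genes_ranked, scores_ranked, gene_set, w = 1) {
  member <- genes_ranked %in% gene_set
  N <- length(genes_ranked); k <- sum(member)
  aw <- abs(scores_ranked)^w
  S <- sum(aw[member])
  incr <- numeric(N)
  if (S == 0) incr[member] <- 1 / k else incr[member] <- aw[member] / S
  incr[!member] <- -1 / (N - k)
  running <- cumsum(incr)
  best_pos <- max(0, running)
  best_neg <- min(0, running)
  if (best_pos >= -best_neg) best_pos else best_neg
}

# Brute-force all-pairs public-clone scan (no length bucketing).
oracle_match_public <- function(pairs, reference, threshold = 0.8,
                                mode = "joint") {
  hits <- character(0)
  for (i in seq_len(nrow(pairs))) for (r in seq_len(nrow(reference))) {
    qh <- pairs$heavy_junction[i]; ql <- pairs$light_junction[i]
    rh <- reference$heavy_junction[r]; rl <- reference$light_junction[r]
    if (nchar(qh) != nchar(rh) || nchar(ql) != nchar(rl)) next
    mh <- sum(strsplit(qh, "")[[1]] == strsplit(rh, "")[[1]])
    ml <- sum(strsplit(ql, "")[[1]] == strsplit(rl, "")[[1]])
    ok <- if (mode == "joint") (mh + ml) / (nchar(qh) + nchar(ql)) >= threshold
          else mh / nchar(qh) >= threshold && ml / nchar(ql) >= threshold
    if (ok) hits <- c(hits, paste(pairs$cell_id[i], reference$reference_id[r]))
  }
  sort(hits)
}

# Adjusted Rand index between two labellings of the same cells.
adjusted_rand_index <- function(a, b) {
  r <- mclust::adjustedRandIndex(as.character(a), as.character(b))
  if (is.nan(r)) {
    # degenerate case (single cluster or all singletons on both sides):
    # 1 iff the two partitions are identical up to relabelling
    tab <- table(a, b)
    r <- if (all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)) 1 else 0
  }
  r
}

# Minimal synthetic pairs table for clustering tests: one candidate group.
make_group_pairs <- function(heavy, light, donor = "D01") {
  n <- length(heavy)
  data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    donor = donor,
    heavy_v_call = "VH1", heavy_j_call = "JH1",
    light_v_call = "VK1", light_j_call = "JK1",
    heavy_junction = heavy, light_junction = light,
    stringsAsFactors = FALSE)
}

# Random nucleotide string and controlled mutation helpers.
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
mutate_nt <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
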