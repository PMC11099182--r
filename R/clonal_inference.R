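#' Nucleotide identity between two equal-length CDR3 sequences
#'
#' Fraction of matching positions: `1 - normalised Hamming distance`.
#' Callers must pre-group candidates by CDR3 length; unequal lengths are an
#' error, not identity 0, because the clonal-family rule only compares
#' length-matched junctions.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Identity in `[0, 1]`.
#' @export
cdr3_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("CDR3 lengths differ (", nchar(a), " vs ", nchar(b),
         "); group candidates by length before comparing")
  }
  if (nchar(a) == 0) stop("empty CDR3")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Parameters of the clonal-family definition
#'
#' A clonal family is a set of cells from one donor sharing heavy and light
#' V/J genes and CDR3 lengths, whose CDR3 identity exceeds
#' `identity_threshold` (strict `>`, i.e. Hamming distance strictly below
#' `1 - identity_threshold`) between members. In `per_chain` mode the rule
#' must hold on each chain independently (pair distance = max over chains);
#' in `joint` mode mismatches are pooled over both CDR3s. With complete
#' linkage every intra-family pair must satisfy the rule; single linkage
#' only chains of passing pairs.
#'
#' @param identity_threshold Identity that must be exceeded (default 0.8).
#' @param chain_mode `"per_chain"` (default) or `"joint"`.
#' @param linkage `"complete"` (default) or `"single"`.
#' @param use_germline_key If `TRUE`, cells must additionally share their
#'   reconstructed gapped germline FR1-FR3 strings (heavy and light) to be
#'   grouped; off by default, where V/J + donor + CDR3 length already key
#'   the germline on allele-free segment libraries.
#' @return A list of class `clonal_params`.
#' @export
clonal_params <- function(identity_threshold = 0.8,
                          chain_mode = c("per_chain", "joint"),
                          linkage = c("complete", "single"),
                          use_germline_key = FALSE) {
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    stop("identity_threshold must be in (0, 1)")
  }
  structure(list(identity_threshold = identity_threshold,
                 chain_mode = match.arg(chain_mode),
                 linkage = match.arg(linkage),
                 use_germline_key = use_germline_key),
            class = "clonal_params")
}

# pairwise chain-aware CDR3 distance matrix for one candidate group
.pair_distance_matrix <- function(h, l, chain_mode) {
  n <- length(h)
  hm <- do.call(rbind, strsplit(h, ""))
  lm <- do.call(rbind, strsplit(l, ""))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mmh <- sum(hm[i, ] != hm[j, ])
    mml <- sum(lm[i, ] != lm[j, ])
    d[i, j] <- d[j, i] <- if (chain_mode == "per_chain") {
      max(mmh / ncol(hm), mml / ncol(lm))
    } else {
      (mmh + mml) / (ncol(hm) + ncol(lm))
    }
  }
  d
}

# deterministic agglomeration with a strict merge cutoff.
# clusters are kept ordered by their smallest member index (input is sorted
# by cell_id); ties in linkage distance merge the lexicographically smallest
# (i, j) cluster pair. 'cutoff' is exclusive: merge only while dist < cutoff.
.agglomerate <- function(d, cutoff, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sub <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      dij <- if (linkage == "complete") max(sub) else min(sub)
      if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
    }
    if (is.null(best) || best_d >= cutoff) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    clusters[[best[1]]] <- merged
    clusters <- clusters[order(vapply(clusters, min, 0L))]
  }
  clusters
}

#' Partition cells into clonal families
#'
#' Cells are first grouped by donor, heavy and light V/J calls and CDR3
#' lengths (and, if enabled, reconstructed germline FR strings); within each
#' candidate group, deterministic agglomerative clustering under the
#' configured linkage merges clusters while their chain-aware CDR3 distance
#' is strictly below `1 - identity_threshold`. Cells are sorted by
#' identifier before clustering, so the result is invariant to input order.
#'
#' @param pairs `pairs` data.frame from [select_contigs()]; must carry a
#'   `donor` column.
#' @param params A [clonal_params()] object.
#' @return A `clonal_partition`: list with `family_of_cell` (named character
#'   vector), `families` (named list of member cell ids), `params`.
#' @export
partition_families <- function(pairs, params = clonal_params()) {
  stopifnot(inherits(params, "clonal_params"))
  if (!"donor" %in% names(pairs) || anyNA(pairs$donor)) {
    stop("every cell needs a donor label")
  }
  pairs <- pairs[order(pairs$cell_id), , drop = FALSE]
  key <- paste(pairs$donor, pairs$heavy_v_call, pairs$heavy_j_call,
               pairs$light_v_call, pairs$light_j_call,
               nchar(pairs$heavy_junction), nchar(pairs$light_junction),
               sep = "|")
  if (params$use_germline_key) {
    gh <- vapply(seq_len(nrow(pairs)), function(i) reconstruct_germline(list(
      sequence_alignment = pairs$heavy_sequence_alignment[i],
      mutation_events = pairs$heavy_mutation_events[i],
      region_spans = pairs$heavy_region_spans[i])), "")
    gl <- vapply(seq_len(nrow(pairs)), function(i) reconstruct_germline(list(
      sequence_alignment = pairs$light_sequence_alignment[i],
      mutation_events = pairs$light_mutation_events[i],
      region_spans = pairs$light_region_spans[i])), "")
    key <- paste(key, gh, gl, sep = "|")
  }

  cutoff <- 1 - params$identity_threshold
  fam <- character(nrow(pairs))
  names(fam) <- pairs$cell_id
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) == 1) {
      fam[idx] <- paste0(g, "#1")
      next
    }
    d <- .pair_distance_matrix(pairs$heavy_junction[idx],
                               pairs$light_junction[idx],
                               params$chain_mode)
    cl <- .agglomerate(d, cutoff, params$linkage)
    for (ci in seq_along(cl)) fam[idx[cl[[ci]]]] <- paste0(g, "#", ci)
  }
  # stable family ids ordered by smallest member cell id
  first_cell <- tapply(names(fam), fam, min)
  ord <- names(sort(first_cell))
  ids <- stats::setNames(sprintf("F%05d", seq_along(ord)), ord)
  fam <- stats::setNames(unname(ids[fam]), names(fam))
  structure(list(
    family_of_cell = fam,
    families = split(names(fam), fam),
    params = params
  ), class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  cat("Clonal partition:", length(x$family_of_cell), "cells in",
      length(x$families), "families\n")
  cat("  identity threshold >", x$params$identity_threshold,
      "| chain mode:", x$params$chain_mode,
      "| linkage:", x$params$linkage, "\n")
  invisible(x)
}

#' Clonal-family diversity per transcriptional cluster
#'
#' Number of distinct clonal families with at least one member in each
#' cluster. A family spanning several clusters is counted once in each.
#'
#' @param partition A `clonal_partition`.
#' @param clusters Named vector mapping cell id to cluster label; must cover
#'   every cell of the partition.
#' @return Named integer vector of family counts per cluster.
#' @export
family_diversity <- function(partition, clusters) {
  fam <- partition$family_of_cell
  if (!all(names(fam) %in% names(clusters))) {
    stop("clusters must cover every cell in the partition")
  }
  cl <- clusters[names(fam)]
  vapply(split(fam, cl), function(f) length(unique(f)), 0L)
}

#' Simpson diversity of clonal families
#'
#' Probability that two randomly selected cells belong to *different*
#' clonal families (Gini-Simpson form). With replacement (default):
#' `1 - sum(p_i^2)` over family frequencies; without replacement (unbiased):
#' `1 - sum(n_i (n_i - 1)) / (N (N - 1))`.
#'
#' @param families Character vector of family labels for the cells of one
#'   cluster (or a `clonal_partition`, in which case all its cells are
#'   used).
#' @param method `"replacement"` (default) or `"unbiased"`.
#' @return Index in `[0, 1]`.
#' @export
simpson_index <- function(families, method = c("replacement", "unbiased")) {
  method <- match.arg(method)
  if (inherits(families, "clonal_partition")) {
    families <- families$family_of_cell
  }
  n <- length(families)
  if (n == 0) stop("empty cluster")
  counts <- table(families)
  if (method == "replacement") {
    1 - sum((counts / n)^2)
  } else {
    if (n == 1) stop("unbiased Simpson index needs at least two cells")
    1 - sum(counts * (counts - 1)) / (n * (n - 1))
  }
}

#' Shared-family overlap table between clusters
#'
#' Entry (i, j) counts clonal families having at least one member in
#' cluster i and at least one in cluster j; the diagonal is the per-cluster
#' family count of [family_diversity()].
#'
#' @inheritParams family_diversity
#' @return Symmetric integer matrix with cluster labels as dimnames.
#' @export
overlap_table <- function(partition, clusters) {
  fam <- partition$family_of_cell
  cl <- clusters[names(fam)]
  labs <- sort(unique(as.character(cl)))
  fam_levels <- sort(unique(fam))
  inc <- matrix(FALSE, length(fam_levels), length(labs))
  inc[cbind(match(fam, fam_levels), match(as.character(cl), labs))] <- TRUE
  out <- crossprod(inc)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(labs, labs)
  out
}

#' Permutation test for cluster overlap of clonal families
#'
#' Significance of each pairwise overlap is assessed against a null obtained
#' by permuting the clonal-family annotation across cells while keeping the
#' cluster labels fixed (default 1000 permutations). P-values use the
#' add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)`, which never
#' returns zero.
#'
#' @inheritParams family_diversity
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `observed` (overlap matrix) and `p_value` (matrix of
#'   upper-tail permutation p-values; diagonal `NA`).
#' @export
permutation_overlap_test <- function(partition, clusters, n_perm = 1000,
                                     seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- overlap_table(partition, clusters)
  fam <- partition$family_of_cell
  cl <- clusters[names(fam)]
  k <- nrow(obs)
  # integer-coded fast path for the permutation loop
  famf <- as.integer(factor(fam, levels = sort(unique(fam))))
  clf <- as.integer(factor(as.character(cl), levels = rownames(obs)))
  nfam <- max(famf)
  count_ge <- matrix(0L, k, k, dimnames = dimnames(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pf <- sample(famf)
      inc <- matrix(FALSE, nfam, k)
      inc[cbind(pf, clf)] <- TRUE
      pobs <- crossprod(inc)
      count_ge <- count_ge + (pobs >= obs)
    }
  })
  p <- (1 + count_ge) / (1 + n_perm)
  diag(p) <- NA_real_
  list(observed = obs, p_value = p, n_perm = n_perm, seed = seed)
}
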