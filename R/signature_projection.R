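#' Log-normalise UMI counts
#'
#' Per-10k library-size normalisation on the natural log scale:
#' `ln(10000 * UMIsGene / UMIsTotal + 1)`. Zero counts map to 0, so
#' sparsity is preserved and sparse input returns sparse output.
#'
#' @param counts Genes x cells count matrix (`dgCMatrix` or dense) with
#'   dimnames.
#' @return Matrix of the same class and dimnames with log-normalised values.
#' @export
log_normalize <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[which(totals <= 0)[1]]
    stop("cell ", bad, " has zero total UMIs")
  }
  if (inherits(counts, "CsparseMatrix")) {
    out <- counts
    percol <- diff(out@p)
    out@x <- log(1e4 * out@x / rep.int(totals, percol) + 1)
    out
  } else {
    log(sweep(1e4 * counts, 2, totals, "/") + 1)
  }
}

#' Derive a marker-gene signature from labelled cells
#'
#' Scores every gene for its ability to separate a target cell group from
#' the rest of the analysed set: the area under the ROC curve (AUC,
#' rank-based with midranks for ties) and a two-sided Mann-Whitney U test
#' on the log-normalised values, adjusted across genes. Genes with
#' `AUC > auc_min` (strict) and adjusted p `<= alpha` form the signature,
#' ordered by decreasing AUC.
#'
#' The Mann-Whitney p-value uses the normal approximation with the tie
#' correction, appropriate for the group sizes of single-cell data.
#'
#' @param log_mat Log-normalised genes x cells matrix ([log_normalize()]).
#' @param target Logical vector over cells (or a vector of target cell
#'   ids) marking the target group.
#' @param name Signature name.
#' @param auc_min AUC that must be exceeded (default 0.6, strict).
#' @param alpha Adjusted-p cutoff (default 0.05, inclusive).
#' @param adjust Multiple-testing adjustment across genes:
#'   `"bonferroni"` (default) or `"BH"`.
#' @return A `gene_signature`: list with `name`, `genes` (character, AUC
#'   descending) and `stats` (per-gene data.frame: `gene`, `auc`,
#'   `p_value`, `p_adj`, `selected`).
#' @export
derive_signature <- function(log_mat, target, name = "signature",
                             auc_min = 0.6, alpha = 0.05,
                             adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.logical(target)) target <- colnames(log_mat) %in% target
  n1 <- sum(target); n2 <- sum(!target)
  if (n1 < 2 || n2 < 2) stop("both label groups need at least 2 cells")
  n <- n1 + n2
  dense <- as.matrix(log_mat)
  auc <- numeric(nrow(dense)); p <- numeric(nrow(dense))
  for (g in seq_len(nrow(dense))) {
    r <- rank(dense[g, ])
    U <- sum(r[target]) - n1 * (n1 + 1) / 2
    auc[g] <- U / (n1 * n2)
    t_tab <- table(dense[g, ])
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p[g] <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p[g] <- 2 * stats::pnorm(-abs(z))
    }
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  selected <- auc > auc_min & p_adj <= alpha
  stats_df <- data.frame(gene = rownames(dense), auc = auc, p_value = p,
                         p_adj = p_adj, selected = selected,
                         stringsAsFactors = FALSE)
  genes <- stats_df$gene[selected][order(-stats_df$auc[selected])]
  structure(list(name = name, genes = genes, stats = stats_df,
                 auc_min = auc_min, alpha = alpha, adjust = adjust),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$genes), " genes (AUC > ",
      x$auc_min, ", adjusted p <= ", x$alpha, ", ", x$adjust, ")\n",
      sep = "")
  invisible(x)
}

#' Per-cell pre-ranked gene list
#'
#' Ranks all genes for one cell by the difference between the cell's
#' log-normalised value and the mean log-normalised value across all cells
#' of the analysed set, descending; ties are broken by gene identifier so
#' the ranking is deterministic. Averaged over cells, every gene's score
#' is zero by construction.
#'
#' @inheritParams derive_signature
#' @param cell Cell identifier (column of `log_mat`).
#' @param gene_means Optional precomputed `rowMeans(log_mat)`.
#' @return data.frame with `gene` and `score`, sorted by decreasing score.
#' @export
per_cell_rank <- function(log_mat, cell, gene_means = NULL) {
  if (is.null(gene_means)) gene_means <- Matrix::rowMeans(log_mat)
  score <- as.numeric(log_mat[, cell]) - as.numeric(gene_means)
  ord <- order(-score, rownames(log_mat))
  data.frame(gene = rownames(log_mat)[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

# enrichment score from sorted member positions in a ranked list.
# pos: sorted positions (1-based) of the set in the ranking; absr: |score|
# of every ranked gene; m: miss decrement 1/(N - k).
.es_from_positions <- function(pos, absr, w = 1) {
  N <- length(absr); k <- length(pos)
  m <- 1 / (N - k)
  wts <- absr[pos]^w
  S <- sum(wts)
  if (S == 0) { wts <- rep(1, k); S <- k }
  cum <- cumsum(wts) / S
  gap <- (pos - seq_len(k)) * m
  hit <- cum - gap
  before <- hit - wts / S
  es_pos <- max(0, hit)
  es_neg <- min(0, before)
  if (es_pos >= -es_neg) es_pos else es_neg
}

# vectorised version over a k x B matrix of column-sorted positions
.es_from_positions_mat <- function(P, absr, w = 1) {
  N <- length(absr); k <- nrow(P); B <- ncol(P)
  m <- 1 / (N - k)
  W <- matrix(absr[P]^w, k, B)
  S <- colSums(W)
  zero <- S == 0
  if (any(zero)) { W[, zero] <- 1; S[zero] <- k }
  cum <- W
  if (k > 1) for (i in 2:k) cum[i, ] <- cum[i - 1, ] + W[i, ]
  Srep <- rep(S, each = k)
  hit <- cum / matrix(Srep, k, B) - (P - seq_len(k)) * m
  before <- hit - W / matrix(Srep, k, B)
  es_pos <- rep(0, B); es_neg <- rep(0, B)
  for (i in seq_len(k)) {
    es_pos <- pmax(es_pos, hit[i, ])
    es_neg <- pmin(es_neg, before[i, ])
  }
  ifelse(es_pos >= -es_neg, es_pos, es_neg)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic pre-ranked GSEA statistic: walking down the ranked list, the
#' running sum increases by `|score|^w / sum(|score|^w over members)` at
#' member genes and decreases by `1 / (N - |set|)` at non-members; the ES is
#' the signed maximum deviation from zero (ties between the positive and
#' negative extreme resolve to the positive one). ES lies in `[-1, 1]`.
#'
#' @param ranked data.frame from [per_cell_rank()] (columns `gene`,
#'   `score`, already sorted), or a named sorted score vector.
#' @param gene_set Character vector of member genes; silently filtered to
#'   genes present in the ranking.
#' @param weight_exponent Weight `w` on `|score|` (default 1).
#' @param min_set_size Sets smaller than this after filtering are skipped
#'   with a warning (`NA` returned).
#' @return The enrichment score, or `NA` for a skipped set.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1,
                             min_set_size = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene; scores <- ranked$score
  } else {
    genes <- names(ranked); scores <- unname(ranked)
  }
  pos <- sort(match(unique(gene_set), genes))
  pos <- pos[!is.na(pos)]
  if (length(pos) < min_set_size || length(pos) == 0) {
    warning("gene set empty or below min_set_size after filtering; skipped")
    return(NA_real_)
  }
  if (length(pos) == length(genes)) {
    stop("gene set covers the entire ranked list")
  }
  .es_from_positions(pos, abs(scores), weight_exponent)
}

#' Per-cell pre-ranked GSEA with a randomisation null
#'
#' Projects gene sets onto single cells: for every cell, genes are ranked
#' by deviation from the population mean ([per_cell_rank()]) and each gene
#' set is scored by [enrichment_score()]. The null distribution per cell
#' and set size is built from `n_perm` random same-size gene sets (drawn
#' once per distinct size from the seeded generator and scored against each
#' cell's ranking). NES is the ES divided by the mean magnitude of
#' same-sign null scores; the nominal p-value is the add-one fraction of
#' same-sign null scores at least as extreme. The FDR q-value follows the
#' NES-based GSEA procedure, computed within each cell across sets and
#' signs (`fdr = "gsea"`), or Benjamini-Hochberg on the nominal p-values
#' (`fdr = "BH"`). A cell x set result is significant when
#' `FDR <= 0.50` and nominal `p < 0.05`.
#'
#' @param log_mat Log-normalised genes x cells matrix.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm Number of random gene sets per size (default 1000).
#' @param seed Integer seed; results are fully reproducible.
#' @param min_set_size Minimum set size after filtering to the matrix
#'   (default 5); smaller sets are dropped with a warning.
#' @param weight_exponent Weight on `|score|` in the running sum (default 1).
#' @param fdr `"gsea"` (default) or `"BH"`.
#' @param fdr_max,p_max Significance rule (defaults 0.50 and 0.05).
#' @return data.frame with one row per cell x gene set: `cell_id`,
#'   `gene_set`, `size`, `es`, `nes`, `p_value`, `fdr`, `significant`.
#' @export
gsea_per_cell <- function(log_mat, gene_sets, n_perm = 1000, seed = 1L,
                          min_set_size = 5, weight_exponent = 1,
                          fdr = c("gsea", "BH"),
                          fdr_max = 0.50, p_max = 0.05) {
  fdr <- match.arg(fdr)
  if (n_perm < 10) stop("n_perm must be >= 10 (estimator degenerate)")
  genes <- rownames(log_mat)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), genes))
  keep <- vapply(sets, length, 0L) >= min_set_size
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " gene set(s) below min_set_size")
  }
  sets <- sets[keep]
  if (length(sets) == 0) stop("no usable gene set")
  if (any(vapply(sets, length, 0L) == length(genes))) {
    stop("a gene set covers all genes in the matrix")
  }
  sizes <- vapply(sets, length, 0L)
  # one null position panel per distinct set size, from the seeded RNG
  null_panels <- withr::with_seed(seed, {
    panels <- list()
    for (k in sort(unique(sizes))) {
      P <- vapply(seq_len(n_perm), function(b)
        sort(sample.int(length(genes), k)), integer(k))
      panels[[as.character(k)]] <- matrix(P, nrow = k)
    }
    panels
  })

  gene_means <- Matrix::rowMeans(log_mat)
  cells <- colnames(log_mat)
  dense <- as.matrix(log_mat)
  out <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    score <- dense[, ci] - gene_means
    ord <- order(-score, genes)
    genes_ranked <- genes[ord]
    absr <- abs(score[ord])
    null_es <- lapply(null_panels, .es_from_positions_mat, absr = absr,
                      w = weight_exponent)
    es <- vapply(sets, function(s)
      .es_from_positions(sort(match(s, genes_ranked)), absr,
                         weight_exponent), 0)
    nes <- numeric(length(es)); pval <- numeric(length(es))
    null_nes <- list()
    for (si in seq_along(sets)) {
      nul <- null_es[[as.character(sizes[si])]]
      npos <- nul[nul > 0]; nneg <- nul[nul < 0]
      mpos <- if (length(npos)) mean(npos) else NA_real_
      mneg <- if (length(nneg)) mean(abs(nneg)) else NA_real_
      null_nes[[si]] <- c(if (length(npos)) npos / mpos,
                          if (length(nneg)) nneg / mneg)
      if (es[si] > 0) {
        nes[si] <- if (is.na(mpos)) 0 else es[si] / mpos
        pval[si] <- (1 + sum(npos >= es[si])) / (1 + length(npos))
      } else if (es[si] < 0) {
        nes[si] <- if (is.na(mneg)) 0 else es[si] / mneg
        pval[si] <- (1 + sum(nneg <= es[si])) / (1 + length(nneg))
      } else {
        nes[si] <- 0; pval[si] <- 1
      }
    }
    q <- if (fdr == "BH") {
      stats::p.adjust(pval, method = "BH")
    } else {
      .gsea_fdr(nes, unlist(null_nes))
    }
    out[[ci]] <- data.frame(
      cell_id = cells[ci], gene_set = names(sets), size = sizes,
      es = es, nes = nes, p_value = pval, fdr = q,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$significant <- res$fdr <= fdr_max & res$p_value < p_max
  rownames(res) <- NULL
  res
}

# NES-based FDR of the cited GSEA procedure, within one cell across sets
# and signs: q(NES*) compares the fraction of pooled null NES at least as
# extreme (same sign) with the fraction of observed NES at least as extreme.
.gsea_fdr <- function(obs_nes, null_nes) {
  q <- rep(NA_real_, length(obs_nes))
  for (i in seq_along(obs_nes)) {
    s <- obs_nes[i]
    if (s > 0) {
      denom_null <- sum(null_nes > 0)
      num <- if (denom_null) sum(null_nes >= s) / denom_null else 0
      denom_obs <- sum(obs_nes >= s) / max(1, sum(obs_nes > 0))
    } else if (s < 0) {
      denom_null <- sum(null_nes < 0)
      num <- if (denom_null) sum(null_nes <= s) / denom_null else 0
      denom_obs <- sum(obs_nes <= s) / max(1, sum(obs_nes < 0))
    } else {
      q[i] <- 1; next
    }
    q[i] <- if (denom_obs > 0) min(1, num / denom_obs) else 1
  }
  q
}

#' Summarise per-cell enrichment by cluster
#'
#' For each cluster and gene set: the fraction of cells significantly
#' enriched with positive NES, and the quartiles of the positive NES among
#' those cells; plus two-sided Mann-Whitney comparisons of the positive
#' significant NES between every cluster pair.
#'
#' @param results data.frame from [gsea_per_cell()].
#' @param clusters Named vector mapping cell id to cluster label.
#' @return List with `summary` (cluster x set rows: `n_cells`,
#'   `frac_significant_pos`, `nes_q1`, `nes_median`, `nes_q3`) and `tests`
#'   (pairwise rows: `gene_set`, `cluster_a`, `cluster_b`, `p_value`).
#' @export
summarize_clusters <- function(results, clusters) {
  if (!all(results$cell_id %in% names(clusters))) {
    stop("clusters must label every cell in the results")
  }
  results$cluster <- as.character(clusters[results$cell_id])
  labs <- sort(unique(results$cluster))
  summ <- list(); tests <- list()
  for (gs in unique(results$gene_set)) {
    rs <- results[results$gene_set == gs, ]
    pos_nes <- list()
    for (cl in labs) {
      rc <- rs[rs$cluster == cl, ]
      sig <- rc$significant & rc$nes > 0
      nes <- rc$nes[sig]
      pos_nes[[cl]] <- nes
      qs <- if (length(nes)) stats::quantile(nes, c(0.25, 0.5, 0.75))
            else rep(NA_real_, 3)
      summ[[length(summ) + 1L]] <- data.frame(
        gene_set = gs, cluster = cl, n_cells = nrow(rc),
        frac_significant_pos = if (nrow(rc)) mean(sig) else NA_real_,
        nes_q1 = qs[1], nes_median = qs[2], nes_q3 = qs[3],
        stringsAsFactors = FALSE)
    }
    for (a in labs) for (b in labs) {
      if (a > b) next
      x <- pos_nes[[a]]; y <- pos_nes[[b]]
      p <- if (length(x) == 0 || length(y) == 0) NA_real_
           else if (a == b) 1
           else suppressWarnings(stats::wilcox.test(x, y)$p.value)
      tests[[length(tests) + 1L]] <- data.frame(
        gene_set = gs, cluster_a = a, cluster_b = b, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summ), tests = do.call(rbind, tests))
}

#' Per-cluster expression statistics of selected genes
#'
#' For heat-map style summaries: the mean log-normalised expression of each
#' gene within each cluster, z-scored across clusters (a constant gene gets
#' z = 0 everywhere), and the fraction of cells per cluster with a non-zero
#' count.
#'
#' @param counts Genes x cells count matrix.
#' @param clusters Named vector mapping cell id to cluster label; at least
#'   two clusters required.
#' @param genes Genes to summarise (default: all).
#' @return Long data.frame: `gene`, `cluster`, `mean_log`, `z_score`,
#'   `frac_expressing`.
#' @export
cluster_expression_stats <- function(counts, clusters,
                                     genes = rownames(counts)) {
  cl <- as.character(clusters[colnames(counts)])
  labs <- sort(unique(cl))
  if (length(labs) < 2) stop("need at least 2 clusters")
  lm <- log_normalize(counts[genes, , drop = FALSE])
  lm <- as.matrix(lm)
  cm <- counts[genes, , drop = FALSE]
  means <- vapply(labs, function(g)
    rowMeans(lm[, cl == g, drop = FALSE]), numeric(length(genes)))
  fracs <- vapply(labs, function(g)
    rowMeans(as.matrix(cm[, cl == g, drop = FALSE]) > 0),
    numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, labs))
  fracs <- matrix(fracs, nrow = length(genes),
                  dimnames = list(genes, labs))
  mu <- rowMeans(means)
  sdv <- apply(means, 1, stats::sd)
  z <- (means - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  data.frame(
    gene = rep(genes, times = length(labs)),
    cluster = rep(labs, each = length(genes)),
    mean_log = as.numeric(means),
    z_score = as.numeric(z),
    frac_expressing = as.numeric(fracs),
    stringsAsFactors = FALSE)
}
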