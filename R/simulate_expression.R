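#' Configuration for the UMI count-matrix simulator
#'
#' Parameters for [simulate_expression()]: a negative-binomial gene x cell
#' count model with per-gene baseline means drawn from a log-normal law,
#' per-cell library-size multipliers, a common inverse dispersion, and
#' planted cluster-specific gene modules. A module multiplies the NB mean of
#' its member genes by `exp(effect)` in its target clusters only (`effect`
#' is a natural-log fold change, matching the pipeline's `ln`
#' normalisation). Module gene sets are disjoint across modules; module
#' members get baseline means redrawn from a moderately-expressed law
#' (log-normal, meanlog `log(1.5)`, sdlog 0.5), reflecting that marker
#' genes are detectably expressed.
#'
#' @param n_genes,n_cells,n_clusters Dimensions; cells are split evenly
#'   across clusters (remainder to the first clusters).
#' @param module_specs List of modules, each a list with `name`, `n_genes`,
#'   `clusters` (integer target cluster indices) and `effect` (natural-log
#'   fold change).
#' @param baseline_meanlog,baseline_sdlog Log-normal law of per-gene
#'   baseline NB means.
#' @param dispersion NB inverse dispersion (`size`), shared across genes.
#' @param libsize_meanlog,libsize_sdlog Log-normal law of per-cell
#'   library-size multipliers (meanlog 0 keeps the average scale at the
#'   baseline law).
#' @param mito_gene_fraction Fraction of genes labelled mitochondrial
#'   (`MT-` prefix), for per-cell QC fractions.
#' @param seed Integer seed.
#' @return A validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000, n_cells = 1000,
                                  n_clusters = 5,
                                  module_specs = list(),
                                  baseline_meanlog = log(0.5),
                                  baseline_sdlog = 1,
                                  dispersion = 2,
                                  libsize_meanlog = 0,
                                  libsize_sdlog = 0.3,
                                  mito_gene_fraction = 0.05,
                                  seed = 1L) {
  if (n_genes < 1 || n_cells < 1 || n_clusters < 1) {
    stop("n_genes, n_cells and n_clusters must be positive counts")
  }
  total_module_genes <- sum(vapply(module_specs, function(m) m$n_genes, 0))
  if (total_module_genes > n_genes) {
    stop("module genes exceed n_genes")
  }
  for (m in module_specs) {
    if (any(m$clusters < 1 | m$clusters > n_clusters)) {
      stop("module ", m$name, " targets a cluster outside 1..n_clusters")
    }
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 module_specs = module_specs,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 mito_gene_fraction = mito_gene_fraction,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a UMI count matrix with planted gene modules
#'
#' Draws genes x cells negative-binomial UMI counts under the model of
#' [expression_sim_config()] and plants cluster-specific modules with known
#' membership, returning the ground truth alongside. The counts are
#' Matrix-Market-writable sparse integers ([write_mtx()]).
#'
#' @param config An [expression_sim_config()].
#' @return List with `counts` (`dgCMatrix`, genes x cells, dimnames set),
#'   `cells` (data.frame: `cell_id`, `cluster`, `total_umis`,
#'   `mito_fraction`) and `truth` (module membership, module target cells,
#'   config echo).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  withr::with_seed(config$seed, {
    ng <- config$n_genes; nc <- config$n_cells
    gene_ids <- sprintf("GENE%05d", seq_len(ng))
    n_mito <- round(config$mito_gene_fraction * ng)
    if (n_mito > 0) {
      gene_ids[seq_len(n_mito)] <- sprintf("MT-GENE%05d", seq_len(n_mito))
    }
    cell_ids <- sprintf("BC%05d", seq_len(nc))
    cluster <- rep(seq_len(config$n_clusters), length.out = nc)
    cluster <- sort(cluster)

    base_mu <- stats::rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
    # assign disjoint module memberships (skip mito genes)
    free <- setdiff(seq_len(ng), seq_len(n_mito))
    module_genes <- list()
    for (m in config$module_specs) {
      g <- sort(sample(free, m$n_genes))
      free <- setdiff(free, g)
      module_genes[[m$name]] <- gene_ids[g]
      base_mu[g] <- stats::rlnorm(m$n_genes, log(1.5), 0.5)
    }

    lib <- stats::rlnorm(nc, config$libsize_meanlog, config$libsize_sdlog)
    # log-fold effects per gene x cluster
    lfc <- matrix(0, ng, config$n_clusters)
    for (m in config$module_specs) {
      g <- match(module_genes[[m$name]], gene_ids)
      lfc[g, m$clusters] <- lfc[g, m$clusters] + m$effect
    }
    counts <- matrix(0L, ng, nc)
    for (k in seq_len(config$n_clusters)) {
      cells_k <- which(cluster == k)
      mu_k <- base_mu * exp(lfc[, k])
      mu <- outer(mu_k, lib[cells_k])
      counts[, cells_k] <- stats::rnbinom(length(mu), mu = mu,
                                          size = config$dispersion)
    }
    dimnames(counts) <- list(gene_ids, cell_ids)
    totals <- colSums(counts)
    mito <- if (n_mito > 0) {
      colSums(counts[seq_len(n_mito), , drop = FALSE]) / pmax(totals, 1)
    } else rep(0, nc)

    truth <- list(
      module_genes = module_genes,
      module_cells = stats::setNames(lapply(config$module_specs, function(m)
        cell_ids[cluster %in% m$clusters]),
        vapply(config$module_specs, function(m) m$name, "")),
      cluster_of_cell = stats::setNames(cluster, cell_ids),
      config = config
    )
    list(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      cells = data.frame(cell_id = cell_ids, cluster = cluster,
                         total_umis = as.integer(totals),
                         mito_fraction = mito, stringsAsFactors = FALSE),
      truth = truth
    )
  })
}
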