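#' Select one analysis contig pair per cell
#'
#' Reduces a multi-contig rearrangement table to one heavy and one light
#' chain per cell. Contigs are first filtered to productive, fully sequenced
#' ones (complete V(D)J, all five FR1-FR3 regions present with non-zero
#' length, and a non-empty CDR3); within each cell and locus the most
#' abundant contig is kept, ranked by UMI count (`duplicate_count`), then
#' read count (`consensus_count`), then lexicographically smallest
#' `contig_id` for full determinism. Cells lacking either chain after
#' filtering — unpaired cells — are dropped and counted in the report.
#'
#' @param rearrangements AIRR-style rearrangement data.frame (see
#'   [simulate_repertoire()] for the column contract). `duplicate_count`
#'   must be present and non-missing for every contig.
#' @return A list:
#'   * `pairs`: one row per retained cell, heavy/light columns prefixed
#'     `heavy_` / `light_`;
#'   * `report`: `n_cells_in`, `n_cells_paired`, `n_cells_dropped_unpaired`,
#'     `n_contigs_filtered`, and the dropped cell identifiers.
#' @export
select_contigs <- function(rearrangements) {
  x <- as.data.frame(rearrangements)
  required <- c("cell_id", "contig_id", "locus", "productive",
                "duplicate_count", "junction", "sequence_alignment")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("rearrangement table lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(x$duplicate_count)) {
    bad <- x$contig_id[is.na(x$duplicate_count)][1]
    stop("contig ", bad, " has no abundance (duplicate_count)")
  }
  if (!"consensus_count" %in% names(x)) x$consensus_count <- x$duplicate_count
  full <- if ("complete_vdj" %in% names(x)) x$complete_vdj else TRUE
  regions_ok <- rep(TRUE, nrow(x))
  for (r in c("fwr1", "cdr1", "fwr2", "cdr2", "fwr3")) {
    if (r %in% names(x)) regions_ok <- regions_ok & nzchar(x[[r]])
  }
  keep <- x$productive & full & regions_ok & nzchar(x$junction)
  n_filtered <- sum(!keep)
  xf <- x[keep, , drop = FALSE]

  # deterministic ranking: UMIs desc, reads desc, contig_id asc
  ord <- order(xf$cell_id, xf$locus, -xf$duplicate_count,
               -xf$consensus_count, xf$contig_id)
  xf <- xf[ord, , drop = FALSE]
  xf <- xf[!duplicated(paste(xf$cell_id, xf$locus)), , drop = FALSE]

  heavy <- xf[xf$locus == "IGH", , drop = FALSE]
  light <- xf[xf$locus != "IGH", , drop = FALSE]
  paired_cells <- intersect(heavy$cell_id, light$cell_id)
  all_cells <- unique(x$cell_id)
  dropped <- setdiff(all_cells, paired_cells)

  heavy <- heavy[match(paired_cells, heavy$cell_id), , drop = FALSE]
  light <- light[match(paired_cells, light$cell_id), , drop = FALSE]
  carry <- setdiff(names(xf), c("cell_id", "donor"))
  pairs <- data.frame(cell_id = paired_cells, stringsAsFactors = FALSE)
  if ("donor" %in% names(xf)) pairs$donor <- heavy$donor
  for (cn in carry) {
    pairs[[paste0("heavy_", cn)]] <- heavy[[cn]]
    pairs[[paste0("light_", cn)]] <- light[[cn]]
  }
  pairs <- pairs[order(pairs$cell_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       report = list(n_cells_in = length(all_cells),
                     n_cells_paired = length(paired_cells),
                     n_cells_dropped_unpaired = length(dropped),
                     n_contigs_filtered = n_filtered,
                     dropped_cells = sort(dropped)))
}

.parse_mutation_events <- function(events) {
  if (is.na(events) || !nzchar(events)) {
    return(data.frame(region = character(0), position = integer(0),
                      germline_base = character(0),
                      observed_base = character(0)))
  }
  parts <- strsplit(strsplit(events, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bases <- vapply(parts, `[`, "", 3L)
  data.frame(
    region = vapply(parts, `[`, "", 1L),
    position = as.integer(vapply(parts, `[`, "", 2L)),
    germline_base = substr(bases, 1L, 1L),
    observed_base = substr(bases, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct the gapped germline FR1-CDR1-FR2-CDR2-FR3 sequence
#'
#' Reverts every substitution listed in a contig's mutation-event table on
#' its gapped observed sequence, reverse-engineering the germline the way
#' the mutation table allows: gaps are preserved, length is unchanged, and
#' positions are validated against the region spans.
#'
#' @param contig A one-row data.frame or list with `sequence_alignment`,
#'   `mutation_events` and `region_spans` fields (AIRR-style contig row, or
#'   a `heavy_` / `light_` slice of a pair row with prefixes stripped).
#' @return The gapped germline string (same length as the observed
#'   alignment).
#' @export
reconstruct_germline <- function(contig) {
  obs <- strsplit(contig$sequence_alignment, "")[[1]]
  spans <- as.integer(strsplit(contig$region_spans, ",", fixed = TRUE)[[1]])
  regions <- .region_of_positions(spans)
  ev <- .parse_mutation_events(contig$mutation_events)
  if (nrow(ev) > 0) {
    if (any(ev$position < 1L | ev$position > length(obs))) {
      stop("mutation position outside the FR1-FR3 gapped span")
    }
    if (any(regions[ev$position] != ev$region)) {
      stop("mutation position falls outside its stated region")
    }
    if (any(obs[ev$position] == ".")) {
      stop("mutation listed at a gap position")
    }
    if (any(obs[ev$position] != ev$observed_base)) {
      stop("observed base in mutation table disagrees with the alignment")
    }
    noop <- ev$germline_base == ev$observed_base
    if (any(noop)) {
      warning(sum(noop), " no-op mutation(s) (germline == observed) ignored")
    }
    obs[ev$position] <- ev$germline_base
  }
  paste(obs, collapse = "")
}

#' Somatic-mutation rate of a paired BCR
#'
#' The mutation rate of a cell is the sum of the estimated mutation counts
#' in the heavy and the light chain divided by the summed nucleotide length
#' of the corresponding regions (gap-excluded), for a region group: `"FR"`
#' pools FR1+FR2+FR3, `"CDR"` pools CDR1+CDR2 (the CDR3 junction has no
#' reconstructed germline in this schema, so its mutations are not
#' observable). The statistic is symmetric in the two chains.
#'
#' @param pair One row of the `pairs` table from [select_contigs()].
#' @param region_group `"FR"` (default) or `"CDR"`.
#' @return Mutations per nucleotide, in `[0, 1]`.
#' @export
mutation_rate <- function(pair, region_group = c("FR", "CDR")) {
  region_group <- match.arg(region_group)
  regs <- if (region_group == "FR") c("fwr1", "fwr2", "fwr3")
          else c("cdr1", "cdr2")
  tally <- function(prefix) {
    counts <- sum(vapply(regs, function(r)
      as.integer(pair[[paste0(prefix, r, "_mutations")]]), 0L))
    len <- sum(vapply(regs, function(r)
      nchar(pair[[paste0(prefix, r)]]), 0L))
    c(counts, len)
  }
  h <- tally("heavy_"); l <- tally("light_")
  total_len <- h[2] + l[2]
  if (total_len == 0) stop("zero total region length for group ", region_group)
  rate <- (h[1] + l[1]) / total_len
  if (rate < 0 || rate > 1) stop("mutation rate outside [0, 1]")
  rate
}

#' @describeIn mutation_rate Vectorised over the rows of a pairs table.
#' @param pairs The full `pairs` data.frame.
#' @export
mutation_rates <- function(pairs, region_group = c("FR", "CDR")) {
  region_group <- match.arg(region_group)
  vapply(seq_len(nrow(pairs)), function(i)
    mutation_rate(pairs[i, , drop = FALSE], region_group), 0)
}
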