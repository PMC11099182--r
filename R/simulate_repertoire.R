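#' Configuration for the paired-chain repertoire simulator
#'
#' Builds and validates the parameter set for [simulate_repertoire()]. The
#' defaults describe a small, skewed plasma-cell repertoire: clone sizes
#' follow a truncated power law, every cell carries one heavy (IGH) and one
#' light (IGK) chain, somatic hypermutation is i.i.d. per-base substitution
#' on the gapped FR1-CDR1-FR2-CDR2-FR3 region, and the CDR3 of each cell
#' diverges from its clonal ancestor only inside a per-clone set of mutable
#' positions.
#'
#' Restricting within-clone variation to a mutable-position set of size
#' `floor(within_clone_divergence * L)` bounds the pairwise Hamming distance
#' between any two cells of a clone by `within_clone_divergence`, so with
#' `within_clone_divergence < 0.2` every intra-clone pair exceeds the 80%
#' CDR3-identity rule used by [partition_families()]. Decoy clones share
#' donor, V/J genes and CDR3 lengths with a partner clone but differ at a
#' disjoint block of positions, capping their cross-clone identity at
#' `decoy_identity_ceiling` (kept below 0.8 so decoys can never merge).
#'
#' @param n_cells,n_clones Number of simulated cells and clonal families.
#' @param clone_size_law `"power"` (default, exponent `alpha`) or
#'   `"uniform"`.
#' @param alpha Power-law exponent for clone sizes (default 2).
#' @param segment_library Germline V/J segment table as returned by
#'   [read_germline_segments()].
#' @param cdr3_length_range Inclusive range (nt) for CDR3 lengths; lengths
#'   are drawn as multiples of 3.
#' @param within_clone_divergence Maximum fraction of CDR3 positions at which
#'   two cells of the same clone may differ. Must be `< 0.2`.
#' @param shm_rate Per-base substitution probability on non-gap positions of
#'   the gapped germline FR1-FR3 string.
#' @param decoy_fraction Fraction of clones that receive a decoy partner
#'   clone (same donor/V/J/CDR3 length, identity capped).
#' @param decoy_identity_ceiling Maximum CDR3 identity between a decoy clone
#'   and its partner; must be `< 0.8`.
#' @param donor_labels Donor identifiers clones are assigned to.
#' @param unpaired_fraction Fraction of cells emitted with a heavy chain only
#'   (dropped later by [select_contigs()]).
#' @param extra_contig_fraction Fraction of cells that receive an extra decoy
#'   contig (unproductive, partial, or lower-UMI duplicate) to exercise
#'   contig selection.
#' @param seed Integer seed; every simulator call is fully seeded.
#' @return A validated list of class `repertoire_sim_config`.
#' @export
repertoire_sim_config <- function(n_cells = 60, n_clones = 10,
                                  clone_size_law = c("power", "uniform"),
                                  alpha = 2,
                                  segment_library = read_germline_segments(),
                                  cdr3_length_range = c(24, 60),
                                  within_clone_divergence = 0.1,
                                  shm_rate = 0.02,
                                  decoy_fraction = 0.2,
                                  decoy_identity_ceiling = 0.6,
                                  donor_labels = c("D01", "D02"),
                                  unpaired_fraction = 0.05,
                                  extra_contig_fraction = 0.2,
                                  seed = 1L) {
  clone_size_law <- match.arg(clone_size_law)
  if (n_cells < 1 || n_clones < 1) {
    stop("n_cells and n_clones must be positive counts")
  }
  if (n_clones > n_cells) stop("n_clones cannot exceed n_cells")
  if (within_clone_divergence < 0 || within_clone_divergence >= 0.2) {
    stop("within_clone_divergence must be in [0, 0.2): values >= 0.2 break ",
         "the guarantee that intra-clone CDR3 identity exceeds 0.8")
  }
  if (decoy_identity_ceiling >= 0.8) {
    stop("decoy_identity_ceiling must be < 0.8 so decoy clones never merge")
  }
  if (shm_rate < 0 || shm_rate > 0.25) stop("shm_rate must be in [0, 0.25]")
  if (cdr3_length_range[1] < 9 || cdr3_length_range[2] < cdr3_length_range[1]) {
    stop("cdr3_length_range must be an increasing range with minimum >= 9")
  }
  # the decoy difference block and both clones' mutable sets must fit in L
  need <- (1 - decoy_identity_ceiling) + 2 * within_clone_divergence
  if (decoy_fraction > 0 && need > 1) {
    stop("decoy_identity_ceiling and within_clone_divergence are jointly ",
         "infeasible: disjoint position blocks exceed the CDR3 length")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_clones = as.integer(n_clones),
    clone_size_law = clone_size_law, alpha = alpha,
    segment_library = segment_library,
    cdr3_length_range = as.integer(cdr3_length_range),
    within_clone_divergence = within_clone_divergence,
    shm_rate = shm_rate, decoy_fraction = decoy_fraction,
    decoy_identity_ceiling = decoy_identity_ceiling,
    donor_labels = donor_labels,
    unpaired_fraction = unpaired_fraction,
    extra_contig_fraction = extra_contig_fraction,
    seed = as.integer(seed)
  ), class = "repertoire_sim_config")
}

NT <- c("A", "C", "G", "T")

.rand_nt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

.mutate_at <- function(chars, pos) {
  for (p in pos) chars[p] <- sample(setdiff(NT, chars[p]), 1L)
  chars
}

# region name of each gapped position given the five span lengths
.region_of_positions <- function(spans) {
  rep(c("fwr1", "cdr1", "fwr2", "cdr2", "fwr3"), times = spans)
}

.translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X"))
}

#' Simulate a paired-chain BCR repertoire with known clonal truth
#'
#' Emits an AIRR-style rearrangement table (one contig per row) together with
#' the generating truth. Each cell receives a heavy and a light contig with
#' gapped observed and germline FR1-CDR1-FR2-CDR2-FR3 strings, a CDR3
#' junction, per-region mutation counts and an explicit mutation-event table
#' (`mutation_events` column, `region:gapped-position:germ>obs` entries), so
#' germline reconstruction and mutation rates can be checked against the
#' generator. A configurable fraction of cells gets decoy contigs
#' (unproductive / partial / lower-UMI duplicates) and a fraction is emitted
#' heavy-only to exercise the pairing filter.
#'
#' @param config A [repertoire_sim_config()].
#' @return A list with `rearrangements` (data.frame, AIRR-style columns) and
#'   `truth` (list: `family_of_cell` named character vector over all emitted
#'   cells, `germline_of_clone`, `clone_table`, `config` echo).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "repertoire_sim_config"))
  withr::with_seed(config$seed, .simulate_repertoire_impl(config))
}

.simulate_repertoire_impl <- function(config) {
  lib <- config$segment_library
  vh <- lib[lib$locus == "IGH" & lib$type == "V", ]
  jh <- lib[lib$locus == "IGH" & lib$type == "J", ]
  vl <- lib[lib$locus == "IGK" & lib$type == "V", ]
  jl <- lib[lib$locus == "IGK" & lib$type == "J", ]
  if (nrow(vh) == 0 || nrow(jh) == 0 || nrow(vl) == 0 || nrow(jl) == 0) {
    stop("segment_library must contain V and J segments for IGH and IGK")
  }

  n_clones <- config$n_clones
  n_decoy <- if (config$decoy_fraction > 0 && n_clones >= 2) {
    min(floor(config$decoy_fraction * n_clones), floor(n_clones / 2))
  } else 0L

  # clone scaffolds; decoys are built against a base clone afterwards
  cdr3_len <- function() {
    lens <- seq(config$cdr3_length_range[1], config$cdr3_length_range[2], by = 3L)
    sample(lens, 1L)
  }
  clones <- vector("list", n_clones)
  n_base <- n_clones - n_decoy
  for (k in seq_len(n_base)) {
    lh <- cdr3_len(); ll <- cdr3_len()
    mh <- floor(config$within_clone_divergence * lh)
    ml <- floor(config$within_clone_divergence * ll)
    clones[[k]] <- list(
      clone_id = sprintf("C%03d", k),
      donor = sample(config$donor_labels, 1L),
      vh = vh[sample.int(nrow(vh), 1L), ], jh = jh[sample.int(nrow(jh), 1L), ],
      vl = vl[sample.int(nrow(vl), 1L), ], jl = jl[sample.int(nrow(jl), 1L), ],
      cdr3_h = strsplit(.rand_nt(lh), "")[[1]],
      cdr3_l = strsplit(.rand_nt(ll), "")[[1]],
      mut_h = sort(sample.int(lh, mh)), mut_l = sort(sample.int(ll, ml))
    )
  }
  if (n_decoy > 0) {
    base_idx <- sample.int(n_base, n_decoy)
    for (d in seq_len(n_decoy)) {
      b <- clones[[base_idx[d]]]
      k <- n_base + d
      mk_decoy_chain <- function(cdr3, mut_set, L) {
        ndiff <- ceiling((1 - config$decoy_identity_ceiling) * L)
        nmut <- length(mut_set)
        avail <- setdiff(seq_len(L), mut_set)
        diff_pos <- sort(sample(avail, ndiff))
        own_mut <- sort(sample(setdiff(avail, diff_pos),
                               min(nmut, length(setdiff(avail, diff_pos)))))
        list(cdr3 = .mutate_at(cdr3, diff_pos), mut = own_mut)
      }
      dh <- mk_decoy_chain(b$cdr3_h, b$mut_h, length(b$cdr3_h))
      dl <- mk_decoy_chain(b$cdr3_l, b$mut_l, length(b$cdr3_l))
      clones[[k]] <- list(
        clone_id = sprintf("C%03d", k), donor = b$donor,
        vh = b$vh, jh = b$jh, vl = b$vl, jl = b$jl,
        cdr3_h = dh$cdr3, cdr3_l = dl$cdr3,
        mut_h = dh$mut, mut_l = dl$mut
      )
    }
  }

  # allocate cells to clones: one guaranteed member each, rest by size law
  sizes <- rep(1L, n_clones)
  extra <- config$n_cells - n_clones
  if (extra > 0) {
    w <- if (config$clone_size_law == "power") {
      raw <- sample.int(config$n_cells, n_clones, replace = TRUE,
                        prob = seq_len(config$n_cells)^(-config$alpha))
      raw / sum(raw)
    } else rep(1 / n_clones, n_clones)
    add <- tabulate(sample.int(n_clones, extra, replace = TRUE, prob = w),
                    nbins = n_clones)
    sizes <- sizes + add
  }

  cell_clone <- rep(seq_len(n_clones), times = sizes)
  n_cells <- length(cell_clone)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  unpaired <- runif(n_cells) < config$unpaired_fraction
  extra_contig <- runif(n_cells) < config$extra_contig_fraction

  rows <- vector("list", 3L * n_cells)
  nrow_used <- 0L
  emit <- function(row) {
    nrow_used <<- nrow_used + 1L
    rows[[nrow_used]] <<- row
  }

  make_contig <- function(cell, contig_n, clone, chain, cdr3_chars,
                          duplicate_count, productive = TRUE,
                          full_length = TRUE) {
    v <- if (chain == "H") clone$vh else clone$vl
    j <- if (chain == "H") clone$jh else clone$jl
    locus <- if (chain == "H") "IGH" else "IGK"
    germ <- strsplit(v$sequence, "")[[1]]
    spans <- v$spans[[1]]
    regions <- .region_of_positions(spans)
    obs <- germ
    events <- character(0)
    if (config$shm_rate > 0 && productive) {
      non_gap <- which(germ != ".")
      hit <- non_gap[runif(length(non_gap)) < config$shm_rate]
      for (p in hit) {
        newb <- sample(setdiff(NT, germ[p]), 1L)
        obs[p] <- newb
        events <- c(events, sprintf("%s:%d:%s>%s", regions[p], p, germ[p], newb))
      }
    }
    mut_counts <- vapply(c("fwr1", "cdr1", "fwr2", "cdr2", "fwr3"),
      function(r) sum(grepl(paste0("^", r, ":"), events)), 0L)
    region_str <- function(r) {
      s <- obs[regions == r]
      paste(s[s != "."], collapse = "")
    }
    junction <- paste(cdr3_chars, collapse = "")
    data.frame(
      cell_id = cell, contig_id = sprintf("%s_contig%d", cell, contig_n),
      donor = clone$donor, locus = locus,
      v_call = v$name, j_call = j$name,
      productive = productive, complete_vdj = full_length,
      duplicate_count = duplicate_count,
      consensus_count = duplicate_count * 3L + 1L,
      junction = junction,
      junction_aa = NA_character_,  # filled in bulk below
      sequence_alignment = paste(obs, collapse = ""),
      germline_alignment = paste(germ, collapse = ""),
      fwr1 = region_str("fwr1"), cdr1 = region_str("cdr1"),
      fwr2 = region_str("fwr2"), cdr2 = region_str("cdr2"),
      fwr3 = region_str("fwr3"),
      region_spans = paste(spans, collapse = ","),
      mutation_events = paste(events, collapse = ";"),
      fwr1_mutations = mut_counts[["fwr1"]],
      cdr1_mutations = mut_counts[["cdr1"]],
      fwr2_mutations = mut_counts[["fwr2"]],
      cdr2_mutations = mut_counts[["cdr2"]],
      fwr3_mutations = mut_counts[["fwr3"]],
      c_call = if (locus == "IGH") sample(c("IGHG1", "IGHA1", "IGHM"), 1L)
               else "IGKC",
      stringsAsFactors = FALSE
    )
  }

  cell_cdr3 <- function(clone, chain) {
    anc <- if (chain == "H") clone$cdr3_h else clone$cdr3_l
    mut <- if (chain == "H") clone$mut_h else clone$mut_l
    if (length(mut) == 0) return(anc)
    touch <- mut[runif(length(mut)) < 0.5]
    .mutate_at(anc, touch)
  }

  for (i in seq_len(n_cells)) {
    clone <- clones[[cell_clone[i]]]
    umi_h <- 5L + stats::rpois(1, 15)
    ch <- cell_cdr3(clone, "H")
    emit(make_contig(cell_ids[i], 1L, clone, "H", ch, umi_h))
    contig_n <- 2L
    if (!unpaired[i]) {
      cl <- cell_cdr3(clone, "L")
      emit(make_contig(cell_ids[i], contig_n, clone, "L", cl,
                       5L + stats::rpois(1, 15)))
      contig_n <- contig_n + 1L
    }
    if (extra_contig[i]) {
      kind <- sample(c("unproductive", "duplicate", "partial"), 1L)
      decoy <- switch(kind,
        # unproductive decoys outrank the real contig by abundance
        unproductive = make_contig(cell_ids[i], contig_n, clone, "H", ch,
                                   umi_h + 10L, productive = FALSE),
        duplicate = make_contig(cell_ids[i], contig_n, clone, "H",
                                cell_cdr3(clone, "H"),
                                max(1L, umi_h - 4L)),
        partial = make_contig(cell_ids[i], contig_n, clone, "H", ch,
                              umi_h + 10L, full_length = FALSE)
      )
      emit(decoy)
    }
  }

  rearr <- do.call(rbind, rows[seq_len(nrow_used)])
  rearr$junction_aa <- .translate_nt(rearr$junction)
  rownames(rearr) <- NULL

  truth <- list(
    family_of_cell = stats::setNames(
      vapply(cell_clone, function(k) clones[[k]]$clone_id, ""), cell_ids),
    germline_of_clone = stats::setNames(lapply(clones, function(cl)
      list(heavy = cl$vh$sequence, light = cl$vl$sequence)),
      vapply(clones, `[[`, "", "clone_id")),
    clone_table = data.frame(
      clone_id = vapply(clones, `[[`, "", "clone_id"),
      donor = vapply(clones, `[[`, "", "donor"),
      v_call_heavy = vapply(clones, function(cl) cl$vh$name, ""),
      j_call_heavy = vapply(clones, function(cl) cl$jh$name, ""),
      v_call_light = vapply(clones, function(cl) cl$vl$name, ""),
      j_call_light = vapply(clones, function(cl) cl$jl$name, ""),
      size = sizes, stringsAsFactors = FALSE
    ),
    unpaired_cells = cell_ids[unpaired],
    config = config[setdiff(names(config), "segment_library")]
  )
  list(rearrangements = rearr, truth = truth)
}

#' Plant public clones into a reference clonotype table
#'
#' Selects `n_public` cells (at most one per clonal family) from a simulated
#' repertoire and derives an antigen-labelled reference clonotype for each by
#' substituting a controlled fraction of concatenated heavy+light CDR3
#' positions, so the joint nucleotide identity between the reference and its
#' source cell is exactly `1 - divergence` (up to integer rounding). The
#' returned truth lists every repertoire cell whose joint identity to some
#' reference reaches the 0.8 matching floor, computed by a direct all-pairs
#' scan inside the generator.
#'
#' @param rearrangements AIRR-style table from [simulate_repertoire()].
#' @param n_public Number of reference clonotypes to plant.
#' @param divergence Fraction of concatenated CDR3 positions substituted in
#'   the reference relative to its source cell.
#' @param seed Integer seed.
#' @param antigen_labels Labels cycled over the planted references.
#' @return List with `reference` (AIRR-style table plus `antigen_label` and
#'   `reference_id`) and `truth` (`true_public_cells`, `planted_cells`,
#'   per-reference source and identity).
#' @export
plant_public_clones <- function(rearrangements, n_public, divergence = 0,
                                seed = 1L,
                                antigen_labels = c("spike", "tetanus")) {
  if (divergence < 0 || divergence > 0.5) {
    stop("divergence must be in [0, 0.5]")
  }
  if (divergence > 0.2) {
    warning("divergence > 0.2 places planted references below the 0.8 joint-",
            "identity floor; use only as a negative control")
  }
  pairs <- select_contigs(rearrangements)$pairs
  if (nrow(pairs) == 0) stop("repertoire has no paired cells")
  if (n_public > nrow(pairs)) stop("n_public exceeds available paired cells")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(pairs), n_public)
    refs <- vector("list", n_public)
    for (r in seq_len(n_public)) {
      src <- pairs[idx[r], ]
      h <- strsplit(src$heavy_junction, "")[[1]]
      l <- strsplit(src$light_junction, "")[[1]]
      total <- length(h) + length(l)
      k <- round(divergence * total)
      pos <- if (k > 0) sample.int(total, k) else integer(0)
      h <- .mutate_at(h, pos[pos <= length(h)])
      l <- .mutate_at(l, pos[pos > length(h)] - length(h))
      refs[[r]] <- data.frame(
        reference_id = sprintf("REF%03d", r),
        antigen_label = antigen_labels[(r - 1L) %% length(antigen_labels) + 1L],
        source_cell = src$cell_id,
        heavy_junction = paste(h, collapse = ""),
        light_junction = paste(l, collapse = ""),
        heavy_v_call = src$heavy_v_call, heavy_j_call = src$heavy_j_call,
        light_v_call = src$light_v_call, light_j_call = src$light_j_call,
        stringsAsFactors = FALSE
      )
    }
    reference <- do.call(rbind, refs)
    # truth by direct all-pairs scan at the inclusive 0.8 floor
    is_public <- vapply(seq_len(nrow(pairs)), function(i) {
      any(vapply(seq_len(nrow(reference)), function(r) {
        ji <- .joint_identity_nt(pairs$heavy_junction[i],
                                 pairs$light_junction[i],
                                 reference$heavy_junction[r],
                                 reference$light_junction[r])
        !is.na(ji) && ji >= 0.8
      }, NA))
    }, NA)
    list(reference = reference,
         truth = list(true_public_cells = pairs$cell_id[is_public],
                      planted_cells = pairs$cell_id[idx],
                      divergence = divergence, seed = seed))
  })
}
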