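# raw joint-identity kernel on CDR3 nucleotide strings.
# NA means incomparable (length mismatch on either chain).
.joint_identity_nt <- function(qh, ql, rh, rl) {
  if (!nzchar(qh) || !nzchar(ql) || !nzchar(rh) || !nzchar(rl)) {
    stop("empty CDR3")
  }
  if (nchar(qh) != nchar(rh) || nchar(ql) != nchar(rl)) return(NA_real_)
  mh <- sum(strsplit(qh, "")[[1]] == strsplit(rh, "")[[1]])
  ml <- sum(strsplit(ql, "")[[1]] == strsplit(rl, "")[[1]])
  (mh + ml) / (nchar(qh) + nchar(ql))
}

#' Joint CDR3 identity between a query and a reference clonotype
#'
#' The sum of identical nucleotides across the heavy and light CDR3s,
#' normalised to their total length. Comparable only when CDR3 lengths agree
#' on both chains; otherwise the pair is incomparable and `NA` is returned
#' (an incomparable pair can never match, regardless of the other chain).
#' The statistic is symmetric: `joint_identity(q, r) == joint_identity(r, q)`.
#'
#' @param query,ref Lists or one-row data.frames carrying `heavy_junction`
#'   and `light_junction`.
#' @return Identity in `[0, 1]`, or `NA` if incomparable.
#' @export
joint_identity <- function(query, ref) {
  .joint_identity_nt(query$heavy_junction, query$light_junction,
                     ref$heavy_junction, ref$light_junction)
}

#' Match repertoire cells against antigen-specific reference clonotypes
#'
#' Identifies putatively antigen-specific ("public") cells: a query matches
#' a reference when their CDR3 lengths agree on both chains and the identity
#' criterion holds at `threshold` (inclusive, default `>= 0.8`). In `joint`
#' mode (default) identity is pooled over both CDR3s; in `per_chain` mode
#' each chain must reach the threshold on its own. V/J gene agreement is not
#' required unless `require_vj = TRUE`. Candidates are bucketed by CDR3
#' length pair purely as an optimisation; results equal the all-pairs scan.
#'
#' @param pairs `pairs` data.frame from [select_contigs()].
#' @param reference Reference clonotype table with `reference_id`,
#'   `antigen_label`, `heavy_junction`, `light_junction` (and
#'   `heavy_v_call`/`heavy_j_call`/`light_v_call`/`light_j_call` when
#'   `require_vj`).
#' @param threshold Minimum identity (inclusive), default 0.8.
#' @param mode `"joint"` (default) or `"per_chain"`.
#' @param require_vj Additionally require identical V and J calls on both
#'   chains.
#' @return A data.frame of matches (`cell_id`, `reference_id`,
#'   `antigen_label`, `joint_identity`, `heavy_identity`, `light_identity`,
#'   `best` flag marking each cell's highest-identity match), ordered by
#'   `cell_id`, descending joint identity, then `reference_id`.
#' @export
match_public <- function(pairs, reference, threshold = 0.8,
                         mode = c("joint", "per_chain"),
                         require_vj = FALSE) {
  mode <- match.arg(mode)
  need_q <- c("cell_id", "heavy_junction", "light_junction")
  need_r <- c("reference_id", "antigen_label", "heavy_junction",
              "light_junction")
  if (require_vj) {
    vj <- c("heavy_v_call", "heavy_j_call", "light_v_call", "light_j_call")
    need_q <- c(need_q, vj); need_r <- c(need_r, vj)
  }
  miss_q <- setdiff(need_q, names(pairs))
  miss_r <- setdiff(need_r, names(reference))
  if (length(miss_q) || length(miss_r)) {
    stop("schema mismatch; missing columns: ",
         paste(c(miss_q, miss_r), collapse = ", "))
  }
  if (nrow(reference) == 0 || nrow(pairs) == 0) {
    return(data.frame(cell_id = character(0), reference_id = character(0),
                      antigen_label = character(0), joint_identity = double(0),
                      heavy_identity = double(0), light_identity = double(0),
                      best = logical(0)))
  }
  qlen <- paste(nchar(pairs$heavy_junction), nchar(pairs$light_junction))
  rlen <- paste(nchar(reference$heavy_junction),
                nchar(reference$light_junction))
  out <- list()
  for (bucket in intersect(unique(qlen), unique(rlen))) {
    qi <- which(qlen == bucket)
    ri <- which(rlen == bucket)
    for (i in qi) for (r in ri) {
      if (require_vj &&
          !(pairs$heavy_v_call[i] == reference$heavy_v_call[r] &&
            pairs$heavy_j_call[i] == reference$heavy_j_call[r] &&
            pairs$light_v_call[i] == reference$light_v_call[r] &&
            pairs$light_j_call[i] == reference$light_j_call[r])) next
      hid <- cdr3_identity(pairs$heavy_junction[i],
                           reference$heavy_junction[r])
      lid <- cdr3_identity(pairs$light_junction[i],
                           reference$light_junction[r])
      lh <- nchar(pairs$heavy_junction[i])
      ll <- nchar(pairs$light_junction[i])
      jid <- (hid * lh + lid * ll) / (lh + ll)
      ok <- if (mode == "joint") jid >= threshold
            else hid >= threshold && lid >= threshold
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          cell_id = pairs$cell_id[i],
          reference_id = reference$reference_id[r],
          antigen_label = reference$antigen_label[r],
          joint_identity = jid, heavy_identity = hid, light_identity = lid,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(cell_id = character(0), reference_id = character(0),
                      antigen_label = character(0), joint_identity = double(0),
                      heavy_identity = double(0), light_identity = double(0),
                      best = logical(0)))
  }
  m <- do.call(rbind, out)
  m <- m[order(m$cell_id, -m$joint_identity, m$reference_id), , drop = FALSE]
  m$best <- !duplicated(m$cell_id)
  rownames(m) <- NULL
  m
}
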