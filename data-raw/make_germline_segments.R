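# Generates the synthetic germline V/J segment library bundled at
# inst/extdata/synthetic_germline_segments.fasta.
# Sequences are random nucleotides (fixed seed) -- not IMGT data.
# Header format: NAME|locus|type|fr1,cdr1,fr2,cdr2,fr3  (gapped span lengths; V only).
# V sequences are IMGT-style gapped: '.' characters inside CDR1/CDR2 spans.
set.seed(20240915)
rnt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

gapped_v <- function(spans, gaps_cdr1, gaps_cdr2) {
  # spans: c(fr1, cdr1, fr2, cdr2, fr3) gapped lengths
  cdr_seq <- function(span, gaps) {
    nt <- strsplit(rnt(span - gaps), "")[[1]]
    # IMGT places gaps centrally in short CDRs
    mid <- floor(length(nt) / 2)
    paste(c(nt[seq_len(mid)], rep(".", gaps), nt[-seq_len(mid)]), collapse = "")
  }
  paste0(rnt(spans[1]), cdr_seq(spans[2], gaps_cdr1), rnt(spans[3]),
         cdr_seq(spans[4], gaps_cdr2), rnt(spans[5]))
}

lines <- character(0)
spans_h <- c(75, 24, 51, 24, 114)
spans_k <- c(78, 18, 51, 9, 108)
for (i in 1:6) {
  g <- sample(0:6, 1); g2 <- sample(0:3, 1)
  lines <- c(lines,
    sprintf(">TOYHV%d|IGH|V|%s", i, paste(spans_h, collapse = ",")),
    gapped_v(spans_h, g, g2))
}
for (i in 1:3) lines <- c(lines, sprintf(">TOYHJ%d|IGH|J|", i), rnt(150 + sample(0:30, 1)))
for (i in 1:4) {
  g <- sample(0:4, 1); g2 <- sample(0:2, 1)
  lines <- c(lines,
    sprintf(">TOYKV%d|IGK|V|%s", i, paste(spans_k, collapse = ",")),
    gapped_v(spans_k, g, g2))
}
for (i in 1:3) lines <- c(lines, sprintf(">TOYKJ%d|IGK|J|", i), rnt(150 + sample(0:30, 1)))

writeLines(lines, "inst/extdata/synthetic_germline_segments.fasta")
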