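# shared interval helpers; all coordinates 1-based, closed intervals

as_granges <- function(chr, start, end) {
  GenomicRanges::GRanges(chr, IRanges::IRanges(start = start, end = end))
}

# logical per query: does it overlap any subject interval (closed, any base)?
overlaps_any <- function(q_chr, q_start, q_end, s_chr, s_start, s_end) {
  if (length(s_chr) == 0L) return(rep(FALSE, length(q_chr)))
  IRanges::overlapsAny(as_granges(q_chr, q_start, q_end),
                       as_granges(s_chr, s_start, s_end))
}

# all query/subject overlap pairs as a two-column matrix of indices
overlap_pairs <- function(q_chr, q_start, q_end, s_chr, s_start, s_end) {
  hits <- GenomicRanges::findOverlaps(
    as_granges(q_chr, q_start, q_end),
    as_granges(s_chr, s_start, s_end))
  cbind(query = S4Vectors::queryHits(hits),
        subject = S4Vectors::subjectHits(hits))
}
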