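#' Circle-caller parameters
#'
#' Thresholds governing sub-read filtering and circle reconstruction. The
#' defaults are the ones used throughout: sub-reads below mapping quality 30
#' are discarded, two sub-reads map to the same locus when both their start
#' and end positions agree within 20 bp, and a circle is kept only when every
#' fragment is covered by at least 2 concordant passes.
#'
#' @param min_mapq minimum mapping quality for a sub-read to be used.
#' @param max_offset maximum start/end offset (bp) between two sub-reads
#'   mapping to the same locus; also the boundary-jitter tolerance used when
#'   attaching partial flanking sub-reads.
#' @param min_full_passes minimum number of full passes (the minimum over
#'   fragments of concordant sub-read counts) for an accepted circle.
#' @param max_query_overlap largest query-space overlap (bp) between
#'   successive sub-reads absorbed by boundary threading; larger overlaps
#'   leave the junction flagged.
#' @param max_junction_gap largest unaligned query gap (bp) at a junction
#'   absorbed by threading; larger gaps leave the junction flagged.
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(min_mapq = 30L, max_offset = 20L,
                          min_full_passes = 2L, max_query_overlap = 20L,
                          max_junction_gap = 50L) {
  p <- list(min_mapq = as.integer(min_mapq),
            max_offset = as.integer(max_offset),
            min_full_passes = as.integer(min_full_passes),
            max_query_overlap = as.integer(max_query_overlap),
            max_junction_gap = as.integer(max_junction_gap))
  stopifnot(p$min_mapq >= 0L, p$max_offset >= 0L, p$min_full_passes >= 1L,
            p$max_query_overlap >= 0L, p$max_junction_gap >= 0L)
  class(p) <- "caller_params"
  p
}

#' Consensus/variant-calling parameters
#'
#' @param min_depth minimum pileup depth for a variant call.
#' @param min_af minimum allele frequency (alt count / depth) for a call.
#' @param boundary_mask variants within this many bp of a voted fragment
#'   boundary are suppressed (boundary jitter stacks artifactual mismatches
#'   at junctions); suppressed calls are reported in the `masked` attribute.
#' @param max_ins_len insertions longer than this in a single cs operation
#'   are treated as unaligned junction sequence and ignored.
#' @param indels when `FALSE`, only substitutions are incorporated into the
#'   consensus.
#' @return a list of class `consensus_params`.
#' @export
consensus_params <- function(min_depth = 4L, min_af = 0.75,
                             boundary_mask = 20L, max_ins_len = 50L,
                             indels = TRUE) {
  p <- list(min_depth = as.integer(min_depth), min_af = as.numeric(min_af),
            boundary_mask = as.integer(boundary_mask),
            max_ins_len = as.integer(max_ins_len), indels = isTRUE(indels))
  stopifnot(p$min_depth >= 1L, p$min_af > 0, p$min_af <= 1,
            p$boundary_mask >= 0L, p$max_ins_len >= 0L)
  class(p) <- "consensus_params"
  p
}
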