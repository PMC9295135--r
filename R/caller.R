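#' Filter and rank sub-reads
#'
#' Drops alignments below the mapping-quality threshold, then sorts each
#' read's surviving alignments by query start and assigns ranks. Successive
#' ranks correspond to successive passes/fragments of the amplified circle.
#'
#' @param records PAF data.frame from [parse_paf()].
#' @param params [caller_params()].
#' @return data.frame of sub-reads with a `rank` column, ordered by read
#'   (first appearance) then query start. Reads whose alignments were all
#'   discarded are recorded in the `"dropped"` attribute.
#' @export
filter_subreads <- function(records, params = caller_params()) {
  all_reads <- unique(records$qname)
  keep <- records$mapq >= params$min_mapq
  sr <- records[keep, , drop = FALSE]
  ord <- order(match(sr$qname, unique(sr$qname)), sr$qstart)
  sr <- sr[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(sr)), sr$qname, FUN = seq_along)
  sr$rank <- as.integer(rank)
  rownames(sr) <- NULL
  attr(sr, "dropped") <- setdiff(all_reads, unique(sr$qname))
  sr
}

#' Cluster the loci of one read's sub-reads
#'
#' Greedy, order-deterministic clustering of mapped loci: walking sub-reads
#' in rank order, a sub-read joins the first existing cluster on the same
#' chromosome and strand whose representative (its first member) has both
#' start and end within `max_offset`; otherwise it seeds a new cluster.
#'
#' @param sr sub-reads of a single read, sorted by rank.
#' @param params [caller_params()].
#' @return list with `labels` (integer cluster id per sub-read) and
#'   `clusters` (data.frame: `chrom`, `strand`, `rep_start`, `rep_end`,
#'   `size`).
#' @export
cluster_loci <- function(sr, params = caller_params()) {
  n <- nrow(sr)
  labels <- integer(n)
  chrom <- character(0); strand <- character(0)
  rep_start <- integer(0); rep_end <- integer(0); size <- integer(0)
  off <- params$max_offset
  for (i in seq_len(n)) {
    hit <- 0L
    for (j in seq_along(chrom)) {
      if (sr$tname[i] == chrom[j] && sr$strand[i] == strand[j] &&
          abs(sr$tstart[i] - rep_start[j]) <= off &&
          abs(sr$tend[i] - rep_end[j]) <= off) { hit <- j; break }
    }
    if (hit == 0L) {
      chrom <- c(chrom, sr$tname[i]); strand <- c(strand, sr$strand[i])
      rep_start <- c(rep_start, sr$tstart[i]); rep_end <- c(rep_end, sr$tend[i])
      size <- c(size, 0L)
      hit <- length(chrom)
    }
    size[hit] <- size[hit] + 1L
    labels[i] <- hit
  }
  list(labels = labels,
       clusters = data.frame(chrom = chrom, strand = strand,
                             rep_start = rep_start, rep_end = rep_end,
                             size = size, stringsAsFactors = FALSE))
}

#' Check cyclic order concordance of a label sequence
#'
#' A read is a tandem traversal of its circle, so the cluster labels of its
#' sub-reads must be the periodic extension of a single fragment cycle (the
#' first k distinct labels in order of appearance). The phase of the RCA
#' reaction is random, so any rotation of the cycle is acceptable at the
#' start; within the sequence, `label[i + k]` must equal `label[i]`.
#'
#' @param labels integer (or atomic) label vector in rank order.
#' @return list with `accepted` (logical), `cycle` (labels in cycle order,
#'   `NULL` when rejected) and `reason` (`NA` or `"discordant_order"`).
#' @export
check_concordance <- function(labels) {
  n <- length(labels)
  cycle <- unique(labels)
  k <- length(cycle)
  ok <- all(labels == cycle[((seq_len(n) - 1L) %% k) + 1L])
  if (ok) list(accepted = TRUE, cycle = cycle, reason = NA_character_)
  else list(accepted = FALSE, cycle = NULL, reason = "discordant_order")
}

#' Count passes per fragment
#'
#' The pass count of a fragment is the number of concordant sub-reads mapped
#' to its locus; the read's number of full passes is the minimum over
#' fragments, i.e. every base of the circle was sequenced at least that many
#' times.
#'
#' @param labels concordant label sequence.
#' @param cycle fragment cycle as returned by [check_concordance()].
#' @return list with `counts` (per-fragment, in cycle order) and
#'   `full_passes`.
#' @export
count_passes <- function(labels, cycle) {
  counts <- vapply(cycle, function(id) sum(labels == id), integer(1))
  list(counts = counts, full_passes = min(counts))
}

#' Mode with deterministic tie-breaking
#'
#' Boundary voting: the most frequent value wins; when several values tie
#' for the highest count, the median of the tied values is taken, and for an
#' even number of tied values the smaller of the two central ones.
#'
#' @param v integer vector of candidate positions (non-empty).
#' @return the voted value.
#' @export
mode_vote <- function(v) {
  stopifnot(length(v) > 0L)
  tab <- table(v)
  tied <- sort(as.integer(names(tab)[tab == max(tab)]))
  tied[ceiling(length(tied) / 2)]
}

#' Vote a fragment boundary pair
#'
#' Start and end are voted independently from the member sub-reads'
#' positions; partial flanking sub-reads contribute only the boundary they
#' fully reach (via `extra_starts`/`extra_ends`).
#'
#' @param starts,ends member sub-read start/end positions.
#' @param extra_starts,extra_ends additional single-boundary votes.
#' @return integer vector `c(start, end)`.
#' @export
vote_boundaries <- function(starts, ends, extra_starts = integer(0),
                            extra_ends = integer(0)) {
  c(start = mode_vote(c(starts, extra_starts)),
    end = mode_vote(c(ends, extra_ends)))
}

#' Refine voted boundaries by threading sub-reads
#'
#' For each junction of the fragment cycle, the median unaligned query gap
#' between rank-adjacent sub-read pairs spanning that junction is computed;
#' the upstream fragment's 3' genomic boundary (in its strand orientation)
#' is extended by that gap (or trimmed by a query-space overlap) so that no
#' gaps or overlaps remain between successive sub-reads. Gaps beyond
#' `max_junction_gap` or overlaps beyond `max_query_overlap` leave the
#' junction flagged and the boundary untouched.
#'
#' @param fragments data.frame (`chrom`, `start`, `end`, `strand`) in cycle
#'   order, with voted boundaries.
#' @param labels trimmed concordant label sequence.
#' @param cycle cluster ids in cycle order.
#' @param sr trimmed sub-reads (rank order, matching `labels`).
#' @param params [caller_params()].
#' @return list with `ok`, `fragments` (adjusted), and `junctions`
#'   diagnostics (`junction`, `delta`, `applied`, `flagged`).
#' @export
thread_refine <- function(fragments, labels, cycle, sr, params = caller_params()) {
  k <- nrow(fragments)
  n <- length(labels)
  pos <- match(labels, cycle)
  delta <- rep(NA_real_, k)
  applied <- logical(k); flagged <- logical(k)
  if (n >= 2L) {
    gaps_by_junction <- vector("list", k)
    for (i in seq_len(n - 1L)) {
      p <- pos[i]
      pn <- pos[i + 1L]
      raw <- sr$qstart[i + 1L] - sr$qend[i]
      # residual gap once each sub-read is threaded onto the voted
      # boundaries: subtract the slack between the sub-read's aligned end
      # and its fragment's voted boundary on both sides of the junction
      slack_up <- if (fragments$strand[p] == "+") {
        fragments$end[p] - sr$tend[i]
      } else {
        sr$tstart[i] - fragments$start[p]
      }
      slack_down <- if (fragments$strand[pn] == "+") {
        sr$tstart[i + 1L] - fragments$start[pn]
      } else {
        fragments$end[pn] - sr$tend[i + 1L]
      }
      gaps_by_junction[[p]] <- c(gaps_by_junction[[p]],
                                 raw - slack_up - slack_down)
    }
    for (p in seq_len(k)) {
      g <- gaps_by_junction[[p]]
      if (is.null(g)) next
      d <- as.integer(round(stats::median(g)))
      delta[p] <- d
      if (d == 0L) next
      if ((d > 0L && d <= params$max_junction_gap) ||
          (d < 0L && -d <= params$max_query_overlap)) {
        if (fragments$strand[p] == "+") {
          fragments$end[p] <- fragments$end[p] + d
        } else {
          fragments$start[p] <- fragments$start[p] - d
        }
        applied[p] <- TRUE
      } else {
        flagged[p] <- TRUE
      }
    }
  }
  ok <- all(fragments$start < fragments$end)
  list(ok = ok, fragments = fragments,
       junctions = data.frame(junction = seq_len(k), delta = delta,
                              applied = applied, flagged = flagged))
}

# Identify partial flanking sub-reads: the first (last) alignment of a read
# may be a truncated copy of a fragment when the read starts (stops)
# mid-circle. Such a sub-read forms a singleton cluster that matches another
# cluster on exactly the boundary it fully reaches; it is excluded from the
# label sequence and pass counts and votes only for that boundary.
detect_partials <- function(sr, labels, clusters, params) {
  n <- nrow(sr)
  is_partial <- logical(n)
  start_votes <- rep(list(integer(0)), nrow(clusters))
  end_votes <- rep(list(integer(0)), nrow(clusters))
  off <- params$max_offset
  csize <- tabulate(labels, nbins = nrow(clusters))
  match_flank <- function(i, head) {
    c0 <- labels[i]
    if (csize[c0] != 1L) return(0L)
    for (j in seq_len(nrow(clusters))) {
      if (j == c0 || csize[j] == 0L) next
      if (clusters$chrom[j] != sr$tname[i] || clusters$strand[j] != sr$strand[i]) next
      plus <- sr$strand[i] == "+"
      # a head partial contains the end of the fragment traversal
      # (genomic end for '+', genomic start for '-'); a tail partial the start
      end_side <- if (head) plus else !plus
      if (end_side) {
        if (abs(sr$tend[i] - clusters$rep_end[j]) <= off &&
            sr$tstart[i] >= clusters$rep_start[j] - off) return(j)
      } else {
        if (abs(sr$tstart[i] - clusters$rep_start[j]) <= off &&
            sr$tend[i] <= clusters$rep_end[j] + off) return(j)
      }
    }
    0L
  }
  flank_vote <- function(i, j, head) {
    plus <- sr$strand[i] == "+"
    end_side <- if (head) plus else !plus
    if (end_side) end_votes[[j]] <<- c(end_votes[[j]], sr$tend[i])
    else start_votes[[j]] <<- c(start_votes[[j]], sr$tstart[i])
  }
  if (n >= 3L) {
    j <- match_flank(1L, head = TRUE)
    if (j > 0L) { is_partial[1L] <- TRUE; flank_vote(1L, j, head = TRUE) }
    j <- match_flank(n, head = FALSE)
    if (j > 0L) { is_partial[n] <- TRUE; flank_vote(n, j, head = FALSE) }
  }
  list(is_partial = is_partial, start_votes = start_votes, end_votes = end_votes)
}

# Two clusters at the same location (start and end both within max_offset)
# on the same chromosome but opposite strands mean the read traversed the
# locus in both orientations: strand discordance.
strand_discordant <- function(clusters, ids, params) {
  ids <- ids[ids > 0L]
  if (length(ids) < 2L) return(FALSE)
  off <- params$max_offset
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      i <- ids[a]; j <- ids[b]
      if (clusters$chrom[i] == clusters$chrom[j] &&
          clusters$strand[i] != clusters$strand[j] &&
          abs(clusters$rep_start[i] - clusters$rep_start[j]) <= off &&
          abs(clusters$rep_end[i] - clusters$rep_end[j]) <= off) return(TRUE)
    }
  }
  FALSE
}

reject_call <- function(read_id, reason, n_subreads = NA_integer_) {
  structure(list(read_id = read_id, status = "rejected", reason = reason,
                 n_subreads = n_subreads, fragments = NULL,
                 pass_counts = NULL, full_passes = NA_integer_,
                 circle_length = NA_integer_, junctions = NULL,
                 members = NULL),
            class = "ecc_call")
}

process_read <- function(sr, params) {
  read_id <- sr$qname[1L]
  n <- nrow(sr)
  if (n == 1L) return(reject_call(read_id, "single_hit", n))
  first <- process_subreads(sr, params, read_id, n)
  if (first$status == "accepted" || !identical(first$reason, "discordant_order")) {
    return(first)
  }
  # A clipped flanking sub-read seeded as a cluster representative can drift
  # the cluster and split later members. Terminal sub-reads are the only
  # candidates for such flanks, so retry with them excluded (they then cast
  # no votes); genuinely chimeric interior structure still rejects the read.
  if (n >= 3L) {
    for (drop in list(1L, n, c(1L, n))) {
      if (n - length(drop) < 2L) next
      att <- process_subreads(sr[-drop, , drop = FALSE], params, read_id, n)
      if (att$status == "accepted") return(att)
    }
  }
  first
}

process_subreads <- function(sr, params, read_id, n) {
  cl <- cluster_loci(sr, params)
  labels <- cl$labels
  clusters <- cl$clusters
  pf <- detect_partials(sr, labels, clusters, params)
  use <- !pf$is_partial
  lab <- labels[use]
  live <- unique(lab)
  if (strand_discordant(clusters, live, params))
    return(reject_call(read_id, "discordant_strand", n))
  if (!length(lab)) {
    # only partial flanks survived: zero full passes
    out <- reject_call(read_id, "insufficient_passes", n)
    out$full_passes <- 0L
    return(out)
  }
  conc <- check_concordance(lab)
  if (!conc$accepted) return(reject_call(read_id, conc$reason, n))
  cycle <- conc$cycle
  pc <- count_passes(lab, cycle)
  if (pc$full_passes < params$min_full_passes) {
    out <- reject_call(read_id, "insufficient_passes", n)
    out$full_passes <- pc$full_passes
    return(out)
  }
  k <- length(cycle)
  frag <- data.frame(chrom = clusters$chrom[cycle],
                     start = NA_integer_, end = NA_integer_,
                     strand = clusters$strand[cycle],
                     passes = pc$counts, stringsAsFactors = FALSE)
  members <- vector("list", k)
  sr_use <- sr[use, , drop = FALSE]
  for (p in seq_len(k)) {
    id <- cycle[p]
    m_all <- sr[labels == id, , drop = FALSE]          # full members
    b <- vote_boundaries(m_all$tstart, m_all$tend,
                         pf$start_votes[[id]], pf$end_votes[[id]])
    frag$start[p] <- b[["start"]]
    frag$end[p] <- b[["end"]]
    # pileup members: full members plus partial flanks attached to this cluster
    part_rows <- which(pf$is_partial &
                         vapply(seq_len(nrow(sr)), function(i) {
                           (sr$tname[i] == clusters$chrom[id] &&
                              sr$strand[i] == clusters$strand[id] &&
                              sr$tstart[i] >= clusters$rep_start[id] - params$max_offset &&
                              sr$tend[i] <= clusters$rep_end[id] + params$max_offset)
                         }, logical(1)))
    mem <- rbind(m_all, sr[part_rows, , drop = FALSE])
    mem$partial <- c(rep(FALSE, nrow(m_all)), rep(TRUE, length(part_rows)))
    members[[p]] <- mem
  }
  tr <- thread_refine(frag, lab, cycle, sr_use, params)
  if (!tr$ok) return(reject_call(read_id, "discordant_location", n))
  frag <- tr$fragments
  structure(list(read_id = read_id, status = "accepted", reason = NA_character_,
                 n_subreads = n, fragments = frag, pass_counts = frag$passes,
                 full_passes = pc$full_passes,
                 circle_length = sum(frag$end - frag$start),
                 junctions = tr$junctions, members = members,
                 qspan = sum(sr_use$qend - sr_use$qstart)),
            class = "ecc_call")
}

#' Call eccDNA circles from PAF alignments
#'
#' Full per-read reconstruction: mapping-quality filtering, locus
#' clustering, cyclic-concordance checking, boundary voting, threading
#' refinement and the full-pass filter. Every read yields either an accepted
#' circle call or a rejection with a reason (`single_hit`, `low_mapq`,
#' `discordant_order`, `discordant_strand`, `discordant_location`,
#' `insufficient_passes`); rejections are values, never errors.
#'
#' @param paf a PAF data.frame from [parse_paf()], a character vector of PAF
#'   lines, or a file path.
#' @param params [caller_params()].
#' @return an `ecc_calls` object: a list of per-read `ecc_call` entries with
#'   the parameters attached. `as.data.frame()` gives the call table.
#' @export
call_circles <- function(paf, params = caller_params()) {
  if (is.character(paf)) {
    paf <- if (length(paf) == 1L && file.exists(paf)) read_paf(paf) else parse_paf(paf)
  }
  sr <- filter_subreads(paf, params)
  calls <- list()
  for (read_id in attr(sr, "dropped")) {
    calls[[length(calls) + 1L]] <- reject_call(read_id, "low_mapq", 0L)
  }
  if (nrow(sr)) {
    by_read <- split(seq_len(nrow(sr)), factor(sr$qname, levels = unique(sr$qname)))
    for (idx in by_read) {
      calls[[length(calls) + 1L]] <- process_read(sr[idx, , drop = FALSE], params)
    }
  }
  structure(list(calls = calls, params = params), class = "ecc_calls")
}

#' @export
as.data.frame.ecc_calls <- function(x, ...) {
  rows <- lapply(x$calls, function(cc) {
    data.frame(read_id = cc$read_id, status = cc$status,
               reason = if (is.na(cc$reason)) "" else cc$reason,
               n_fragments = if (is.null(cc$fragments)) 0L else nrow(cc$fragments),
               full_passes = cc$full_passes,
               circle_length = cc$circle_length,
               fragments = if (is.null(cc$fragments)) "" else
                 fragments_string(cc$fragments),
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(), status = character(),
                      reason = character(), n_fragments = integer(),
                      full_passes = integer(), circle_length = integer(),
                      fragments = character(), stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.ecc_calls <- function(x, ...) {
  df <- as.data.frame(x)
  acc <- sum(df$status == "accepted")
  cat(sprintf("eccDNA calls: %d reads, %d accepted, %d rejected\n",
              nrow(df), acc, nrow(df) - acc))
  if (nrow(df)) {
    tab <- table(df$reason[df$status == "rejected"])
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Accepted calls of an `ecc_calls` object
#'
#' @param x `ecc_calls`.
#' @return list of accepted `ecc_call` entries.
#' @export
accepted_calls <- function(x) {
  Filter(function(cc) cc$status == "accepted", x$calls)
}

fragments_string <- function(fragments) {
  paste(sprintf("%s:%d-%d:%s", fragments$chrom, fragments$start,
                fragments$end, fragments$strand), collapse = ";")
}

parse_fragments_string <- function(s) {
  if (!nzchar(s)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  coords <- vapply(parts, function(p) p[length(p) - 1L], character(1))
  se <- do.call(rbind, strsplit(coords, "-", fixed = TRUE))
  data.frame(chrom = vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)],
                                                     collapse = ":"), character(1)),
             start = as.integer(se[, 1]), end = as.integer(se[, 2]),
             strand = vapply(parts, function(p) p[length(p)], character(1)),
             stringsAsFactors = FALSE)
}

#' Write the eccDNA call table
#'
#' @param calls `ecc_calls` object.
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_call_table <- function(calls, path) {
  df <- as.data.frame(calls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write accepted circles as BED
#'
#' Single-chromosome circles whose fragments do not overlap are written as
#' BED12 (blocks = fragments); all fragments of every accepted circle are
#' additionally written per-fragment as BED6 in a companion file, which is
#' the only representation possible for multi-chromosome circles.
#'
#' @param calls `ecc_calls` object.
#' @param bed12_path,bed6_path output paths.
#' @return invisible `NULL`.
#' @export
write_circle_bed <- function(calls, bed12_path, bed6_path) {
  acc <- accepted_calls(calls)
  bed12 <- character(0); bed6 <- character(0)
  for (cc in acc) {
    f <- cc$fragments
    bed6 <- c(bed6, sprintf("%s\t%d\t%d\t%s\t%d\t%s", f$chrom, f$start, f$end,
                            cc$read_id, cc$full_passes, f$strand))
    if (length(unique(f$chrom)) == 1L) {
      o <- order(f$start)
      fs <- f[o, , drop = FALSE]
      if (all(fs$start[-1] >= fs$end[-nrow(fs)])) {
        chrom_start <- min(fs$start); chrom_end <- max(fs$end)
        bed12 <- c(bed12, sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%s\t%s",
                                  fs$chrom[1], chrom_start, chrom_end, cc$read_id,
                                  cc$full_passes, fs$strand[1], chrom_start, chrom_end,
                                  nrow(fs),
                                  paste0(paste(fs$end - fs$start, collapse = ","), ","),
                                  paste0(paste(fs$start - chrom_start, collapse = ","), ",")))
      }
    }
  }
  writeLines(bed12, bed12_path)
  writeLines(bed6, bed6_path)
  invisible(NULL)
}
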