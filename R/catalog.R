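#' Canonicalize a fragment cycle
#'
#' Two reads of the same circular molecule may start at any rotation of the
#' fragment cycle and may traverse it in either orientation. Among all
#' rotations of the forward traversal and of the reverse traversal
#' (fragments in reverse order with strands flipped), the one whose
#' `(chrom, start, end, strand)` tuple sequence is lexicographically
#' smallest is chosen; its serialisation is the circle's identity key.
#'
#' @param fragments data.frame (`chrom`, `start`, `end`, `strand`) in cycle
#'   order.
#' @return list: `key` (character), `fragments` (canonically ordered
#'   data.frame), `order` (indices into the input rows), `flipped` (was the
#'   reverse traversal chosen).
#' @export
canonicalize_circle <- function(fragments) {
  k <- nrow(fragments)
  flip <- function(s) ifelse(s == "+", "-", "+")
  fwd <- fragments[, c("chrom", "start", "end", "strand"), drop = FALSE]
  bwd <- fwd[rev(seq_len(k)), , drop = FALSE]
  bwd$strand <- flip(bwd$strand)
  cand_keys <- character(2L * k)
  cand_meta <- vector("list", 2L * k)
  for (r in seq_len(k)) {
    ord <- c(seq.int(r, k), if (r > 1L) seq.int(1L, r - 1L))
    f1 <- fwd[ord, , drop = FALSE]
    cand_keys[r] <- fragments_string(f1)
    cand_meta[[r]] <- list(fragments = f1, order = ord, flipped = FALSE)
    f2 <- bwd[ord, , drop = FALSE]
    cand_keys[k + r] <- fragments_string(f2)
    cand_meta[[k + r]] <- list(fragments = f2,
                               order = rev(seq_len(k))[ord], flipped = TRUE)
  }
  best <- order(cand_keys)[1L]
  m <- cand_meta[[best]]
  frags <- m$fragments
  rownames(frags) <- NULL
  list(key = cand_keys[best], fragments = frags, order = m$order,
       flipped = m$flipped)
}

#' Deduplicate accepted circles into unique eccDNAs
#'
#' Circles with identical canonical fragment cycles are the same molecule;
#' the number of distinct supporting long reads is the unique eccDNA's event
#' count. Single-fragment circles are "continuous", multi-fragment circles
#' "non-continuous".
#'
#' @param calls an `ecc_calls` object or a list of accepted `ecc_call`s.
#' @return data.frame (`key`, `n_fragments`, `circle_length`, `event_count`,
#'   `continuity`) with the canonical fragment tables in the `"fragments"`
#'   attribute (a named list keyed by `key`).
#' @export
deduplicate_circles <- function(calls) {
  acc <- if (inherits(calls, "ecc_calls")) accepted_calls(calls) else calls
  keys <- character(length(acc))
  frag_by_key <- list()
  lens <- integer(length(acc)); nf <- integer(length(acc))
  for (i in seq_along(acc)) {
    canon <- canonicalize_circle(acc[[i]]$fragments)
    keys[i] <- canon$key
    lens[i] <- sum(canon$fragments$end - canon$fragments$start)
    nf[i] <- nrow(canon$fragments)
    if (is.null(frag_by_key[[canon$key]])) frag_by_key[[canon$key]] <- canon$fragments
  }
  if (!length(acc)) {
    out <- data.frame(key = character(), n_fragments = integer(),
                      circle_length = integer(), event_count = integer(),
                      continuity = character(), stringsAsFactors = FALSE)
    attr(out, "fragments") <- list()
    return(out)
  }
  first <- !duplicated(keys)
  event_count <- as.integer(table(keys)[keys[first]])
  out <- data.frame(key = keys[first], n_fragments = nf[first],
                    circle_length = lens[first], event_count = event_count,
                    continuity = ifelse(nf[first] == 1L, "continuous",
                                        "non_continuous"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fragments") <- frag_by_key
  out
}

#' Deduplicate eccDNA fragments
#'
#' Fragments with the same chromosome, start and end are duplicates and only
#' one is retained; strand is ignored (coverage is strandless).
#'
#' @param x an `ecc_calls` object, a list of `ecc_call`s, or a fragment
#'   data.frame.
#' @return data.frame of unique fragments (`chrom`, `start`, `end`).
#' @export
deduplicate_fragments <- function(x) {
  if (inherits(x, "ecc_calls")) x <- accepted_calls(x)
  if (is.data.frame(x)) {
    frags <- x
  } else {
    frags <- rbind_rows(lapply(x, `[[`, "fragments"))
  }
  if (is.null(frags) || !nrow(frags)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  frags <- frags[, c("chrom", "start", "end"), drop = FALSE]
  frags <- frags[!duplicated(frags), , drop = FALSE]
  frags <- frags[order(frags$chrom, frags$start, frags$end), , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

#' Event-count distribution of unique eccDNAs
#'
#' Fraction of unique eccDNAs supported by 1, 2, 3 or more than 3 distinct
#' long reads; an event count of 1 defines a single-event eccDNA.
#'
#' @param uniques data.frame from [deduplicate_circles()].
#' @return data.frame (`events`, `count`, `fraction`); zero rows for an
#'   empty catalog.
#' @export
event_count_distribution <- function(uniques) {
  if (!nrow(uniques)) {
    return(data.frame(events = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  ev <- uniques$event_count
  bins <- c("1" = sum(ev == 1L), "2" = sum(ev == 2L), "3" = sum(ev == 3L),
            ">3" = sum(ev > 3L))
  data.frame(events = names(bins), count = as.integer(bins),
             fraction = as.numeric(bins) / length(ev),
             stringsAsFactors = FALSE)
}

#' Per-base coverage of unique fragments
#'
#' Each deduplicated fragment contributes once; per-base counts are the
#' number of unique fragments overlapping each base, emitted as sorted
#' merged-run bedGraph records (zero runs omitted).
#'
#' @param fragments unique-fragment data.frame from
#'   [deduplicate_fragments()].
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @return list of class `ecc_coverage`: `coverage` (an
#'   [IRanges::RleList]) and `bedgraph` (data.frame `chrom`, `start`, `end`,
#'   `value`, 0-based half-open).
#' @export
coverage_bedgraph <- function(fragments, chrom_sizes) {
  sl <- stats::setNames(as.integer(chrom_sizes$length), chrom_sizes$chrom)
  if (nrow(fragments)) {
    bad <- fragments$end > sl[fragments$chrom]
    if (any(is.na(bad)) || any(bad)) {
      stop("fragment beyond chromosome end (or unknown chromosome)",
           call. = FALSE)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(fragments)) fragments$chrom else character(0),
    ranges = IRanges::IRanges(start = fragments$start + 1L, end = fragments$end),
    seqlengths = sl)
  cov <- GenomicRanges::coverage(gr)
  rows <- list()
  for (chrom in names(cov)) {
    r <- cov[[chrom]]
    v <- S4Vectors::runValue(r)
    len <- S4Vectors::runLength(r)
    ends <- cumsum(len)
    starts <- ends - len
    keep <- v > 0L
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(starts[keep]),
        end = as.integer(ends[keep]), value = as.integer(v[keep]),
        stringsAsFactors = FALSE)
    }
  }
  bg <- rbind_rows(rows)
  if (is.null(bg)) {
    bg <- data.frame(chrom = character(), start = integer(), end = integer(),
                     value = integer(), stringsAsFactors = FALSE)
  }
  structure(list(coverage = cov, bedgraph = bg), class = "ecc_coverage")
}

#' Write a bedGraph file
#'
#' @param coverage an `ecc_coverage` object.
#' @param path output path.
#' @return invisible `NULL`.
#' @export
write_bedgraph <- function(coverage, path) {
  bg <- coverage$bedgraph
  writeLines(sprintf("%s\t%d\t%d\t%d", bg$chrom, bg$start, bg$end, bg$value),
             path)
  invisible(NULL)
}

#' Estimate the periodic size interval of a circle-length distribution
#'
#' Apoptotic eccDNA lengths fall on a nucleosomal ladder; the average
#' spacing between successive peaks of the size histogram estimates its
#' period (about 188 bp). Lengths are binned at 1 bp over `[0, max_len]`,
#' smoothed with a centered moving average, and local maxima with
#' topographic prominence of at least `min_prom_frac` of the global maximum
#' are retained; the statistic is the mean spacing of successive peaks.
#'
#' @param lengths integer circle lengths (bp).
#' @param max_len histogram upper bound (bp).
#' @param window moving-average window (odd).
#' @param min_prom_frac minimum peak prominence as a fraction of the global
#'   maximum of the smoothed histogram.
#' @param min_sep peaks closer than this (bp) are merged, keeping the
#'   higher; histogram-count noise puts small wiggles on top of each true
#'   peak.
#' @param max_spacing_cv the statistic is a period, so it is reported only
#'   when the peak spacings are regular: coefficient of variation of
#'   successive spacings at most this value (aperiodic length distributions
#'   produce irregularly spaced noise peaks and an undefined result).
#' @return list: `interval` (bp; `NA` when fewer than 2 regular peaks) and
#'   `peaks` (positions in bp).
#' @export
size_interval_statistic <- function(lengths, max_len = 3000L, window = 11L,
                                    min_prom_frac = 0.05, min_sep = 50L,
                                    max_spacing_cv = 0.3) {
  lengths <- as.integer(round(lengths))
  lengths <- lengths[lengths >= 1L & lengths <= max_len]
  undefined <- list(interval = NA_real_, peaks = numeric(0))
  if (!length(lengths)) return(undefined)
  counts <- tabulate(lengths, nbins = max_len)
  sm <- as.numeric(stats::filter(counts, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- 0
  peaks <- find_peaks(sm, min_prom = min_prom_frac * max(sm))
  peaks <- merge_close_peaks(peaks, sm, min_sep)
  if (length(peaks) < 2L) {
    return(list(interval = NA_real_, peaks = as.numeric(peaks)))
  }
  spacing <- diff(peaks)
  if (length(spacing) > 1L &&
      stats::sd(spacing) / mean(spacing) > max_spacing_cv) {
    return(list(interval = NA_real_, peaks = as.numeric(peaks)))
  }
  list(interval = mean(spacing), peaks = as.numeric(peaks))
}

# collapse peaks closer than min_sep, keeping the higher of each pair
merge_close_peaks <- function(peaks, y, min_sep) {
  while (length(peaks) >= 2L) {
    d <- diff(peaks)
    i <- which(d < min_sep)
    if (!length(i)) break
    i <- i[1L]
    drop <- if (y[peaks[i]] >= y[peaks[i + 1L]]) i + 1L else i
    peaks <- peaks[-drop]
  }
  peaks
}

# Local maxima with topographic prominence: for each candidate peak, walk
# outward on each side to the nearest strictly higher point (or the edge),
# tracking the minimum along the way; prominence is the peak height minus
# the higher of the two minima.
find_peaks <- function(y, min_prom) {
  n <- length(y)
  d <- diff(y)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    h <- y[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
    keep[ci] <- (h - max(lmin, rmin)) >= min_prom
  }
  cand[keep]
}

#' Histogram of fragment counts per unique eccDNA
#'
#' @param uniques data.frame from [deduplicate_circles()].
#' @return list: `counts` (named integer vector over 1..max fragment count),
#'   `continuous`, `non_continuous` totals.
#' @export
fragment_count_histogram <- function(uniques) {
  if (!nrow(uniques)) {
    return(list(counts = integer(0), continuous = 0L, non_continuous = 0L))
  }
  mx <- max(uniques$n_fragments)
  counts <- tabulate(uniques$n_fragments, nbins = mx)
  names(counts) <- seq_len(mx)
  list(counts = counts,
       continuous = sum(uniques$n_fragments == 1L),
       non_continuous = sum(uniques$n_fragments > 1L))
}

#' Chromosome pairing of two-fragment eccDNAs
#'
#' @param uniques data.frame from [deduplicate_circles()] (with the
#'   `"fragments"` attribute).
#' @return data.frame (`chromA`, `chromB`, `count`); unordered pairs,
#'   `chromA <= chromB`.
#' @export
interchromosomal_pairs <- function(uniques) {
  frag_by_key <- attr(uniques, "fragments")
  two <- uniques$key[uniques$n_fragments == 2L]
  if (!length(two)) {
    return(data.frame(chromA = character(), chromB = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  pairs <- vapply(two, function(key) {
    ch <- sort(frag_by_key[[key]]$chrom)
    paste(ch[1L], ch[2L], sep = "\r")
  }, character(1))
  tab <- table(pairs)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(chromA = parts[, 1], chromB = parts[, 2],
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$chromA, out$chromB), , drop = FALSE]
}

#' Per-chromosome eccDNA density and X/autosome ratio
#'
#' Density is the covered base mass (total unique-fragment bases) divided by
#' the chromosome length. In a diploid male genome the X is present in one
#' copy against two autosomal copies, so its density is expected to be about
#' half the autosomal mean.
#'
#' @param fragments unique-fragment data.frame.
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @return list: `table` (data.frame `chrom`, `covered_bases`, `density`)
#'   and `x_autosome_ratio` (`NA` when no X chromosome is present).
#' @export
chromosome_density <- function(fragments, chrom_sizes) {
  mass <- stats::setNames(rep(0, nrow(chrom_sizes)), chrom_sizes$chrom)
  if (nrow(fragments)) {
    by_chrom <- tapply(fragments$end - fragments$start, fragments$chrom, sum)
    mass[names(by_chrom)] <- as.numeric(by_chrom)
  }
  tab <- data.frame(chrom = chrom_sizes$chrom,
                    covered_bases = as.numeric(mass),
                    density = as.numeric(mass) / as.numeric(chrom_sizes$length),
                    stringsAsFactors = FALSE)
  is_x <- is_x_chrom(tab$chrom)
  is_auto <- !is_x & !tab$chrom %in% c("chrY", "Y", "chrM", "MT", "chrMT", "M")
  ratio <- if (any(is_x) && any(is_auto)) {
    tab$density[is_x][1L] / mean(tab$density[is_auto])
  } else NA_real_
  list(table = tab, x_autosome_ratio = ratio)
}

#' Full catalog statistics
#'
#' Bundles the unique-eccDNA table, event-count fractions, fragment-count
#' histogram, two-fragment chromosome pairing, size-interval statistic,
#' per-chromosome density and coverage conservation into one JSON-ready
#' list.
#'
#' @param calls an `ecc_calls` object (or list of accepted calls).
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @return list of class `ecc_stats`.
#' @export
catalog_stats <- function(calls, chrom_sizes) {
  uniques <- deduplicate_circles(calls)
  frags <- deduplicate_fragments(calls)
  cov <- coverage_bedgraph(frags, chrom_sizes)
  ecd <- event_count_distribution(uniques)
  fch <- fragment_count_histogram(uniques)
  sis <- size_interval_statistic(uniques$circle_length)
  dens <- chromosome_density(frags, chrom_sizes)
  n <- nrow(uniques)
  structure(list(
    n_unique_eccdna = n,
    n_unique_fragments = nrow(frags),
    total_events = if (n) sum(uniques$event_count) else 0L,
    median_circle_length = if (n) stats::median(uniques$circle_length) else NA_real_,
    event_count_fractions = if (nrow(ecd)) {
      stats::setNames(as.list(ecd$fraction), ecd$events)
    } else NULL,
    single_event_fraction = if (n) mean(uniques$event_count == 1L) else NA_real_,
    fragment_count_histogram = as.list(fch$counts),
    continuous = fch$continuous,
    non_continuous = fch$non_continuous,
    size_interval_bp = sis$interval,
    size_peaks_bp = sis$peaks,
    chromosome_density = dens$table,
    x_autosome_ratio = dens$x_autosome_ratio,
    coverage_mass = sum(as.numeric(cov$bedgraph$value) *
                          (cov$bedgraph$end - cov$bedgraph$start)),
    uniques = uniques,
    coverage = cov
  ), class = "ecc_stats")
}
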