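#' Pile up sub-read alleles over a fragment
#'
#' Walks each member sub-read's cs operations from its target start and
#' accumulates per-position allele counts over the fragment's reference
#' interval. Matches count toward the reference allele (`.`), substitutions
#' toward their alternative base, deletions cover their positions with a
#' `-` allele, and insertions anchor to the preceding reference position
#' (counted separately, prefixed `+`, so that non-insertion allele counts
#' partition the depth). Sub-reads without a short-form cs string carry no
#' base-level information and are skipped; when none has one the pileup is
#' unavailable and the fragment is reference-only.
#'
#' @param fragment one-row data.frame (`chrom`, `start`, `end`, `strand`).
#' @param members data.frame of member sub-reads with `tstart` and `cs`.
#' @param params [consensus_params()].
#' @return an `ecc_pileup` (list with `fragment` and `counts`: `pos`,
#'   `allele`, `ref`, `count`), or `NULL` when no cs is available.
#' @export
fragment_pileup <- function(fragment, members, params = consensus_params()) {
  lo <- fragment$start
  hi <- fragment$end
  usable <- which(cs_is_short(members$cs))
  if (!length(usable)) return(NULL)
  pos_l <- list(); allele_l <- list(); ref_l <- list()
  add <- function(pos, allele, ref) {
    i <- length(pos_l) + 1L
    pos_l[[i]] <<- pos; allele_l[[i]] <<- allele; ref_l[[i]] <<- ref
  }
  for (i in usable) {
    ops <- parse_cs(members$cs[i])
    p <- members$tstart[i]
    for (o in seq_len(nrow(ops))) {
      kind <- ops$kind[o]; len <- ops$length[o]
      if (kind == "match_run") {
        add(seq.int(p, length.out = len), rep(".", len), rep("", len))
        p <- p + len
      } else if (kind == "substitution") {
        add(p, toupper(ops$query[o]), toupper(ops$ref[o]))
        p <- p + 1L
      } else if (kind == "deletion") {
        add(seq.int(p, length.out = len), rep("-", len),
            strsplit(toupper(ops$ref[o]), "")[[1L]])
        p <- p + len
      } else { # insertion
        if (len <= params$max_ins_len) {
          add(p - 1L, paste0("+", toupper(ops$query[o])), "")
        }
      }
    }
  }
  pos <- unlist(pos_l, use.names = FALSE)
  allele <- unlist(allele_l, use.names = FALSE)
  ref <- unlist(ref_l, use.names = FALSE)
  keep <- pos >= lo & pos < hi
  pos <- pos[keep]; allele <- allele[keep]; ref <- ref[keep]
  key <- paste(pos, allele, ref, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  counts <- data.frame(
    pos = as.integer(vapply(parts, `[`, character(1), 1L)),
    allele = vapply(parts, `[`, character(1), 2L),
    # trailing empty ref fields are dropped by strsplit
    ref = vapply(parts, function(x) if (length(x) >= 3L) x[3L] else "", character(1)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  counts <- counts[order(counts$pos, counts$allele), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(fragment = fragment, counts = counts), class = "ecc_pileup")
}

#' Call variants from a fragment pileup
#'
#' A variant is emitted at a position when the pileup depth (sub-reads
#' covering the position) is at least `min_depth` and the alternative
#' allele's frequency is at least `min_af`; at most one variant per position
#' (highest frequency; ties broken by the lexicographically smaller
#' alternative allele). Adjacent called deletion positions are merged into
#' one deletion. Calls within `boundary_mask` bp of a fragment boundary are
#' suppressed (junction jitter stacks artifactual mismatches there) and
#' returned in the `"masked"` attribute.
#'
#' @param pileup an `ecc_pileup` (or `NULL`).
#' @param params [consensus_params()].
#' @return data.frame: `chrom`, `pos` (0-based), `kind` (`snv`/`ins`/`del`),
#'   `ref`, `alt`, `depth`, `alt_count`, `af`.
#' @export
call_variants <- function(pileup, params = consensus_params()) {
  empty <- data.frame(chrom = character(), pos = integer(), kind = character(),
                      ref = character(), alt = character(), depth = integer(),
                      alt_count = integer(), af = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(pileup) || !nrow(pileup$counts)) {
    attr(empty, "masked") <- empty
    return(empty)
  }
  counts <- pileup$counts
  is_ins <- startsWith(counts$allele, "+")
  depth_tab <- tapply(counts$count[!is_ins], counts$pos[!is_ins], sum)
  cand <- counts[counts$allele != ".", , drop = FALSE]
  if (!params$indels) {
    cand <- cand[cand$allele %in% c("A", "C", "G", "T"), , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    depth <- unname(depth_tab[as.character(cand$pos[i])])
    if (is.na(depth) || depth < params$min_depth) next
    af <- cand$count[i] / depth
    if (af < params$min_af) next
    allele <- cand$allele[i]
    kind <- if (allele == "-") "del"
            else if (startsWith(allele, "+")) "ins" else "snv"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = pileup$fragment$chrom, pos = cand$pos[i], kind = kind,
      ref = if (kind == "ins") "" else cand$ref[i],
      alt = if (kind == "del") "" else if (kind == "ins") substring(allele, 2L) else allele,
      depth = as.integer(depth), alt_count = cand$count[i], af = af,
      stringsAsFactors = FALSE)
  }
  out <- rbind_rows(rows)
  if (is.null(out)) out <- empty
  # one variant per position: highest AF, then lexicographically smaller alt
  if (nrow(out) > 1L) {
    out <- out[order(out$pos, -out$af, out$alt), , drop = FALSE]
    out <- out[!duplicated(out$pos), , drop = FALSE]
  }
  # boundary suppression
  mask <- params$boundary_mask
  near <- out$pos < pileup$fragment$start + mask |
    out$pos >= pileup$fragment$end - mask
  masked <- out[near, , drop = FALSE]
  out <- out[!near, , drop = FALSE]
  # merge runs of adjacent deletion positions
  out <- merge_deletions(out)
  rownames(out) <- NULL
  attr(out, "masked") <- masked
  out
}

merge_deletions <- function(variants) {
  if (!nrow(variants)) return(variants)
  is_del <- variants$kind == "del"
  if (!any(is_del)) return(variants)
  keep <- rep(TRUE, nrow(variants))
  dels <- which(is_del)
  run_start <- dels[1L]
  flush <- function(run_start, run_end) {
    variants$ref[run_start] <<- paste(variants$ref[run_start:run_end], collapse = "")
    variants$depth[run_start] <<- min(variants$depth[run_start:run_end])
    variants$alt_count[run_start] <<- min(variants$alt_count[run_start:run_end])
    variants$af[run_start] <<- min(variants$af[run_start:run_end])
    if (run_end > run_start) keep[(run_start + 1L):run_end] <<- FALSE
  }
  prev <- dels[1L]
  for (d in dels[-1L]) {
    contiguous <- (d == prev + 1L) && (variants$pos[d] == variants$pos[prev] + 1L)
    if (!contiguous) { flush(run_start, prev); run_start <- d }
    prev <- d
  }
  flush(run_start, prev)
  variants[keep, , drop = FALSE]
}

#' Call variants for every fragment of a circle
#'
#' @param call accepted `ecc_call`.
#' @param params [consensus_params()].
#' @return data.frame of variants with a `fragment` index column; fragments
#'   without cs support contribute no rows.
#' @export
circle_variants <- function(call, params = consensus_params()) {
  rows <- list()
  for (p in seq_len(nrow(call$fragments))) {
    pu <- fragment_pileup(call$fragments[p, , drop = FALSE],
                          call$members[[p]], params)
    v <- call_variants(pu, params)
    if (nrow(v)) {
      v$fragment <- p
      rows[[length(rows) + 1L]] <- v
    }
  }
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), kind = character(),
                      ref = character(), alt = character(), depth = integer(),
                      alt_count = integer(), af = numeric(), fragment = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

apply_variants_to_seq <- function(s, fr, v) {
  if (!nrow(v)) return(s)
  v <- v[order(-v$pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    off <- v$pos[i] - fr$start + 1L
    if (v$kind[i] == "snv") {
      substr(s, off, off) <- v$alt[i]
    } else if (v$kind[i] == "del") {
      d <- nchar(v$ref[i])
      s <- paste0(substr(s, 1L, off - 1L), substring(s, off + d))
    } else { # ins, after anchor base
      s <- paste0(substr(s, 1L, off), v$alt[i], substring(s, off + 1L))
    }
  }
  s
}

#' Build the full-length consensus sequence of a circle
#'
#' Each fragment's sequence is the reference substring over its refined
#' interval with the called variants incorporated (on the plus strand),
#' reverse-complemented for minus-strand fragments, and the fragments are
#' concatenated in cycle order. By default the cycle is first rotated and
#' oriented canonically (see [canonicalize_circle()]) so that identical
#' circles observed from different reads produce identical strings.
#'
#' @param call accepted `ecc_call`.
#' @param reference a [Biostrings::DNAStringSet], a `generate_reference()`
#'   result, or a FASTA path.
#' @param params [consensus_params()].
#' @param variants optional precomputed [circle_variants()] table.
#' @param canonical start at the canonical fragment in canonical
#'   orientation; `FALSE` keeps the call's own cycle order and strands.
#' @return an `ecc_consensus` (list: `read_id`, `seq`, `fragments`,
#'   `variants`).
#' @export
build_consensus <- function(call, reference, params = consensus_params(),
                            variants = NULL, canonical = TRUE) {
  ref <- as_reference(reference)
  if (is.null(variants)) variants <- circle_variants(call, params)
  frags <- call$fragments
  ord <- seq_len(nrow(frags))
  if (canonical) {
    canon <- canonicalize_circle(frags)
    frags <- canon$fragments
    ord <- canon$order
  }
  pieces <- character(nrow(frags))
  for (p in seq_len(nrow(frags))) {
    fr <- frags[p, ]
    if (!fr$chrom %in% names(ref)) {
      stop(sprintf("fragment %d: chromosome '%s' absent from reference",
                   p, fr$chrom), call. = FALSE)
    }
    if (fr$end > length(ref[[fr$chrom]]) || fr$start < 0L) {
      stop(sprintf("fragment %d (%s:%d-%d) exceeds chromosome bounds",
                   p, fr$chrom, fr$start, fr$end), call. = FALSE)
    }
    s <- as.character(Biostrings::subseq(ref[[fr$chrom]], fr$start + 1L, fr$end))
    v <- variants[variants$fragment == ord[p], , drop = FALSE]
    s <- apply_variants_to_seq(s, fr, v)
    if (fr$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    pieces[p] <- s
  }
  structure(list(read_id = call$read_id, seq = paste(pieces, collapse = ""),
                 fragments = frags, variants = variants),
            class = "ecc_consensus")
}

as_reference <- function(reference) {
  if (is.list(reference) && !is.null(reference$ref)) return(reference$ref)
  if (is.character(reference)) return(Biostrings::readDNAStringSet(reference))
  reference
}

#' Write consensus sequences as FASTA
#'
#' @param consensuses list of `ecc_consensus` objects.
#' @param path output FASTA path.
#' @param calls optional `ecc_calls` to annotate pass counts in headers.
#' @return invisible `NULL`.
#' @export
write_consensus_fasta <- function(consensuses, path, calls = NULL) {
  if (!length(consensuses)) {
    writeLines(character(0), path)
    return(invisible(NULL))
  }
  seqs <- Biostrings::DNAStringSet(vapply(consensuses, `[[`, character(1), "seq"))
  names(seqs) <- vapply(consensuses, function(co) {
    sprintf("%s fragments=%s n_variants=%d", co$read_id,
            fragments_string(co$fragments), nrow(co$variants))
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(NULL)
}

#' Write a variant table
#'
#' Minimal VCF-like TSV; positions are reported 1-based.
#'
#' @param variants data.frame from [circle_variants()] (may carry a
#'   `read_id` column).
#' @param path output path.
#' @return invisible `NULL`.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants
  if (nrow(out)) out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
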