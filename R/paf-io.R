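PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend",
              "nmatch", "alnlen", "mapq")
PAF_INT_COLS <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
                  "nmatch", "alnlen", "mapq")

empty_paf <- function() {
  df <- data.frame(qname = character(), qlen = integer(),
                   qstart = integer(), qend = integer(),
                   strand = character(), tname = character(),
                   tlen = integer(), tstart = integer(), tend = integer(),
                   nmatch = integer(), alnlen = integer(), mapq = integer(),
                   cs = character(), tags = character(),
                   stringsAsFactors = FALSE)
  df
}

#' Parse PAF alignment lines
#'
#' Parses minimap2-style PAF (pairwise alignment format): twelve mandatory
#' tab-separated columns per line, followed by optional SAM-style typed tags.
#' Coordinates are 0-based half-open on both query and target, as emitted by
#' the aligner. A `cs:Z:` difference tag, when present, is lifted into its
#' own `cs` column (needed downstream for variant pileups); all other tags
#' are preserved verbatim in `tags` so that records round-trip losslessly
#' (including `tp:A:` primary/secondary flags).
#'
#' @param lines character vector of PAF lines (empty lines ignored).
#' @return data.frame with columns `qname, qlen, qstart, qend, strand, tname,
#'   tlen, tstart, tend, nmatch, alnlen, mapq, cs, tags`; one row per record,
#'   in input order. `cs` is `NA` when the tag is absent.
#' @export
parse_paf <- function(lines) {
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad)) {
    stop(sprintf("PAF parse error at line %d: expected >= 12 tab-separated columns, found %d",
                 lineno[bad[1L]], nf[bad[1L]]), call. = FALSE)
  }
  core <- matrix(unlist(lapply(fields, `[`, 1:12), use.names = FALSE),
                 ncol = 12L, byrow = TRUE)
  ints <- suppressWarnings(matrix(as.integer(core[, c(2, 3, 4, 7, 8, 9, 10, 11, 12)]),
                                  ncol = 9L))
  if (anyNA(ints)) {
    bad <- which(apply(is.na(ints), 1L, any))[1L]
    stop(sprintf("PAF parse error at line %d: non-integer coordinate field",
                 lineno[bad]), call. = FALSE)
  }
  strand <- core[, 5]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("PAF parse error at line %d: strand must be '+' or '-', found '%s'",
                 lineno[bad[1L]], strand[bad[1L]]), call. = FALSE)
  }
  cs <- rep(NA_character_, length(lines))
  tags <- character(length(lines))
  has_extra <- nf > 12L
  if (any(has_extra)) {
    for (i in which(has_extra)) {
      extra <- fields[[i]][-(1:12)]
      is_cs <- startsWith(extra, "cs:Z:")
      if (any(is_cs)) cs[i] <- sub("^cs:Z:", "", extra[which(is_cs)[1L]])
      rest <- extra[!is_cs]
      if (length(rest)) tags[i] <- paste(rest, collapse = "\t")
    }
  }
  data.frame(qname = core[, 1], qlen = ints[, 1],
             qstart = ints[, 2], qend = ints[, 3],
             strand = strand, tname = core[, 6],
             tlen = ints[, 4], tstart = ints[, 5], tend = ints[, 6],
             nmatch = ints[, 7], alnlen = ints[, 8], mapq = ints[, 9],
             cs = cs, tags = tags, stringsAsFactors = FALSE)
}

#' Read a PAF file
#'
#' @param path path to a PAF file.
#' @return see [parse_paf()].
#' @export
read_paf <- function(path) {
  parse_paf(readLines(path))
}

validate_paf <- function(records) {
  checks <- list(
    qstart = records$qstart >= 0L & records$qstart < records$qend,
    qend   = records$qend <= records$qlen,
    tstart = records$tstart >= 0L & records$tstart < records$tend,
    tend   = records$tend <= records$tlen,
    nmatch = records$nmatch <= records$alnlen,
    strand = records$strand %in% c("+", "-"),
    mapq   = records$mapq >= 0L
  )
  for (field in names(checks)) {
    bad <- which(!checks[[field]])
    if (length(bad)) {
      stop(sprintf("invalid PAF record %d: field '%s' violates its invariant",
                   bad[1L], field), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write PAF records
#'
#' Inverse of [parse_paf()]: records are validated against the PAF
#' invariants (refused naming the offending field) and serialised so that
#' `parse_paf(write_paf(x))` is the identity. Preserved optional tags are
#' re-emitted, followed by the `cs:Z:` tag when present.
#'
#' @param records data.frame as returned by [parse_paf()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of PAF lines, invisibly when `path` is given.
#' @export
write_paf <- function(records, path = NULL) {
  if (nrow(records)) validate_paf(records)
  lines <- character(nrow(records))
  if (nrow(records)) {
    core <- paste(records$qname, records$qlen, records$qstart, records$qend,
                  records$strand, records$tname, records$tlen,
                  records$tstart, records$tend, records$nmatch,
                  records$alnlen, records$mapq, sep = "\t")
    tags <- if ("tags" %in% names(records)) records$tags else character(nrow(records))
    tags[is.na(tags)] <- ""
    cs <- if ("cs" %in% names(records)) records$cs else rep(NA_character_, nrow(records))
    lines <- core
    has_tags <- nzchar(tags)
    lines[has_tags] <- paste(lines[has_tags], tags[has_tags], sep = "\t")
    has_cs <- !is.na(cs)
    lines[has_cs] <- paste(lines[has_cs], paste0("cs:Z:", cs[has_cs]), sep = "\t")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a short-form cs difference string
#'
#' The cs tag encodes the base-level alignment as a sequence of operations:
#' `:<n>` a run of `n` matches, `*<r><a>` a substitution of reference base
#' `r` by query base `a`, `+<seq>` an insertion (query only) and `-<seq>` a
#' deletion (reference only). Reference bases in the cs string follow the
#' forward target strand regardless of the alignment's strand.
#'
#' @param cs a single short-form cs string (without the `cs:Z:` prefix).
#' @return data.frame with columns `kind` (one of `match_run`,
#'   `substitution`, `insertion`, `deletion`), `length`, `ref`, `query`.
#' @export
parse_cs <- function(cs) {
  empty <- data.frame(kind = character(), length = integer(),
                      ref = character(), query = character(),
                      stringsAsFactors = FALSE)
  if (is.na(cs) || !nzchar(cs)) return(empty)
  if (!cs_is_short(cs)) {
    stop("long-form cs (with '=' match operators) is not supported for variant calling",
         call. = FALSE)
  }
  m <- gregexpr(":[0-9]+|\\*[acgtnACGTN][acgtnACGTN]|\\+[acgtnACGTN]+|-[acgtnACGTN]+",
                cs)[[1L]]
  if (m[1L] == -1L) {
    stop(sprintf("cs parse error: unknown operator at offset 1 in '%s'", cs),
         call. = FALSE)
  }
  len <- attr(m, "match.length")
  # tokens must tile the whole string with no gaps
  expected <- cumsum(c(1L, len))
  if (any(m != expected[seq_along(m)]) || expected[length(expected)] != nchar(cs) + 1L) {
    gap <- c(which(m != expected[seq_along(m)]), length(m) + 1L)[1L]
    stop(sprintf("cs parse error: unknown operator at offset %d",
                 expected[gap]), call. = FALSE)
  }
  tok <- substring(cs, m, m + len - 1L)
  op <- substr(tok, 1L, 1L)
  body <- substring(tok, 2L)
  kind <- c(":" = "match_run", "*" = "substitution",
            "+" = "insertion", "-" = "deletion")[op]
  out <- data.frame(kind = unname(kind), length = 0L,
                    ref = "", query = "", stringsAsFactors = FALSE)
  is_match <- op == ":"
  out$length[is_match] <- as.integer(body[is_match])
  is_sub <- op == "*"
  out$length[is_sub] <- 1L
  out$ref[is_sub] <- substr(body[is_sub], 1L, 1L)
  out$query[is_sub] <- substr(body[is_sub], 2L, 2L)
  is_ins <- op == "+"
  out$length[is_ins] <- nchar(body[is_ins])
  out$query[is_ins] <- body[is_ins]
  is_del <- op == "-"
  out$length[is_del] <- nchar(body[is_del])
  out$ref[is_del] <- body[is_del]
  out
}

#' Is a cs string in the short form?
#'
#' Long-form cs spells out match bases with `=`; such records (and records
#' with no cs at all) are accepted by the caller but flagged as having no
#' variant support, so the consensus falls back to reference bases.
#'
#' @param cs cs string (may be `NA`).
#' @return logical.
#' @export
cs_is_short <- function(cs) {
  !is.na(cs) & !grepl("=", cs, fixed = TRUE)
}

#' Reference and query spans implied by cs operations
#'
#' @param ops data.frame from [parse_cs()].
#' @return named integer vector `c(ref = , query = )`; for a valid record the
#'   reference span equals `tend - tstart` and the query span `qend - qstart`.
#' @export
cs_spans <- function(ops) {
  ref <- sum(ops$length[ops$kind %in% c("match_run", "substitution", "deletion")])
  query <- sum(ops$length[ops$kind %in% c("match_run", "substitution", "insertion")])
  c(ref = as.integer(ref), query = as.integer(query))
}

#' Render cs operations back to a cs string
#'
#' @param ops data.frame as produced by [parse_cs()].
#' @return a single cs string.
#' @export
render_cs <- function(ops) {
  if (!nrow(ops)) return("")
  piece <- character(nrow(ops))
  for (i in seq_len(nrow(ops))) {
    piece[i] <- switch(ops$kind[i],
      match_run    = paste0(":", ops$length[i]),
      substitution = paste0("*", tolower(ops$ref[i]), tolower(ops$query[i])),
      insertion    = paste0("+", tolower(ops$query[i])),
      deletion     = paste0("-", tolower(ops$ref[i])))
  }
  paste(piece, collapse = "")
}

# rbind a list of data.frame rows; NULL when the list is empty
rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
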