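#' Read a SAM file into a tibble of alignment records
#'
#' Parses the text SAM format (v1) losslessly: the eleven mandatory fields
#' become columns, optional tags are carried through verbatim in a single
#' `tags` column, and the header block is attached as the `"header"`
#' attribute. Coordinates stay 1-based as printed; all internal arithmetic
#' converts at this boundary.
#'
#' @param path Path to a SAM text file.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual` (ASCII Phred+33
#'   string), `tags` (tab-joined optional fields, `""` if none), and a
#'   `class` column from [classify_read()]. Attribute `header` holds the
#'   header lines verbatim.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  n_header <- if (all(is_header)) length(lines) else which(!is_header)[1] - 1L
  header <- lines[seq_len(n_header)]
  body <- lines[seq_along(lines) > n_header]
  body_lineno <- seq_along(body) + n_header
  if (any(startsWith(body, "@"))) {
    stop("header line after first alignment record at line ",
         body_lineno[startsWith(body, "@")][1])
  }
  if (length(body) == 0L) {
    reads <- tibble::tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character(), tags = character(),
      class = character())
    attr(reads, "header") <- header
    return(reads)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("malformed SAM record (", nf[bad], " fields, need >= 11) at line ",
         body_lineno[bad])
  }
  fld <- function(i) vapply(fields, `[[`, character(1), i)
  tags <- vapply(fields, function(f) {
    if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else ""
  }, character(1))
  reads <- tibble::tibble(
    qname = fld(1), flag = as.integer(fld(2)), rname = fld(3),
    pos = as.integer(fld(4)), mapq = as.integer(fld(5)), cigar = fld(6),
    rnext = fld(7), pnext = as.integer(fld(8)), tlen = as.integer(fld(9)),
    seq = fld(10), qual = fld(11), tags = tags)
  has_both <- reads$seq != "*" & reads$qual != "*"
  mism <- has_both & nchar(reads$seq) != nchar(reads$qual)
  if (any(mism)) {
    bad <- which(mism)[1]
    stop("SEQ/QUAL length mismatch for read '", reads$qname[bad],
         "' at line ", body_lineno[bad])
  }
  has_cigar <- reads$cigar != "*" & reads$seq != "*"
  if (any(has_cigar)) {
    qlen <- cigar_query_length(reads$cigar[has_cigar])
    off <- qlen != nchar(reads$seq[has_cigar])
    if (any(off)) {
      bad <- which(has_cigar)[which(off)[1]]
      stop("CIGAR query length does not match SEQ for read '",
           reads$qname[bad], "' at line ", body_lineno[bad])
    }
  }
  reads$class <- classify_read(reads$flag)
  attr(reads, "header") <- header
  reads
}

#' Classify a SAM flag into an alignment class
#'
#' Only primary alignments enter the denoiser's statistics; everything else
#' is copied through untouched.
#'
#' @param flag Integer vector of SAM flag bitfields.
#' @return Character vector: `"unmapped"` (0x4), `"secondary"` (0x100),
#'   `"supplementary"` (0x800) or `"primary_mapped"`, tested in that order.
#' @export
#' @examples
#' classify_read(c(0L, 4L, 256L, 2048L, 99L))
classify_read <- function(flag) {
  dplyr::case_when(
    bitwAnd(flag, 4L) != 0L    ~ "unmapped",
    bitwAnd(flag, 256L) != 0L  ~ "secondary",
    bitwAnd(flag, 2048L) != 0L ~ "supplementary",
    TRUE                       ~ "primary_mapped")
}

parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  if (m[[1]][1] == -1L ||
      sum(attr(m[[1]], "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  parts <- regmatches(cigar, m)[[1]]
  tibble::tibble(
    op = substr(parts, nchar(parts), nchar(parts)),
    len = as.integer(substr(parts, 1L, nchar(parts) - 1L)))
}

cigar_op_sum <- function(cigar, ops) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% ops])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_query_length <- function(cigar) cigar_op_sum(cigar, c("M", "I", "S", "=", "X"))
cigar_ref_length <- function(cigar) cigar_op_sum(cigar, c("M", "D", "N", "=", "X"))

#' Walk a CIGAR alignment into per-base query/reference coordinates
#'
#' Expands one alignment into a row per aligned, inserted, clipped or
#' deleted position: M/=/X rows carry both a query index and a reference
#' position, I and S rows carry only a query index, D/N rows only the
#' deleted reference position. H and P consume nothing and emit nothing.
#'
#' @param cigar A single CIGAR string.
#' @param pos 1-based leftmost mapped reference position.
#' @param seq Optional read sequence; if given, its length is checked
#'   against the CIGAR's query-consuming length.
#' @return Tibble with columns `query_index` (0-based, NA for D/N),
#'   `ref_pos` (1-based, NA for I/S) and `op`.
#' @export
#' @examples
#' walk_alignment("3S5M", pos = 100)
#' walk_alignment("2M1I2M", pos = 50)
walk_alignment <- function(cigar, pos, seq = NULL) {
  p <- parse_cigar(cigar)
  if (!is.null(seq)) {
    qlen <- sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
    if (qlen != nchar(seq)) {
      stop("CIGAR query length ", qlen, " does not match sequence length ",
           nchar(seq))
    }
  }
  qi <- 0L
  rp <- pos
  out <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    op <- p$op[i]; len <- p$len[i]
    if (op %in% c("M", "=", "X")) {
      out[[i]] <- tibble::tibble(query_index = qi:(qi + len - 1L),
                                 ref_pos = rp:(rp + len - 1L), op = op)
      qi <- qi + len; rp <- rp + len
    } else if (op %in% c("I", "S")) {
      out[[i]] <- tibble::tibble(query_index = qi:(qi + len - 1L),
                                 ref_pos = NA_integer_, op = op)
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      out[[i]] <- tibble::tibble(query_index = NA_integer_,
                                 ref_pos = rp:(rp + len - 1L), op = op)
      rp <- rp + len
    }
  }
  dplyr::bind_rows(out)
}

#' Write a tibble of alignment records back to SAM
#'
#' The inverse of [read_sam()]: every field other than SEQ and QUAL is
#' written byte-identically, and a program-group line recording the tool and
#' its parameters is appended to the header.
#'
#' @param reads Tibble as returned by [read_sam()] (possibly with modified
#'   `seq`/`qual`).
#' @param path Output file path.
#' @param header Character vector of header lines; defaults to the tibble's
#'   `header` attribute.
#' @param pg_cl Command-line text recorded in the appended `@PG` line, or
#'   `NULL` to append none.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, header = attr(reads, "header"),
                      pg_cl = "aligndude") {
  if (is.null(header)) header <- character()
  if (!is.null(pg_cl)) {
    header <- c(header,
                paste0("@PG\tID:aligndude\tPN:aligndude\tCL:", pg_cl))
  }
  body <- paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
                reads$cigar, reads$rnext, reads$pnext, reads$tlen,
                reads$seq, reads$qual, sep = "\t")
  has_tags <- !is.na(reads$tags) & reads$tags != ""
  body[has_tags] <- paste(body[has_tags], reads$tags[has_tags], sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# Phred integer vectors <-> ASCII Phred+33 strings
qual_to_phred <- function(qual) utf8ToInt(qual) - 33L
phred_to_qual <- function(phred) intToUtf8(phred + 33L)
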