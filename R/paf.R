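#' Read PAF alignments into a segment table
#'
#' Parses one or more PAF files (12 mandatory columns; SAM-style tags are
#' ignored) into a per-read segment table. Segments from all files for the
#' same read are pooled — this supports a primary mapping pass plus a
#' masked-remap pass — and sorted by read start within each read. PAF is
#' natively 0-based half-open, matching the package's internal convention.
#'
#' @param paf_paths Character vector of PAF file paths.
#' @return Tibble with one row per mapped segment: `read_id`, `read_length`,
#'   `read_start`, `read_end`, `direction` (+1 forward / -1 reverse),
#'   `target_name` (chromosome), `genome_start`, `genome_end`, `mapq`.
#' @export
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("r1\t500\t0\t500\t+\tchr1\t10000\t1000\t1500\t480\t500\t60", paf)
#' read_paf(paf)
read_paf <- function(paf_paths) {
  recs <- purrr::map(paf_paths, function(p) {
    if (!file.exists(p)) stop("PAF file not found: ", p, call. = FALSE)
    lines <- readLines(p)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(NULL)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L)) {
      stop("Malformed PAF line ", which(nf < 12L)[1], " in ", p,
           ": fewer than 12 columns", call. = FALSE)
    }
    col <- function(i) vapply(fields, `[[`, "", i)
    strand <- col(5L)
    if (!all(strand %in% c("+", "-"))) {
      stop("Malformed PAF line ", which(!strand %in% c("+", "-"))[1],
           " in ", p, ": strand column must be '+' or '-'", call. = FALSE)
    }
    tibble::tibble(
      read_id = col(1L),
      read_length = as.integer(col(2L)),
      read_start = as.integer(col(3L)),
      read_end = as.integer(col(4L)),
      direction = ifelse(strand == "+", 1L, -1L),
      target_name = col(6L),
      genome_start = as.integer(col(8L)),
      genome_end = as.integer(col(9L)),
      mapq = as.integer(col(12L)))
  })
  dplyr::bind_rows(recs) |>
    dplyr::arrange(.data$read_id, .data$read_start, .data$genome_start)
}

#' Merge near-adjacent segments of each read
#'
#' Consecutive segments of a read that map to the same chromosome in the same
#' direction are merged into their union when the gap is strictly less than
#' `max_gap` nucleotides on both the read and the reference genome. This
#' absorbs the small indels long-read sequencing introduces into otherwise
#' contiguous alignments. Merging is applied transitively left-to-right and
#' is idempotent. Overlapping genome intervals (negative genome gap) merge
#' whenever the read gap qualifies.
#'
#' If two segments of one read overlap on the read (a mapper artifact), the
#' longer segment is kept intact and the shorter one is truncated to the
#' non-overlapping remainder (dropped if contained).
#'
#' @param segments Segment tibble from [read_paf()].
#' @param max_gap Merge gap bound in nucleotides; gaps must be `< max_gap`
#'   (default 10).
#' @return Segment tibble, merged, sorted by read then read start.
#' @export
merge_segments <- function(segments, max_gap = 10L) {
  if (nrow(segments) == 0L) return(segments)
  segments |>
    dplyr::arrange(.data$read_id, .data$read_start, .data$genome_start) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::group_modify(~ merge_one_read(.x, max_gap)) |>
    dplyr::ungroup()
}

merge_one_read <- function(seg, max_gap) {
  seg <- resolve_read_overlaps(seg)
  n <- nrow(seg)
  if (n <= 1L) return(seg)
  out <- seg[1L, ]
  for (i in seq_len(n)[-1L]) {
    cur <- seg[i, ]
    last <- out[nrow(out), ]
    read_gap <- cur$read_start - last$read_end
    # genome gap measured in the direction of mapping: on '-' mappings
    # consecutive read segments advance toward lower genome coordinates
    genome_gap <- if (cur$direction == 1L) {
      cur$genome_start - last$genome_end
    } else {
      last$genome_start - cur$genome_end
    }
    if (cur$target_name == last$target_name &&
        cur$direction == last$direction &&
        read_gap < max_gap && genome_gap < max_gap) {
      out$read_end[nrow(out)] <- max(last$read_end, cur$read_end)
      out$genome_start[nrow(out)] <- min(last$genome_start, cur$genome_start)
      out$genome_end[nrow(out)] <- max(last$genome_end, cur$genome_end)
    } else {
      out <- dplyr::bind_rows(out, cur)
    }
  }
  out
}

# Keep the longer of two read-overlapping segments; truncate the shorter.
resolve_read_overlaps <- function(seg) {
  n <- nrow(seg)
  if (n <= 1L) return(seg)
  seg <- seg[order(seg$read_start, seg$read_end), ]
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(seg)) {
      a <- seg[i, ]; b <- seg[i + 1L, ]
      if (b$read_start < a$read_end) {
        len_a <- a$read_end - a$read_start
        len_b <- b$read_end - b$read_start
        if (len_a >= len_b) {
          # truncate b's left edge (and clip its genome interval coarsely)
          seg$read_start[i + 1L] <- a$read_end
        } else {
          seg$read_end[i] <- b$read_start
        }
        seg <- seg[seg$read_end > seg$read_start, ]
        seg <- seg[order(seg$read_start, seg$read_end), ]
        changed <- TRUE
        break
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  seg
}

#' Annotate segments with overlapping exons
#'
#' Produces the chaining input `M`: one row per (segment, overlapping exon)
#' pair. Segments whose genome interval overlaps no annotated exon contribute
#' nothing — such segments likely fall in intronic or intergenic sequence,
#' and reads with no exon match at all are later classified intergenic.
#' More than one exon can annotate a segment (adjacent exons, overlapping
#' isoforms, or overlapping genes).
#'
#' Rows are ordered deterministically by read start, then genome start, then
#' (gene_id, transcript_id, exon_rank); this fixes tie-breaking in the
#' chaining dynamic program.
#'
#' @param segments Merged segment tibble.
#' @param db A `fusion_annotation`.
#' @return Tibble `M` with segment fields plus `exon_start`, `exon_end`,
#'   `gene_id`, `transcript_id`, `exon_rank`, `n_exons`.
#' @export
annotate_segments <- function(segments, db) {
  empty <- tibble::tibble(
    read_id = character(), read_start = integer(), read_end = integer(),
    direction = integer(), target_name = character(),
    genome_start = integer(), genome_end = integer(),
    exon_start = integer(), exon_end = integer(), gene_id = character(),
    transcript_id = character(), exon_rank = integer(), n_exons = integer())
  if (nrow(segments) == 0L) return(empty)
  q <- GenomicRanges::GRanges(
    segments$target_name,
    IRanges::IRanges(segments$genome_start + 1L, segments$genome_end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, db$exon_gr, minoverlap = 1L))
  if (length(hits) == 0L) return(empty)
  seg <- segments[S4Vectors::queryHits(hits), ]
  ex <- db$exons[S4Vectors::subjectHits(hits), ]
  tibble::tibble(
    read_id = seg$read_id,
    read_start = seg$read_start, read_end = seg$read_end,
    direction = seg$direction, target_name = seg$target_name,
    genome_start = seg$genome_start, genome_end = seg$genome_end,
    exon_start = ex$start, exon_end = ex$end,
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    exon_rank = ex$exon_rank, n_exons = ex$n_exons) |>
    dplyr::arrange(.data$read_id, .data$read_start, .data$genome_start,
                   .data$gene_id, .data$transcript_id, .data$exon_rank)
}
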