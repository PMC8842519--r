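#' Load a gene annotation from a GTF file
#'
#' Parses gene/transcript/exon records from an Ensembl-dialect GTF and builds
#' the annotation index used throughout the fusion-calling pipeline: per-gene
#' models, transcript exon lists in transcription order, gene-body intervals
#' and a genome-wide exon interval index.
#'
#' All coordinates are stored 0-based half-open internally; the 1-based closed
#' GTF convention is converted on read. Exon rank is transcription order
#' (rank 1 = first transcribed exon), so on the minus strand rank 1 is the
#' exon with the highest genomic coordinate.
#'
#' @param gtf_path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on exon lines.
#' @return An object of class `fusion_annotation`: a list with tibbles
#'   `genes` (gene_id, gene_name, chrom, strand, body_start, body_end) and
#'   `exons` (gene_id, transcript_id, chrom, strand, start, end, exon_rank,
#'   n_exons), plus an exon interval index.
#' @export
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "longfuse")
#' db <- read_annotation(gtf)
#' db$genes
read_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) {
    stop("GTF file not found: ", gtf_path, call. = FALSE)
  }
  lines <- readLines(gtf_path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("GTF file has no feature lines", call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- line_no[which(nf < 9L)[1]]
    stop("Malformed GTF line ", bad, ": expected 9 tab-separated fields",
         call. = FALSE)
  }
  feat <- vapply(fields, `[[`, "", 3L)
  use <- feat %in% c("gene", "transcript", "exon")
  fields <- fields[use]
  line_no <- line_no[use]
  feat <- feat[use]

  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)

  bad_coord <- which(is.na(start1) | is.na(end1) | start1 > end1 |
                       !(strand %in% c("+", "-")))
  if (length(bad_coord) > 0L) {
    stop("Malformed GTF line ", line_no[bad_coord[1]],
         ": bad coordinates or strand", call. = FALSE)
  }

  gene_id <- stringr::str_match(attrs, 'gene_id "([^"]+)"')[, 2]
  tx_id <- stringr::str_match(attrs, 'transcript_id "([^"]+)"')[, 2]
  gene_name <- stringr::str_match(attrs, 'gene_name "([^"]+)"')[, 2]

  if (anyNA(gene_id)) {
    stop("Malformed GTF line ", line_no[which(is.na(gene_id))[1]],
         ": missing gene_id attribute", call. = FALSE)
  }
  is_exon <- feat == "exon"
  if (any(is_exon & is.na(tx_id))) {
    stop("Malformed GTF line ", line_no[which(is_exon & is.na(tx_id))[1]],
         ": exon record lacks transcript_id", call. = FALSE)
  }

  # 1-based closed -> 0-based half-open
  tab <- tibble::tibble(
    feature = feat, chrom = chrom, start = start1 - 1L, end = end1,
    strand = strand, gene_id = gene_id, transcript_id = tx_id,
    gene_name = dplyr::coalesce(gene_name, gene_id)
  )

  exons <- dplyr::filter(tab, .data$feature == "exon")
  if (nrow(exons) == 0L) stop("GTF contains no exon records", call. = FALSE)

  # validate exons against declared transcript spans, when present
  tx_span <- dplyr::filter(tab, .data$feature == "transcript")
  if (nrow(tx_span) > 0L) {
    chk <- dplyr::inner_join(
      exons, dplyr::select(tx_span, "transcript_id",
                           tx_start = "start", tx_end = "end"),
      by = "transcript_id")
    out <- chk$start < chk$tx_start | chk$end > chk$tx_end
    if (any(out)) {
      stop("Exon of transcript ", chk$transcript_id[which(out)[1]],
           " lies outside the declared transcript span", call. = FALSE)
    }
  }

  # transcription-order rank: ascending coordinate on '+', descending on '-'
  exons <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      exon_rank = if (.data$strand[1] == "+") dplyr::row_number()
                  else dplyr::n() - dplyr::row_number() + 1L,
      n_exons = dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "gene_name", "transcript_id", "chrom", "strand",
                  "start", "end", "exon_rank", "n_exons") |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id,
                   .data$transcript_id, .data$exon_rank)

  genes <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      gene_name = .data$gene_name[1], chrom = .data$chrom[1],
      strand = .data$strand[1],
      body_start = min(.data$start), body_end = max(.data$end),
      .groups = "drop")

  db <- list(genes = genes, exons = exons,
             exon_gr = exon_granges(exons))
  class(db) <- "fusion_annotation"
  db
}

# IRanges index over exons (internal; 1-based closed for GRanges)
exon_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end))
}

#' @export
print.fusion_annotation <- function(x, ...) {
  cat("<fusion_annotation> ", nrow(x$genes), " genes, ",
      length(unique(x$exons$transcript_id)), " transcripts, ",
      nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Write an annotation back to GTF
#'
#' Emits gene, transcript and exon records in 1-based closed GTF coordinates.
#' Reloading the file with [read_annotation()] reproduces the same intervals.
#'
#' @param db A `fusion_annotation` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(db, path) {
  ex <- db$exons
  attr_str <- function(g, n, t = NA_character_) {
    s <- sprintf('gene_id "%s"; gene_name "%s";', g, n)
    ifelse(is.na(t), s, sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";', g, t, n))
  }
  gene_lines <- sprintf("%s\tlongfuse\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        db$genes$chrom, db$genes$body_start + 1L,
                        db$genes$body_end, db$genes$strand,
                        attr_str(db$genes$gene_id, db$genes$gene_name))
  tx <- ex |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(gene_id = .data$gene_id[1], gene_name = .data$gene_name[1],
                     chrom = .data$chrom[1], strand = .data$strand[1],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  tx_lines <- sprintf("%s\tlongfuse\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, tx$start + 1L, tx$end, tx$strand,
                      attr_str(tx$gene_id, tx$gene_name, tx$transcript_id))
  ex_lines <- sprintf("%s\tlongfuse\texon\t%d\t%d\t.\t%s\t.\t%s",
                      ex$chrom, ex$start + 1L, ex$end, ex$strand,
                      attr_str(ex$gene_id, ex$gene_name, ex$transcript_id))
  writeLines(c(gene_lines, tx_lines, ex_lines), path)
  invisible(path)
}

#' Query exons overlapping a genomic interval
#'
#' Returns every annotated exon overlapping the query by at least one base;
#' there is no minimum-overlap threshold. Unknown chromosomes yield an empty
#' result rather than an error.
#'
#' @param db A `fusion_annotation`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query interval (`start < end`).
#' @return Tibble of overlapping exons with gene/transcript ids and ranks.
#' @export
query_exons <- function(db, chrom, start, end) {
  stopifnot(start < end)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  # suppress seqlevel warnings for chromosomes absent from the annotation
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, db$exon_gr, minoverlap = 1L))
  db$exons[S4Vectors::subjectHits(hits), ]
}

#' Test whether two gene bodies overlap
#'
#' Gene bodies are the `[min exon start, max exon end)` interval of each gene.
#' Overlap requires the same chromosome and at least 1 bp in common,
#' irrespective of strand.
#'
#' @param db A `fusion_annotation`.
#' @param gene_a,gene_b Gene identifiers present in `db`.
#' @return Logical scalar.
#' @export
genes_overlap <- function(db, gene_a, gene_b) {
  g <- db$genes
  a <- g[g$gene_id == gene_a, ]
  b <- g[g$gene_id == gene_b, ]
  if (nrow(a) == 0L) stop("Unknown gene id: ", gene_a, call. = FALSE)
  if (nrow(b) == 0L) stop("Unknown gene id: ", gene_b, call. = FALSE)
  a$chrom == b$chrom &&
    max(a$body_start, b$body_start) < min(a$body_end, b$body_end)
}

#' Load a segmental-duplication pair table
#'
#' Reads a UCSC genomicSuperDups-style tab-separated table of duplicated
#' interval pairs. Both the UCSC column names (`chrom`, `chromStart`,
#' `chromEnd`, `otherChrom`, `otherStart`, `otherEnd`) and the plain
#' `start`/`end` variants are honoured; extra columns are ignored.
#' Coordinates are taken as 0-based half-open (UCSC convention).
#'
#' @param path Path to the tab-separated table (a header line is required;
#'   a leading `#` on it is tolerated).
#' @return An object of class `sd_index`.
#' @export
read_sd_pairs <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         comment = "", progress = FALSE)
  names(tab)[1] <- sub("^#", "", names(tab)[1])
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    stop("segmental-duplication table lacks required column: one of ",
         paste(c(...), collapse = "/"), call. = FALSE)
  }
  pairs <- tibble::tibble(
    chrom1 = as.character(pick("chrom")),
    start1 = as.integer(pick("chromStart", "start")),
    end1 = as.integer(pick("chromEnd", "end")),
    chrom2 = as.character(pick("otherChrom")),
    start2 = as.integer(pick("otherStart")),
    end2 = as.integer(pick("otherEnd")))
  idx <- list(
    pairs = pairs,
    gr1 = GenomicRanges::GRanges(pairs$chrom1,
            IRanges::IRanges(pairs$start1 + 1L, pairs$end1)),
    gr2 = GenomicRanges::GRanges(pairs$chrom2,
            IRanges::IRanges(pairs$start2 + 1L, pairs$end2)))
  class(idx) <- "sd_index"
  idx
}

#' Test whether two regions are linked by a segmental duplication
#'
#' True when some duplication pair has one side overlapping `region_a` and
#' its partner overlapping `region_b`; both orientations are tested, so the
#' lookup is symmetric in its two region arguments.
#'
#' @param sd An `sd_index` from [read_sd_pairs()].
#' @param chrom_a,start_a,end_a First region (0-based half-open).
#' @param chrom_b,start_b,end_b Second region.
#' @return Logical scalar.
#' @export
sd_linked <- function(sd, chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (nrow(sd$pairs) == 0L) return(FALSE)
  ga <- GenomicRanges::GRanges(chrom_a, IRanges::IRanges(start_a + 1L, end_a))
  gb <- GenomicRanges::GRanges(chrom_b, IRanges::IRanges(start_b + 1L, end_b))
  ov <- function(q, gr) {
    S4Vectors::subjectHits(suppressWarnings(
      GenomicRanges::findOverlaps(q, gr, minoverlap = 1L)))
  }
  length(intersect(ov(ga, sd$gr1), ov(gb, sd$gr2))) > 0L ||
    length(intersect(ov(gb, sd$gr1), ov(ga, sd$gr2))) > 0L
}

#' Build a homologous gene-pair index from a transcriptome self-alignment
#'
#' Each PAF record whose query and target transcripts resolve (via `db`) to
#' two distinct genes contributes that unordered gene pair; alignments between
#' transcripts of the same gene are ignored. Records naming transcripts
#' absent from the annotation are skipped with a warning.
#'
#' @param self_alignment_paf Path to a PAF of the transcriptome aligned to
#'   itself (query and target names are transcript ids).
#' @param db A `fusion_annotation`.
#' @return A `homolog_index`: tibble of unordered gene pairs.
#' @export
build_homolog_index <- function(self_alignment_paf, db) {
  paf <- read_paf(self_alignment_paf)
  tx2gene <- db$exons |>
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  lookup <- stats::setNames(tx2gene$gene_id, tx2gene$transcript_id)
  strip_version <- function(x) sub("\\.\\d+$", "", x)
  resolve <- function(x) {
    g <- unname(lookup[x])
    miss <- is.na(g)
    g[miss] <- unname(lookup[strip_version(x[miss])])
    g
  }
  ga <- resolve(paf$read_id)
  gb <- resolve(paf$target_name)
  bad <- is.na(ga) | is.na(gb)
  if (any(bad)) {
    warning(sum(bad), " self-alignment record(s) skipped: transcript id not ",
            "in annotation", call. = FALSE)
  }
  keep <- !bad & ga != gb
  homolog_index(ga[keep], gb[keep])
}

#' Construct a homolog index from gene-id pairs
#'
#' @param gene_a,gene_b Character vectors of equal length; self-pairs are
#'   dropped and pairs are deduplicated symmetrically.
#' @return A `homolog_index`.
#' @export
homolog_index <- function(gene_a = character(), gene_b = character()) {
  keep <- gene_a != gene_b
  idx <- tibble::tibble(
    gene1 = pmin(gene_a[keep], gene_b[keep]),
    gene2 = pmax(gene_a[keep], gene_b[keep])) |>
    dplyr::distinct()
  class(idx) <- c("homolog_index", class(idx))
  idx
}

#' Read a homolog index from a two-column gene-pair TSV
#'
#' An alternative to [build_homolog_index()] for users without a
#' self-alignment PAF.
#'
#' @param path TSV with two columns of gene ids (no header).
#' @return A `homolog_index`.
#' @export
read_homolog_pairs <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("gene1", "gene2"),
                         col_types = "cc", progress = FALSE)
  homolog_index(tab$gene1, tab$gene2)
}

#' Test membership of a gene pair in a homolog index
#'
#' Symmetric lookup: argument order does not matter.
#'
#' @param idx A `homolog_index`.
#' @param gene_a,gene_b Gene ids (vectorised).
#' @return Logical vector.
#' @export
has_homolog_pair <- function(idx, gene_a, gene_b) {
  key <- paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b))
  key %in% paste(idx$gene1, idx$gene2)
}
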