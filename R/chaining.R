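#' Reciprocal overlap of two intervals
#'
#' The size of the intersection divided by the size of the larger interval,
#' clamped at zero for disjoint intervals. Vectorised. A zero-length larger
#' interval yields 0 by convention.
#'
#' @param a_start,a_end,b_start,b_end Interval endpoints (half-open).
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' reciprocal_overlap(0, 100, 50, 250)  # 50/200 = 0.25
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  larger <- pmax(a_end - a_start, b_end - b_start)
  inter <- pmin(a_end, b_end) - pmax(a_start, b_start)
  out <- ifelse(larger > 0, pmax(0, inter / larger), 0)
  as.numeric(out)
}

#' Gene/isoform switch penalty between two chained matches
#'
#' The chaining score multiplies each added match by 1 when it continues the
#' same transcript, 0.9 when it switches isoform within a gene, and 0.5 when
#' it switches gene. This prioritises single-isoform chains over single-gene
#' multi-isoform chains, and those over multi-gene (potential fusion) chains,
#' so a fusion is only called when no comparable single-gene explanation
#' exists.
#'
#' @param gene_c,tx_c Gene and transcript id of the current match.
#' @param gene_p,tx_p Gene and transcript id of the parent match.
#' @return Numeric penalty factor (vectorised).
#' @export
switch_penalty <- function(gene_c, tx_c, gene_p, tx_p) {
  ifelse(tx_c == tx_p, 1,
         ifelse(gene_c == gene_p, 0.9, 0.5))
}

# Parent predicate for the chaining DP, vectorised over candidate parents p
# for a fixed current match c. A parent's read interval must end before c's
# starts — with half-open intervals that is p_end <= c_start (adjacent
# segments do not overlap); if the mapping directions agree the genomic intervals
# must advance in the direction of mapping (D * (g_e^c - g_s^p) > 0, same
# chromosome); opposite directions carry no genomic-order restriction, which
# admits inversion and translocation fusions.
is_parent <- function(p_read_end, p_dir, p_chrom, p_genome_start,
                      c_read_start, c_dir, c_chrom, c_genome_end) {
  before <- p_read_end <= c_read_start
  opposite <- p_dir != c_dir
  colinear <- p_dir == c_dir &
    (p_chrom != c_chrom | c_dir * (c_genome_end - p_genome_start) > 0)
  before & (opposite | colinear)
}

#' Compute optimal exon chains for each read
#'
#' Runs the co-linear chaining dynamic program over the annotated match list
#' `M` of each read. Let `w[c] = reciprocal_overlap(segment, exon) *
#' segment_genome_length`; then `S[c]` is the best of the singleton chain
#' (`w[c]`) and `S[p] + w[c] * penalty(c, p)` over all parents `p`. The
#' optimal chain is recovered by backtracking from the argmax of `S`, and
#' consecutive identical exons are collapsed so the chain is an ordered list
#' of unique exons. Ties are broken toward the lowest index, which together
#' with the deterministic ordering of `M` makes results reproducible.
#'
#' @param M Annotated match tibble from [annotate_segments()] (any number of
#'   reads).
#' @return Tibble of chain entries, one row per chained exon occurrence:
#'   read_id, chain_pos, gene_id, transcript_id, exon_start, exon_end,
#'   exon_rank, n_exons, read_start, read_end, target_name, genome_start,
#'   genome_end, direction, and the read-level chain `score`.
#' @export
chain_exons <- function(M) {
  empty <- tibble::tibble(
    read_id = character(), chain_pos = integer(), gene_id = character(),
    transcript_id = character(), exon_start = integer(), exon_end = integer(),
    exon_rank = integer(), n_exons = integer(), read_start = integer(),
    read_end = integer(), target_name = character(), genome_start = integer(),
    genome_end = integer(), direction = integer(), score = numeric())
  if (is.null(M) || nrow(M) == 0L) return(empty)
  M <- dplyr::arrange(M, .data$read_id, .data$read_start, .data$genome_start,
                      .data$gene_id, .data$transcript_id, .data$exon_rank)
  parts <- split(M, M$read_id)
  out <- purrr::map(parts, chain_one_read)
  dplyr::bind_rows(out)
}

chain_one_read <- function(m) {
  n <- nrow(m)
  w <- reciprocal_overlap(m$genome_start, m$genome_end,
                          m$exon_start, m$exon_end) *
    (m$genome_end - m$genome_start)
  S <- w
  parent <- rep(NA_integer_, n)
  if (n > 1L) {
    for (c in 2:n) {
      ok <- is_parent(m$read_end[1:(c - 1L)], m$direction[1:(c - 1L)],
                      m$target_name[1:(c - 1L)], m$genome_start[1:(c - 1L)],
                      m$read_start[c], m$direction[c],
                      m$target_name[c], m$genome_end[c])
      ps <- which(ok)
      if (length(ps) > 0L) {
        cand <- S[ps] + w[c] * switch_penalty(
          m$gene_id[c], m$transcript_id[c],
          m$gene_id[ps], m$transcript_id[ps])
        best <- which.max(cand)  # lowest index on ties
        if (cand[best] > S[c]) {
          S[c] <- cand[best]
          parent[c] <- ps[best]
        }
      }
    }
  }
  b <- which.max(S)  # lowest index on ties
  idx <- integer()
  cur <- b
  while (!is.na(cur)) {
    idx <- c(cur, idx)
    cur <- parent[cur]
  }
  chain <- m[idx, ]
  # collapse consecutive identical exons (same exon interval + ids)
  if (nrow(chain) > 1L) {
    key <- paste(chain$gene_id, chain$transcript_id,
                 chain$exon_start, chain$exon_end)
    keep <- c(TRUE, key[-1L] != key[-length(key)])
    chain <- chain[keep, ]
  }
  tibble::tibble(
    read_id = chain$read_id, chain_pos = seq_len(nrow(chain)),
    gene_id = chain$gene_id, transcript_id = chain$transcript_id,
    exon_start = chain$exon_start, exon_end = chain$exon_end,
    exon_rank = chain$exon_rank, n_exons = chain$n_exons,
    read_start = chain$read_start, read_end = chain$read_end,
    target_name = chain$target_name, genome_start = chain$genome_start,
    genome_end = chain$genome_end, direction = chain$direction,
    score = S[b])
}

#' Classify reads from their exon chains
#'
#' A read whose chain contains exons of multiple genes is chimeric; a
#' single-gene chain is a normal RNA read; a read with no chain (no exon
#' overlap at all) is intergenic. For chimeric reads the head gene is the
#' first gene along the read and the tail the second; chains touching more
#' than two genes are clustered by their first two genes.
#'
#' The `rt_junction` flag records whether the chain's last head-gene exon is
#' the second-to-last exon of its transcript and its first tail-gene exon is
#' the second exon of its transcript — the junction structure expected of
#' read-through transcripts.
#'
#' @param chains Chain-entry tibble from [chain_exons()].
#' @param read_ids Optional character vector of all read ids in the sample;
#'   reads absent from `chains` are reported as intergenic.
#' @return Tibble with one row per read: read_id, class
#'   (normal/chimeric/intergenic), n_genes, gene_id (sole gene of a normal
#'   read), head_gene, tail_gene, score, rt_junction.
#' @export
classify_reads <- function(chains, read_ids = NULL) {
  per_read <- chains |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$chain_pos, .by_group = TRUE) |>
    dplyr::summarise(
      genes = list(unique(.data$gene_id)),
      score = .data$score[1],
      rt_junction = rt_junction_flag(
        .data$gene_id, .data$exon_rank, .data$n_exons),
      .groups = "drop")
  nth_gene <- function(genes, i) {
    vapply(genes, function(g) if (length(g) >= i) g[i] else NA_character_, "")
  }
  per_read <- per_read |>
    dplyr::mutate(
      n_genes = lengths(.data$genes),
      class = dplyr::if_else(.data$n_genes >= 2L, "chimeric", "normal"),
      gene_id = dplyr::if_else(.data$class == "normal",
                               nth_gene(.data$genes, 1L), NA_character_),
      head_gene = dplyr::if_else(.data$class == "chimeric",
                                 nth_gene(.data$genes, 1L), NA_character_),
      tail_gene = dplyr::if_else(.data$class == "chimeric",
                                 nth_gene(.data$genes, 2L), NA_character_)) |>
    dplyr::select(-"genes")
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, per_read$read_id)
    if (length(missing) > 0L) {
      per_read <- dplyr::bind_rows(
        per_read,
        tibble::tibble(read_id = missing, n_genes = 0L,
                       gene_id = NA_character_, head_gene = NA_character_,
                       tail_gene = NA_character_, score = 0,
                       rt_junction = FALSE, class = "intergenic"))
    }
  }
  dplyr::arrange(
    dplyr::select(per_read, "read_id", "class", "n_genes", "gene_id",
                  "head_gene", "tail_gene", "score", "rt_junction"),
    .data$read_id)
}

# Junction structure test used by the read-through rule: last head-gene exon
# in chain order has rank n_exons - 1 and first tail-gene exon has rank 2.
rt_junction_flag <- function(gene_id, exon_rank, n_exons) {
  genes <- unique(gene_id)
  if (length(genes) < 2L) return(FALSE)
  head_gene <- genes[1]
  tail_gene <- genes[2]
  h <- which(gene_id == head_gene)
  t <- which(gene_id == tail_gene)
  last_head <- h[length(h)]
  first_tail <- t[1]
  isTRUE(exon_rank[last_head] == n_exons[last_head] - 1L) &&
    isTRUE(exon_rank[first_tail] == 2L)
}

#' Remove low-complexity chain segments
#'
#' The chaining score ignores sequence content, so unclipped poly-A tails can
#' be chained onto spurious exons. Any chain entry whose read-interval
#' subsequence consists of more than 70% of a single base (A, C, G, T and N
#' counted separately, case-insensitive) is removed. Reads should be
#' reclassified afterwards with [classify_reads()], since removing a gene's
#' only entries can turn a chimeric read into a normal one.
#'
#' @param chains Chain-entry tibble from [chain_exons()].
#' @param reads A named `Biostrings::DNAStringSet` (or path to FASTA/FASTQ,
#'   read via [read_reads()]) covering every read id in `chains`.
#' @param max_single_base_frac Removal threshold; entries are removed when
#'   the dominant base fraction is strictly greater (default 0.70).
#' @return Filtered chain-entry tibble with `chain_pos` renumbered.
#' @export
strip_low_complexity <- function(chains, reads,
                                 max_single_base_frac = 0.70) {
  if (is.character(reads)) reads <- read_reads(reads)
  if (nrow(chains) == 0L) return(chains)
  miss <- setdiff(unique(chains$read_id), names(reads))
  if (length(miss) > 0L) {
    stop("Read sequence missing for: ", miss[1], call. = FALSE)
  }
  seqs <- reads[chains$read_id]
  too_long <- chains$read_end > Biostrings::width(seqs)
  if (any(too_long)) {
    stop("Chain read interval exceeds sequence length for read ",
         chains$read_id[which(too_long)[1]], call. = FALSE)
  }
  sub <- Biostrings::subseq(seqs, start = chains$read_start + 1L,
                            end = chains$read_end)
  freq <- Biostrings::letterFrequency(sub, letters = c("A", "C", "G", "T", "N"))
  frac <- apply(freq, 1L, max) / pmax(1L, chains$read_end - chains$read_start)
  kept <- chains[frac <= max_single_base_frac, ]
  kept |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$chain_pos, .by_group = TRUE) |>
    dplyr::mutate(chain_pos = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that detects FASTQ from
#' the extension, trims names at the first whitespace and uppercases the
#' sequence so base-composition tests are case-insensitive.
#'
#' @param path FASTA or FASTQ file (extensions .fq/.fastq imply FASTQ).
#' @return Named `DNAStringSet`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  nm <- sub("\\s.*$", "", names(x))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- nm
  x
}
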