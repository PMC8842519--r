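#' Filter ambiguous chimeric chains
#'
#' Chimeric chains can arise from mapping ambiguity rather than genuine
#' chimeric molecules. Three independent, order-insensitive rules discard
#' such chains before clustering (so dropped chains contribute neither to
#' cluster support nor to expression counts):
#'
#' * `overlapping_genes` — any two genes in the chain have overlapping gene
#'   bodies (reads over overlapping loci cannot distinguish a fusion from
#'   normal transcription of either gene);
#' * `homologous_genes` — any gene pair in the chain is in the homolog
#'   index (split mappings across near-identical paralogs);
#' * `segmental_duplication` — the gene bodies of the first two genes are
#'   linked by an annotated segmental-duplication pair.
#'
#' Only chimeric reads are examined; normal and intergenic reads pass
#' through untouched.
#'
#' @param read_classes Per-read classification tibble from
#'   [classify_reads()].
#' @param chains Chain-entry tibble (needed to enumerate all genes of
#'   multi-gene chains).
#' @param db A `fusion_annotation`.
#' @param homologs Optional `homolog_index`.
#' @param sd Optional `sd_index`.
#' @return `read_classes` with a `filter_reason` column (`NA` for kept
#'   reads, otherwise the name of the triggering rule).
#' @export
filter_chimeric_chains <- function(read_classes, chains, db,
                                   homologs = NULL, sd = NULL) {
  read_classes$filter_reason <- NA_character_
  chim <- read_classes$read_id[read_classes$class == "chimeric"]
  if (length(chim) == 0L) return(read_classes)

  gene_sets <- chains |>
    dplyr::filter(.data$read_id %in% chim) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$chain_pos, .by_group = TRUE) |>
    dplyr::summarise(genes = list(unique(.data$gene_id)), .groups = "drop")

  reason <- purrr::map_chr(gene_sets$genes, function(gs) {
    prs <- utils::combn(gs, 2L)
    for (j in seq_len(ncol(prs))) {
      if (genes_overlap(db, prs[1, j], prs[2, j])) return("overlapping_genes")
    }
    if (!is.null(homologs)) {
      for (j in seq_len(ncol(prs))) {
        if (has_homolog_pair(homologs, prs[1, j], prs[2, j])) {
          return("homologous_genes")
        }
      }
    }
    if (!is.null(sd)) {
      g <- db$genes
      a <- g[g$gene_id == gs[1], ]
      b <- g[g$gene_id == gs[2], ]
      if (sd_linked(sd, a$chrom, a$body_start, a$body_end,
                    b$chrom, b$body_start, b$body_end)) {
        return("segmental_duplication")
      }
    }
    NA_character_
  })
  idx <- match(gene_sets$read_id, read_classes$read_id)
  read_classes$filter_reason[idx] <- reason
  read_classes
}

#' @rdname filter_chimeric_chains
#' @param gene_ids Character vector of the genes in one chain, in read order.
#' @export
filter_overlapping_genes <- function(gene_ids, db) {
  prs <- utils::combn(unique(gene_ids), 2L)
  any(vapply(seq_len(ncol(prs)),
             function(j) genes_overlap(db, prs[1, j], prs[2, j]), logical(1)))
}

#' @rdname filter_chimeric_chains
#' @export
filter_homologs <- function(gene_ids, homologs) {
  prs <- utils::combn(unique(gene_ids), 2L)
  any(has_homolog_pair(homologs, prs[1, ], prs[2, ]))
}

#' @rdname filter_chimeric_chains
#' @export
filter_segdup <- function(gene_ids, sd, db) {
  gs <- unique(gene_ids)
  g <- db$genes
  a <- g[g$gene_id == gs[1], ]
  b <- g[g$gene_id == gs[2], ]
  sd_linked(sd, a$chrom, a$body_start, a$body_end,
            b$chrom, b$body_start, b$body_end)
}
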