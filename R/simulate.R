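#' Configuration for the chimeric-read simulator
#'
#' The simulator emulates, at desk scale, the simulation design used to
#' benchmark long-read fusion callers: a toy genome with non-overlapping
#' multi-exon genes, log-normal per-gene expression, validated-fusion-style
#' events (deletions, inversions, translocations; a mix of homozygous and
#' heterozygous zygosity), read-through transcripts at 5% of the head gene's
#' expression that omit the head's last exon and the tail's first exon, and
#' a configurable fraction of reads randomly paired into artifactual
#' chimeras.
#'
#' Zygosity follows the standard diploid model: a heterozygous fusion is
#' expressed at 50% of the head gene's expression and leaves both member
#' genes at 50% of their normal expression; a homozygous fusion is expressed
#' at 100% and silences both members.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param n_chroms,chrom_length Toy genome shape.
#' @param genes_per_chrom Genes laid out left to right per chromosome.
#' @param exon_count_range,exon_length_range,intron_length_range,gene_gap_range
#'   Ranges (inclusive) for gene structure and spacing, in bp.
#' @param mean_expression Mean of the log-normal expression profile
#'   (reads per gene); a floor of `min_expression` keeps every simulated
#'   gene detectable, mirroring the use of expressed genes for event
#'   selection.
#' @param min_expression Expression floor.
#' @param n_fusions Number of gene fusions (default 16).
#' @param n_homozygous How many fusions are homozygous (default 10; the
#'   rest are heterozygous).
#' @param n_read_throughs Number of read-through events between adjacent
#'   same-strand genes (default 8).
#' @param read_through_expression_frac Read-through expression as a fraction
#'   of head-gene expression (default 0.05).
#' @param heterozygous_expression_frac Heterozygous fusion expression as a
#'   fraction of head-gene expression (default 0.5).
#' @param random_pairing_rate Fraction of simulated reads selected and
#'   randomly paired into chimeras (default 0.01).
#' @param overlapping_fusion If TRUE, one fusion pair is placed between two
#'   genes with overlapping genomic coordinates, exercising the
#'   overlapping-gene filter.
#' @param short_head_fusion If TRUE, one fusion uses a single-exon 80 bp
#'   head gene, the hardest regime for exon chaining: the gene-switch
#'   penalty on the first tail exon can outweigh the short head exon's own
#'   score, so such fusions may lose their head gene during chaining.
#' @param wobble Uniform perturbation (bp) applied to emitted genome
#'   interval ends to mimic alignment wobble.
#' @param polya_len If positive, a poly-A tail of this length is appended to
#'   every read sequence (not represented in the alignments).
#' @return A list of class `sim_config`.
#' @export
simulate_config <- function(seed = 1L, n_chroms = 4L, chrom_length = 1200000L,
                            genes_per_chrom = 20L,
                            exon_count_range = c(3L, 8L),
                            exon_length_range = c(100L, 300L),
                            intron_length_range = c(200L, 1000L),
                            gene_gap_range = c(30000L, 50000L),
                            mean_expression = 85, min_expression = 20L,
                            n_fusions = 16L, n_homozygous = 10L,
                            n_read_throughs = 8L,
                            read_through_expression_frac = 0.05,
                            heterozygous_expression_frac = 0.5,
                            random_pairing_rate = 0.01,
                            overlapping_fusion = FALSE,
                            short_head_fusion = FALSE,
                            wobble = 2L, polya_len = 0L) {
  stopifnot(n_homozygous <= n_fusions, random_pairing_rate >= 0,
            random_pairing_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a toy reference genome and annotation
#'
#' Deterministically (from `config$seed`) builds a random genome and a gene
#' annotation with non-overlapping multi-exon single-isoform genes laid out
#' along each chromosome, standing in for a real genome and annotation at
#' toy scale. With `overlapping_fusion = TRUE` the last chromosome
#' additionally carries exactly one pair of genes with overlapping bodies.
#'
#' @param config A [simulate_config()].
#' @return List with `genome` (named `DNAStringSet`) and `db`
#'   (`fusion_annotation`).
#' @export
make_toy_reference <- function(config = simulate_config()) {
  set.seed(config$seed)
  rint <- function(n, range) {
    if (range[1] == range[2]) rep(range[1], n)
    else sample(seq(range[1], range[2]), n, replace = TRUE)
  }
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))

  gene_rows <- list()
  exon_rows <- list()
  gid <- 0L
  place_gene <- function(chrom, start, strand, ex_len = NULL) {
    gid <<- gid + 1L
    id <- sprintf("G%04d", gid)
    if (is.null(ex_len)) {
      n_ex <- rint(1L, config$exon_count_range)
      ex_len <- rint(n_ex, config$exon_length_range)
    }
    n_ex <- length(ex_len)
    introns <- if (n_ex > 1L) rint(n_ex - 1L, config$intron_length_range)
               else integer()
    starts <- start + cumsum(c(0L, ex_len[-n_ex] + introns))
    ends <- starts + ex_len
    rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exon_rows[[length(exon_rows) + 1L]] <<- tibble::tibble(
      gene_id = id, gene_name = id, transcript_id = paste0(id, ".t1"),
      chrom = chrom, strand = strand, start = starts, end = ends,
      exon_rank = rank, n_exons = n_ex)
    gene_rows[[length(gene_rows) + 1L]] <<- tibble::tibble(
      gene_id = id, gene_name = id, chrom = chrom, strand = strand,
      body_start = starts[1], body_end = ends[n_ex])
    list(id = id, end = ends[n_ex])
  }

  for (chrom in chroms) {
    pos <- rint(1L, config$gene_gap_range %/% 4L)
    for (i in seq_len(config$genes_per_chrom)) {
      strand <- sample(c("+", "-"), 1L)
      placed <- place_gene(chrom, pos, strand)
      pos <- placed$end + rint(1L, config$gene_gap_range)
      if (pos > config$chrom_length - 20000L) break
    }
  }
  special <- list()
  chrom_end <- function(chrom) {
    g <- dplyr::bind_rows(gene_rows)
    max(g$body_end[g$chrom == chrom])
  }
  if (config$overlapping_fusion) {
    chrom <- chroms[length(chroms)]
    base <- chrom_end(chrom) + 40000L
    a <- place_gene(chrom, base, "+")
    # partner starts inside the first gene's body: overlapping pair
    b <- place_gene(chrom, base + max(200L, (a$end - base) %/% 3L), "+")
    special$overlapping_pair <- c(a$id, b$id)
  }
  if (config$short_head_fusion) {
    # TMPRSS2-style head gene contributing only ~80 bp to the fusion
    sh <- place_gene(chroms[1], chrom_end(chroms[1]) + 40000L, "+",
                     ex_len = 80L)
    special$short_head <- sh$id
  }

  genes <- dplyr::bind_rows(gene_rows)
  exons <- dplyr::bind_rows(exon_rows) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id,
                   .data$transcript_id, .data$exon_rank)
  if (max(exons$end) > config$chrom_length) {
    stop("gene specification exceeds chromosome length", call. = FALSE)
  }
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
                 prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
  }, ""))
  names(genome) <- chroms
  db <- list(genes = genes, exons = exons, exon_gr = exon_granges(exons))
  class(db) <- "fusion_annotation"
  list(genome = genome, db = db, special = special)
}

# spliced transcript sequence of a gene (transcription sense)
transcript_seq <- function(ref, gene_id, exon_ranks = NULL) {
  ex <- ref$db$exons[ref$db$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$exon_rank), ]
  if (!is.null(exon_ranks)) ex <- ex[ex$exon_rank %in% exon_ranks, ]
  chrom_seq <- ref$genome[[ex$chrom[1]]]
  pieces <- Biostrings::Views(chrom_seq, start = ex$start + 1L, end = ex$end)
  pieces <- as(pieces, "DNAStringSet")
  if (ex$strand[1] == "-") {
    pieces <- Biostrings::reverseComplement(pieces)
  }
  as.character(Biostrings::DNAStringSet(paste(as.character(pieces),
                                              collapse = "")))
}

# per-exon alignment segments of a (partial) transcript, in read order;
# read offset 0. Returns tibble of PAF-ready fields.
transcript_segments <- function(db, gene_id, exon_ranks = NULL) {
  ex <- db$exons[db$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$exon_rank), ]
  if (!is.null(exon_ranks)) ex <- ex[ex$exon_rank %in% exon_ranks, ]
  len <- ex$end - ex$start
  read_end <- cumsum(len)
  tibble::tibble(
    read_start = read_end - len, read_end = read_end,
    strand = ex$strand, target_name = ex$chrom,
    genome_start = ex$start, genome_end = ex$end)
}

#' Simulate reads, alignments and truth labels
#'
#' Emits normal reads following the expression profile, fusion reads joining
#' head-gene exons to tail-gene exons at a per-fusion junction, read-through
#' reads containing all exons except the head's last and the tail's first,
#' and random pairings formed by concatenating randomly selected reads in
#' pairs. Alignments are synthesised directly from the known simulated
#' coordinates (one PAF record per exon segment), bypassing a mapper so the
#' dataset is fully hermetic; interval ends receive a small uniform wobble.
#'
#' Event placement respects the genomic signatures of each class: deletion
#' fusions join distant same-strand genes on one chromosome, inversions join
#' opposite-strand genes, translocations join genes on different
#' chromosomes, and read-throughs join adjacent same-strand genes.
#'
#' @param ref Reference from [make_toy_reference()].
#' @param config The same [simulate_config()].
#' @return List with `reads` (named `DNAStringSet`), `paf` (alignment
#'   tibble; write with [write_paf()]), `truth` (read_id, class, gene_id,
#'   head_gene, tail_gene, cluster_id), `events` (one row per simulated
#'   fusion/read-through with type, zygosity and read count) and
#'   `expression` (post-modification per-gene expression).
#' @export
simulate_reads <- function(ref, config = simulate_config()) {
  set.seed(config$seed + 1L)
  db <- ref$db
  genes <- db$genes
  n_genes <- nrow(genes)

  expr <- pmax(config$min_expression,
               round(stats::rlnorm(n_genes,
                                   meanlog = log(config$mean_expression) - 0.125,
                                   sdlog = 0.5)))
  names(expr) <- genes$gene_id

  # --- event selection on the realized layout -------------------------------
  # reserve the deliberately pathological genes for their dedicated events
  used <- as.character(unlist(ref$special))
  by_pos <- genes |> dplyr::arrange(.data$chrom, .data$body_start)

  # read-throughs: adjacent same-strand gene pairs; head is the upstream gene
  # in transcription order
  rt_pairs <- list()
  for (ch in unique(by_pos$chrom)) {
    g <- by_pos[by_pos$chrom == ch, ]
    for (i in seq_len(nrow(g) - 1L)) {
      if (length(rt_pairs) >= config$n_read_throughs) break
      a <- g[i, ]; b <- g[i + 1L, ]
      if (a$strand != b$strand) next
      if (a$gene_id %in% used || b$gene_id %in% used) next
      if (b$body_start - a$body_end >= 500000L) next
      hd <- if (a$strand == "+") a$gene_id else b$gene_id
      tl <- setdiff(c(a$gene_id, b$gene_id), hd)
      rt_pairs[[length(rt_pairs) + 1L]] <- c(hd, tl)
      used <- c(used, hd, tl)
    }
  }

  # fusions: overlapping pair (if configured) + deletions, inversions,
  # translocations
  fusion_pairs <- list()
  fusion_types <- character()
  if (config$overlapping_fusion) {
    ov <- ref$special$overlapping_pair
    fusion_pairs[[1L]] <- ov
    fusion_types <- "overlapping"
    used <- c(used, ov)
  }
  if (config$short_head_fusion) {
    sh <- ref$special$short_head
    partner <- by_pos$gene_id[by_pos$chrom != genes$chrom[
      genes$gene_id == sh] & !(by_pos$gene_id %in% used)][1]
    fusion_pairs[[length(fusion_pairs) + 1L]] <- c(sh, partner)
    fusion_types <- c(fusion_types, "short_head")
    used <- c(used, sh, partner)
  }
  n_left <- config$n_fusions - length(fusion_pairs)
  want <- rep(c("deletion", "inversion", "translocation"),
              length.out = n_left)

  candidates <- function(type) {
    out <- list()
    if (type == "translocation") {
      pool <- by_pos[!(by_pos$gene_id %in% used), ]
      chs <- unique(pool$chrom)
      for (i in seq_along(chs)) {
        for (j in seq_along(chs)) {
          if (i == j) next
          ga <- pool$gene_id[pool$chrom == chs[i]]
          gb <- pool$gene_id[pool$chrom == chs[j]]
          if (length(ga) && length(gb)) {
            out[[length(out) + 1L]] <- c(ga[1], gb[1])
          }
        }
      }
    } else {
      for (ch in unique(by_pos$chrom)) {
        g <- by_pos[by_pos$chrom == ch & !(by_pos$gene_id %in% used), ]
        if (nrow(g) < 2L) next
        for (i in seq_len(nrow(g) - 1L)) {
          for (j in seq(i + 1L, nrow(g))) {
            a <- g[i, ]; b <- g[j, ]
            if (type == "deletion") {
              if (a$strand != b$strand) next
              if (b$body_start - a$body_end < 500000L) next
              hd <- if (a$strand == "+") a$gene_id else b$gene_id
            } else {  # inversion
              if (a$strand == b$strand) next
              hd <- a$gene_id
            }
            tl <- setdiff(c(a$gene_id, b$gene_id), hd)
            out[[length(out) + 1L]] <- c(hd, tl)
          }
        }
      }
    }
    out
  }

  for (type in want) {
    cands <- candidates(type)
    if (length(cands) == 0L) {
      cands <- candidates("translocation")
      type <- "translocation"
    }
    if (length(cands) == 0L) stop("could not place fusion events; ",
                                  "enlarge the gene layout", call. = FALSE)
    pick <- cands[[sample.int(length(cands), 1L)]]
    fusion_pairs[[length(fusion_pairs) + 1L]] <- pick
    fusion_types <- c(fusion_types, type)
    used <- c(used, pick)
  }

  zyg <- sample(rep(c("hom", "het"),
                    c(config$n_homozygous,
                      config$n_fusions - config$n_homozygous)))

  # --- expression modification by fusion zygosity ---------------------------
  fusion_reads <- integer(length(fusion_pairs))
  for (i in seq_along(fusion_pairs)) {
    hd <- fusion_pairs[[i]][1]; tl <- fusion_pairs[[i]][2]
    e_head <- expr[[hd]]
    if (zyg[i] == "hom") {
      fusion_reads[i] <- e_head
      expr[c(hd, tl)] <- 0L
    } else {
      fusion_reads[i] <- round(config$heterozygous_expression_frac * e_head)
      expr[c(hd, tl)] <- round(0.5 * expr[c(hd, tl)])
    }
  }
  rt_reads <- vapply(rt_pairs, function(p) {
    as.integer(round(config$read_through_expression_frac * expr[[p[1]]]))
  }, integer(1))

  # --- assemble reads -------------------------------------------------------
  seqs <- character()
  segs <- list()        # per template: segment tibble (read offsets local)
  tmpl_class <- character()
  tmpl_gene <- character()
  tmpl_head <- character()
  tmpl_tail <- character()
  tmpl_count <- integer()

  add_template <- function(seq, seg, class, gene = NA, head = NA, tail = NA,
                           count) {
    if (count <= 0L) return(invisible())
    seqs[[length(seqs) + 1L]] <<- seq
    segs[[length(segs) + 1L]] <<- seg
    tmpl_class[[length(tmpl_class) + 1L]] <<- class
    tmpl_gene[[length(tmpl_gene) + 1L]] <<- gene
    tmpl_head[[length(tmpl_head) + 1L]] <<- head
    tmpl_tail[[length(tmpl_tail) + 1L]] <<- tail
    tmpl_count[[length(tmpl_count) + 1L]] <<- as.integer(count)
  }

  for (g in genes$gene_id) {
    if (expr[[g]] > 0L) {
      add_template(transcript_seq(ref, g), transcript_segments(db, g),
                   "normal", gene = g, count = expr[[g]])
    }
  }
  for (i in seq_along(fusion_pairs)) {
    hd <- fusion_pairs[[i]][1]; tl <- fusion_pairs[[i]][2]
    nh <- db$exons$n_exons[match(hd, db$exons$gene_id)]
    nt <- db$exons$n_exons[match(tl, db$exons$gene_id)]
    # validated fusions retain a substantial 5' head portion and a
    # multi-exon 3' tail: keep >= 2 exons on each side of the junction
    # where the gene structure allows (a single-exon short head gene, as
    # configured by short_head_fusion, contributes its only exon)
    pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1
    j <- if (nh >= 3L) pick1(2:(nh - 1L)) else max(1L, nh - 1L)
    k <- if (nt >= 3L) pick1(2:(nt - 1L)) else min(2L, nt)
    head_seg <- transcript_segments(db, hd, seq_len(j))
    tail_seg <- transcript_segments(db, tl, k:nt)
    off <- max(head_seg$read_end)
    tail_seg$read_start <- tail_seg$read_start + off
    tail_seg$read_end <- tail_seg$read_end + off
    add_template(paste0(transcript_seq(ref, hd, seq_len(j)),
                        transcript_seq(ref, tl, k:nt)),
                 dplyr::bind_rows(head_seg, tail_seg),
                 "fusion", head = hd, tail = tl, count = fusion_reads[i])
  }
  for (i in seq_along(rt_pairs)) {
    hd <- rt_pairs[[i]][1]; tl <- rt_pairs[[i]][2]
    nh <- db$exons$n_exons[match(hd, db$exons$gene_id)]
    nt <- db$exons$n_exons[match(tl, db$exons$gene_id)]
    if (nh < 2L || nt < 2L) next
    head_seg <- transcript_segments(db, hd, seq_len(nh - 1L))
    tail_seg <- transcript_segments(db, tl, 2:nt)
    off <- max(head_seg$read_end)
    tail_seg$read_start <- tail_seg$read_start + off
    tail_seg$read_end <- tail_seg$read_end + off
    add_template(paste0(transcript_seq(ref, hd, seq_len(nh - 1L)),
                        transcript_seq(ref, tl, 2:nt)),
                 dplyr::bind_rows(head_seg, tail_seg),
                 "read_through", head = hd, tail = tl, count = rt_reads[i])
  }

  # expand templates into reads
  tmpl_idx <- rep(seq_along(tmpl_count), tmpl_count)
  n_reads <- length(tmpl_idx)
  read_class <- tmpl_class[tmpl_idx]
  read_gene <- tmpl_gene[tmpl_idx]
  read_head <- tmpl_head[tmpl_idx]
  read_tail <- tmpl_tail[tmpl_idx]

  # random pairing: select a fraction of reads and join them two by two
  n_rp_reads <- 2L * (round(config$random_pairing_rate * n_reads) %/% 2L)
  rp_members <- if (n_rp_reads >= 2L) sample.int(n_reads, n_rp_reads)
                else integer()
  primary_gene <- ifelse(read_class == "normal", read_gene, read_head)

  read_id <- sprintf("read%06d", seq_len(n_reads))
  truth <- tibble::tibble(
    read_id = read_id, class = read_class, gene_id = read_gene,
    head_gene = read_head, tail_gene = read_tail)

  paf_parts <- vector("list", n_reads)
  seq_out <- character(n_reads)
  wob <- function(x) {
    if (config$wobble <= 0L) return(x)
    x + sample(seq(-config$wobble, config$wobble), length(x), replace = TRUE)
  }
  seg_for <- function(t_i) {
    s <- segs[[t_i]]
    gs <- wob(s$genome_start); ge <- wob(s$genome_end)
    swap <- gs >= ge
    s$genome_start <- pmax(0L, ifelse(swap, s$genome_start, gs))
    s$genome_end <- ifelse(swap, s$genome_end, ge)
    s
  }

  half <- length(rp_members) %/% 2L
  rp_first <- rp_members[seq_len(half)]
  rp_second <- rp_members[half + seq_len(half)]
  is_second <- logical(n_reads)
  is_second[rp_second] <- TRUE

  for (i in seq_len(n_reads)) {
    if (is_second[i]) next  # absorbed into its partner
    s <- seg_for(tmpl_idx[i])
    sq <- seqs[[tmpl_idx[i]]]
    j <- match(i, rp_first)
    if (!is.na(j)) {
      p <- rp_second[j]
      s2 <- seg_for(tmpl_idx[p])
      off <- nchar(sq)
      s2$read_start <- s2$read_start + off
      s2$read_end <- s2$read_end + off
      s <- dplyr::bind_rows(s, s2)
      sq <- paste0(sq, seqs[[tmpl_idx[p]]])
      truth$class[i] <- "random_pairing"
      truth$gene_id[i] <- NA_character_
      truth$head_gene[i] <- primary_gene[i]
      truth$tail_gene[i] <- primary_gene[p]
    }
    s$read_id <- read_id[i]
    s$read_length <- nchar(sq) + config$polya_len
    paf_parts[[i]] <- s
    seq_out[i] <- if (config$polya_len > 0L) {
      paste0(sq, strrep("A", config$polya_len))
    } else sq
  }

  keep <- !is_second
  truth <- truth[keep, ]
  truth$cluster_id <- dplyr::case_when(
    truth$class == "normal" ~ paste0("gene:", truth$gene_id),
    TRUE ~ paste0(truth$class, ":", pmin(truth$head_gene, truth$tail_gene),
                  "|", pmax(truth$head_gene, truth$tail_gene)))

  paf <- dplyr::bind_rows(paf_parts[keep])
  chrom_len <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                               names(ref$genome))
  paf <- paf |>
    dplyr::mutate(
      target_length = unname(chrom_len[.data$target_name]),
      n_match = .data$read_end - .data$read_start,
      block_len = .data$read_end - .data$read_start,
      mapq = 60L) |>
    dplyr::select("read_id", "read_length", "read_start", "read_end",
                  "strand", "target_name", "target_length", "genome_start",
                  "genome_end", "n_match", "block_len", "mapq")

  reads <- Biostrings::DNAStringSet(seq_out[keep])
  names(reads) <- read_id[keep]

  events <- tibble::tibble(
    class = c(rep("fusion", length(fusion_pairs)),
              rep("read_through", length(rt_pairs))),
    head_gene = c(vapply(fusion_pairs, `[[`, "", 1L),
                  vapply(rt_pairs, `[[`, "", 1L)),
    tail_gene = c(vapply(fusion_pairs, `[[`, "", 2L),
                  vapply(rt_pairs, `[[`, "", 2L)),
    type = c(fusion_types, rep("read_through", length(rt_pairs))),
    zygosity = c(zyg, rep(NA_character_, length(rt_pairs))),
    n_reads = c(fusion_reads, rt_reads))

  list(reads = reads, paf = paf, truth = truth, events = events,
       expression = tibble::tibble(gene_id = genes$gene_id,
                                   expression = as.integer(unname(expr))))
}

#' Write simulated alignments as PAF
#'
#' @param paf Alignment tibble from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   paf$read_id, paf$read_length, paf$read_start, paf$read_end,
                   paf$strand, paf$target_name, paf$target_length,
                   paf$genome_start, paf$genome_end, paf$n_match,
                   paf$block_len, paf$mapq)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Writes the genome FASTA, annotation GTF, reads FASTA, alignment PAF and
#' truth-label TSV for a simulated dataset.
#'
#' @param ref Reference from [make_toy_reference()].
#' @param sim Simulation from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_simulated_dataset <- function(ref, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    reads = file.path(dir, "reads.fa"),
    paf = file.path(dir, "alignments.paf"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(ref$genome, paths$genome)
  write_annotation_gtf(ref$db, paths$gtf)
  Biostrings::writeXStringSet(sim$reads, paths$reads)
  write_paf(sim$paf, paths$paf)
  readr::write_tsv(sim$truth, paths$truth)
  paths
}
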