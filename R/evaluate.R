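#' Pair-counting Adjusted Rand Index
#'
#' Compares a predicted clustering with a ground-truth clustering by
#' counting read pairs: TP pairs share a cluster in both clusterings, TN
#' pairs share a cluster in neither, FP pairs share only a predicted
#' cluster, FN pairs share only a truth cluster. The ARI is the
#' chance-corrected agreement
#' `2(TP*TN - FN*FP) / ((TP+FN)(FN+TN) + (TP+FP)(FP+TN))`.
#' Reads without a predicted assignment should be encoded as singleton
#' clusters by the caller (see [evaluate_against_truth()]). Two identical
#' clusterings give ARI 1 by convention even in the degenerate all-singleton
#' case.
#'
#' @param truth Character vector of ground-truth cluster ids, one per read.
#' @param predicted Character vector of predicted cluster ids, aligned with
#'   `truth`.
#' @return A list with `ari`, `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' pair_counting_ari(c("a", "a", "b"), c("x", "x", "y"))$ari  # 1
pair_counting_ari <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  n <- length(truth)
  ch2 <- function(x) x * (x - 1) / 2
  tp_plus_fn <- sum(ch2(table(truth)))
  tp_plus_fp <- sum(ch2(table(predicted)))
  tp <- sum(ch2(table(paste(truth, predicted, sep = "\r"))))
  total <- ch2(n)
  fn <- tp_plus_fn - tp
  fp <- tp_plus_fp - tp
  tn <- total - tp - fn - fp
  denom <- (tp + fn) * (fn + tn) + (tp + fp) * (fp + tn)
  ari <- if (denom == 0) {
    if (fn + fp == 0) 1 else 0
  } else {
    2 * (tp * tn - fn * fp) / denom
  }
  list(ari = ari, tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Evaluate fusion calls against simulated ground truth
#'
#' Computes, for a pipeline run on a simulated dataset:
#' * fusion recall and precision — truth fusion gene pairs vs `PASS:GF`
#'   calls (unordered pair match);
#' * the pair-counting ARI over all ground-truth chimeric reads (fusion,
#'   read-through and random-pairing classes), with reads the pipeline did
#'   not place in a chimeric cluster counted as singleton clusters;
#' * mean FiN per ground-truth chimera class, over the clusters whose gene
#'   pair matches a truth event of that class (clusters matching no event
#'   are random-pairing clusters).
#'
#' @param result A `fusion_calls` object from [call_fusions()].
#' @param sim Simulation list from [simulate_reads()].
#' @return A list of metrics (JSON-serialisable).
#' @export
evaluate_against_truth <- function(result, sim) {
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

  truth_fusions <- dplyr::filter(sim$events, .data$class == "fusion")
  truth_fusion_keys <- pair_key(truth_fusions$head_gene,
                                truth_fusions$tail_gene)
  truth_rt_keys <- pair_key(
    sim$events$head_gene[sim$events$class == "read_through"],
    sim$events$tail_gene[sim$events$class == "read_through"])

  gf <- dplyr::filter(result$calls, .data$label == "PASS:GF")
  gf_keys <- pair_key(gf$head_gene, gf$tail_gene)
  n_recalled <- sum(truth_fusion_keys %in% gf_keys)
  recall <- n_recalled / max(1L, length(truth_fusion_keys))
  precision <- if (nrow(gf) == 0L) NA_real_
               else sum(gf_keys %in% truth_fusion_keys) / nrow(gf)

  # ARI over ground-truth chimeric reads
  chim_truth <- dplyr::filter(
    sim$truth, .data$class %in% c("fusion", "read_through", "random_pairing"))
  pred <- result$reads[match(chim_truth$read_id, result$reads$read_id), ]
  pred_cluster <- ifelse(
    !is.na(pred$cluster_head),
    pair_key(pred$cluster_head, pred$cluster_tail),
    paste0("singleton:", chim_truth$read_id))
  ari <- pair_counting_ari(chim_truth$cluster_id, pred_cluster)

  # mean FiN per truth class of the matching clusters
  calls <- result$calls
  call_keys <- pair_key(calls$head_gene, calls$tail_gene)
  cls <- dplyr::case_when(
    call_keys %in% truth_fusion_keys ~ "fusion",
    call_keys %in% truth_rt_keys ~ "read_through",
    TRUE ~ "random_pairing")
  mean_fin <- tapply(calls$fin, cls, mean)

  list(
    n_truth_fusions = length(truth_fusion_keys),
    n_fusions_called = nrow(gf),
    n_fusions_recalled = n_recalled,
    fusion_recall = recall,
    fusion_precision = precision,
    ari = ari$ari,
    ari_pairs = ari[c("tp", "tn", "fp", "fn")],
    n_truth_chimeric_reads = nrow(chim_truth),
    mean_fin_fusion = unname(mean_fin["fusion"]),
    mean_fin_read_through = unname(mean_fin["read_through"]),
    mean_fin_random_pairing = unname(mean_fin["random_pairing"]))
}

#' Simulate, call and evaluate in one step
#'
#' Generates a toy reference and reads from `config`, runs the full
#' fusion-calling pipeline with `fusion_cfg`, and scores the result against
#' the simulation's ground truth.
#'
#' @param config A [simulate_config()].
#' @param fusion_cfg A [fusion_config()].
#' @param use_files If TRUE, the simulated dataset is round-tripped through
#'   GTF/PAF/FASTA files in a temporary directory, exercising the on-disk
#'   interfaces; otherwise in-memory objects are passed directly.
#' @return List with `ref`, `sim`, `result` (a `fusion_calls`) and
#'   `metrics` (from [evaluate_against_truth()]).
#' @export
run_end_to_end <- function(config = simulate_config(),
                           fusion_cfg = fusion_config(),
                           use_files = FALSE) {
  ref <- make_toy_reference(config)
  sim <- simulate_reads(ref, config)
  if (use_files) {
    dir <- tempfile("longfuse_sim_")
    paths <- write_simulated_dataset(ref, sim, dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    result <- call_fusions(paths$paf, paths$gtf, reads = paths$reads,
                           config = fusion_cfg)
  } else {
    result <- call_fusions(sim$paf, ref$db, reads = sim$reads,
                           config = fusion_cfg)
  }
  metrics <- evaluate_against_truth(result, sim)
  list(ref = ref, sim = sim, result = result, metrics = metrics)
}
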