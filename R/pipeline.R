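#' Run the full phasing analysis pipeline
#'
#' Executes the stage chain on a run's read pairs: barcode extraction
#' (handle matching) -> iterative barcode clustering -> read-to-target
#' assignment by primer prefix -> depth filtering -> per-target variant
#' sub-clustering -> consensus calling and amplification-clonality
#' classification -> k-mer taxonomic classification -> phasing
#' statistics (presence fractions, observed / shuffled-null / corrected
#' phasing rates, hit-list overlap reduction). All randomness (the
#' shuffle null) is forked from `seed`, so identical inputs give
#' identical results.
#'
#' @param run a `phasing_run` from [simulate_phasing_run()], or a list
#'   with a `reads` data.frame (`read_id`, `seq1`, `seq2`) and a
#'   `reference` `species_reference` plus a `config` carrying the read
#'   layout (see [sim_config()]); use [read_fastq_pairs()] and
#'   [read_reference_fasta()] for file input.
#' @param max_barcode_mismatch barcode grouping tolerance (default 2).
#' @param handle_max_mismatch combined handle tolerance (default 4).
#' @param max_primer_mismatch primer prefix tolerance (default 2).
#' @param min_reads_per_target,min_cluster_reads depth filters (see
#'   [filter_clusters()]).
#' @param max_mismatch_fraction variant sub-clustering threshold.
#' @param dominant_threshold monoclonal-amplification threshold.
#' @param k,margin classifier k-mer size and score margin.
#' @param n_shuffles permutations for the random match rate.
#' @param phasing_on_monoclonal restrict the phasing statistics to
#'   clusters with monoclonal amplification (default TRUE).
#' @param seed integer seed; defaults to the run config's seed.
#' @return an object of class `phasing_result`: list with `summary`
#'   (the headline statistics), `clusters`, `read_clusters` (read ->
#'   cluster map), `assignments`, `consensus`, `calls`, `counts`
#'   (stage-by-stage read conservation) and `params`.
#' @export
run_phasing_pipeline <- function(run,
                                 max_barcode_mismatch = 2,
                                 handle_max_mismatch = 4,
                                 max_primer_mismatch = 2,
                                 min_reads_per_target = 3,
                                 min_cluster_reads = 5,
                                 max_mismatch_fraction = 0.02,
                                 dominant_threshold = 0.90,
                                 k = 8, margin = 0.05,
                                 n_shuffles = 100,
                                 phasing_on_monoclonal = TRUE,
                                 seed = run$config$seed) {
  cfg <- run$config
  reference <- run$reference
  layout <- read_layout(cfg$handle_5p, cfg$handle_3p, cfg$barcode_length,
                        offset = 0, handle_max_mismatch = handle_max_mismatch)
  target_primers <- attr(reference, "target_primers")
  target_ids <- sort(unique(reference$target_id))

  params <- list(max_barcode_mismatch = max_barcode_mismatch,
                 handle_max_mismatch = handle_max_mismatch,
                 max_primer_mismatch = max_primer_mismatch,
                 min_reads_per_target = min_reads_per_target,
                 min_cluster_reads = min_cluster_reads,
                 max_mismatch_fraction = max_mismatch_fraction,
                 dominant_threshold = dominant_threshold,
                 k = k, margin = margin, n_shuffles = n_shuffles,
                 phasing_on_monoclonal = phasing_on_monoclonal, seed = seed)

  empty_summary <- function(counts) {
    structure(list(summary = list(n_clusters = 0L, n_eligible = 0L,
                                  frac_target1_only = NA_real_,
                                  frac_target2_only = NA_real_,
                                  frac_both = NA_real_,
                                  monoclonal_rate = NA_real_,
                                  p_obs = NA_real_, p_rand = NA_real_,
                                  p_rand_se = NA_real_, p_corr = NA_real_,
                                  overlap = NULL, target_ids = target_ids),
                   clusters = NULL, read_clusters = NULL, assignments = NULL,
                   consensus = NULL, calls = NULL, counts = counts,
                   params = params),
              class = "phasing_result")
  }

  n_in <- nrow(run$reads)
  counts <- list(reads_in = n_in)
  if (n_in == 0L) return(empty_summary(counts))

  # 1. barcode extraction
  obs <- extract_barcodes(run$reads$seq1, layout)
  ok <- obs$status == "ok"
  counts$reads_barcode_rejected <- sum(!ok)
  if (!any(ok)) return(empty_summary(counts))

  # 2. barcode clustering
  cl <- cluster_barcodes(obs$barcode[ok], max_mismatch = max_barcode_mismatch)
  read_clusters <- data.frame(
    read_id = run$reads$read_id[ok],
    cluster_id = cl$members$cluster_id[match(obs$barcode[ok], cl$members$barcode)],
    stringsAsFactors = FALSE)

  # 3. target assignment
  target <- assign_reads_to_targets(run$reads$seq2[ok], target_primers,
                                    max_primer_mismatch)
  counts$reads_target_unassigned <- sum(is.na(target))
  assignments <- data.frame(read_id = read_clusters$read_id,
                            cluster_id = read_clusters$cluster_id,
                            target_id = target,
                            seq2 = run$reads$seq2[ok],
                            stringsAsFactors = FALSE)
  assignments <- assignments[!is.na(assignments$target_id), , drop = FALSE]
  if (!nrow(assignments)) return(empty_summary(counts))

  # 4. depth filtering
  flt <- filter_clusters(assignments, min_reads_per_target, min_cluster_reads)
  counts$reads_filtered <- flt$report$n_reads_in - flt$report$n_reads_retained
  counts$filter_report <- flt$report
  retained <- flt$retained
  if (!nrow(retained)) return(empty_summary(counts))

  # 5-6. variant sub-clustering, consensus and clonality per cluster
  grp <- split(retained, retained$cluster_id)
  cons_rows <- list()
  clonality <- character(length(grp))
  names(clonality) <- names(grp)
  for (cid in names(grp)) {
    g <- grp[[cid]]
    by_target <- split(g$seq2, g$target_id)
    vgs <- lapply(by_target, subcluster_reads,
                  max_mismatch_fraction = max_mismatch_fraction)
    clonality[cid] <- classify_amplification_clonality(vgs, dominant_threshold)
    for (t in names(vgs)) {
      vg <- vgs[[t]]
      asn <- attr(vg, "assignment")
      dom_reads <- by_target[[t]][asn == 1L]
      cons_rows[[paste(cid, t)]] <- data.frame(
        cluster_id = cid, target_id = t,
        consensus = call_consensus(dom_reads),
        support = vg$n_reads[1L],
        n_variant_groups = nrow(vg),
        dominant_fraction = vg$n_reads[1L] / sum(vg$n_reads),
        stringsAsFactors = FALSE)
    }
  }
  consensus <- do.call(rbind, cons_rows)
  rownames(consensus) <- NULL

  # 7. taxonomic classification
  index <- build_reference_index(reference, k = k)
  tax <- lapply(seq_len(nrow(consensus)), function(i)
    classify_consensus(consensus$consensus[i], index,
                       target_id = consensus$target_id[i], margin = margin))
  calls <- data.frame(cluster_id = consensus$cluster_id,
                      target_id = consensus$target_id,
                      best_call = vapply(tax, `[[`, "", "best_call"),
                      n_hits = vapply(tax, `[[`, 0L, "n_hits"),
                      monoclonal = clonality[consensus$cluster_id] == "monoclonal",
                      stringsAsFactors = FALSE)
  calls$hit_list <- lapply(tax, function(x) x$hit_list$species_id)

  # 8. phasing statistics
  pres <- target_presence_fractions(calls, target_ids)
  stat_calls <- if (phasing_on_monoclonal)
    calls[calls$monoclonal, , drop = FALSE] else calls
  p_obs <- p_corr <- NA_real_
  p_rand <- list(p_rand = NA_real_, se = NA_real_)
  n_eligible <- 0L
  ok_stats <- tryCatch({
    po <- phasing_rate(stat_calls, target_ids)
    pr <- random_match_rate(stat_calls, n_shuffles, seed, target_ids)
    list(po = po, pr = pr)
  }, beadphase_undefined = function(e) NULL)
  if (!is.null(ok_stats)) {
    p_obs <- as.numeric(ok_stats$po)
    n_eligible <- attr(ok_stats$po, "n_eligible")
    p_rand <- ok_stats$pr
    p_corr <- corrected_phasing_rate(p_obs, p_rand$p_rand)
  }
  both <- .eligible_calls(calls, target_ids)
  overlap <- NULL
  if (nrow(both)) {
    key <- paste(calls$cluster_id, calls$target_id)
    h1 <- calls$hit_list[match(paste(both$cluster_id, target_ids[1L]), key)]
    h2 <- calls$hit_list[match(paste(both$cluster_id, target_ids[2L]), key)]
    overlap <- hitlist_overlap_reduction(h1, h2)
  }

  structure(list(
    summary = list(n_clusters = length(grp),
                   n_eligible = n_eligible,
                   frac_target1_only = pres$frac_target1_only,
                   frac_target2_only = pres$frac_target2_only,
                   frac_both = pres$frac_both,
                   monoclonal_rate = mean(clonality == "monoclonal"),
                   p_obs = p_obs, p_rand = p_rand$p_rand,
                   p_rand_se = p_rand$se, p_corr = p_corr,
                   overlap = overlap, target_ids = target_ids),
    clusters = cl$clusters, read_clusters = read_clusters,
    assignments = retained, consensus = consensus, calls = calls,
    counts = counts, params = params), class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Phasing pipeline result: %d clusters passed filtering\n",
              s$n_clusters))
  cat(sprintf("  target presence: %s only %.1f%%, %s only %.1f%%, both %.1f%%\n",
              s$target_ids[1L], 100 * s$frac_target1_only,
              s$target_ids[2L], 100 * s$frac_target2_only,
              100 * s$frac_both))
  cat(sprintf("  monoclonal amplification: %.1f%%\n", 100 * s$monoclonal_rate))
  if (!is.na(s$p_obs)) {
    cat(sprintf("  observed phasing rate:  %.1f%% (%d eligible clusters)\n",
                100 * s$p_obs, s$n_eligible))
    cat(sprintf("  random match rate:      %.1f%% (+/- %.2f%% SE)\n",
                100 * s$p_rand, 100 * s$p_rand_se))
    cat(sprintf("  corrected phasing rate: %.1f%%\n", 100 * s$p_corr))
  }
  invisible(x)
}

#' Run the bead-sorting analysis pipeline
#'
#' Demultiplexes reads to wells by tag, clusters each well's barcodes
#' with the iterative grouping procedure, classifies every well as
#' monoclonal / polyclonal / empty, and reports the monoclonal fraction
#' among non-empty wells, the observable the Poisson loading model
#' predicts.
#'
#' @param run a `sorting_run` from [simulate_sorting_run()], or a list
#'   with `reads` (`read_id`, `seq1`), `well_tags` and `config`.
#' @param max_tag_mismatch well tag tolerance (default 2).
#' @param handle_max_mismatch combined handle tolerance (default 4).
#' @param max_barcode_mismatch barcode grouping tolerance (default 2).
#' @param min_fraction well-clonality read-share threshold.
#' @return an object of class `sorting_result`: list with `wells`
#'   (per-well table), `monoclonal_fraction`, `counts`, `params`.
#' @export
run_sorting_pipeline <- function(run, max_tag_mismatch = 2,
                                 handle_max_mismatch = 4,
                                 max_barcode_mismatch = 2,
                                 min_fraction = 0.10) {
  cfg <- run$config
  tags <- run$well_tags
  well <- demultiplex_wells(run$reads$seq1, tags, max_tag_mismatch)
  counts <- list(reads_in = nrow(run$reads),
                 reads_unassigned_well = sum(is.na(well)))
  layout <- read_layout(cfg$handle_5p, cfg$handle_3p, cfg$barcode_length,
                        offset = nchar(tags[1L]),
                        handle_max_mismatch = handle_max_mismatch)
  rows <- lapply(seq_along(tags), function(w) {
    seqs <- run$reads$seq1[!is.na(well) & well == w]
    obs <- extract_barcodes(seqs, layout)
    bcs <- obs$barcode[obs$status == "ok"]
    if (!length(bcs))
      return(data.frame(well = w, n_reads = length(seqs), n_used = 0L,
                        n_clusters = 0L, label = "empty",
                        stringsAsFactors = FALSE))
    cl <- cluster_barcodes(bcs, max_mismatch = max_barcode_mismatch)
    lab <- classify_well_clonality(cl, min_fraction)
    data.frame(well = w, n_reads = length(seqs), n_used = length(bcs),
               n_clusters = nrow(cl$clusters), label = lab,
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, rows)
  wells$well_tag <- tags
  nonempty <- wells$label != "empty"
  structure(list(wells = wells,
                 monoclonal_fraction = if (any(nonempty))
                   mean(wells$label[nonempty] == "monoclonal") else NA_real_,
                 counts = counts,
                 params = list(max_tag_mismatch = max_tag_mismatch,
                               handle_max_mismatch = handle_max_mismatch,
                               max_barcode_mismatch = max_barcode_mismatch,
                               min_fraction = min_fraction)),
            class = "sorting_result")
}

#' @export
print.sorting_result <- function(x, ...) {
  tab <- table(x$wells$label)
  cat(sprintf("Sorting pipeline result: %d wells (%s)\n", nrow(x$wells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  if (!is.na(x$monoclonal_fraction))
    cat(sprintf("  monoclonal fraction of non-empty wells: %.1f%%\n",
                100 * x$monoclonal_fraction))
  invisible(x)
}

#' Truth-derived single-fragment fraction of eligible clusters
#'
#' Using the simulator's ground truth, computes the fraction of the
#' pipeline's phasing-eligible clusters whose member reads all derive
#' from a single genomic fragment, i.e. the fraction for which a target
#' match reflects genuine single-molecule phasing. The pipeline's
#' corrected phasing rate estimates this quantity.
#'
#' @param run the simulated `phasing_run`.
#' @param result the `phasing_result` from [run_phasing_pipeline()] on
#'   that run.
#' @return the truth fraction, with attribute `n_eligible`.
#' @export
truth_single_fragment_fraction <- function(run, result) {
  stopifnot(inherits(run, "phasing_run"), inherits(result, "phasing_result"))
  calls <- result$calls
  if (result$params$phasing_on_monoclonal)
    calls <- calls[calls$monoclonal, , drop = FALSE]
  e <- .eligible_calls(calls, result$summary$target_ids)
  if (!nrow(e)) stop_undefined("no eligible clusters")
  rc <- result$read_clusters
  frag <- run$truth$reads$fragment_id[match(rc$read_id, run$truth$reads$read_id)]
  nfrag <- vapply(split(frag, rc$cluster_id), function(f)
    length(unique(f)), 0L)
  structure(mean(nfrag[e$cluster_id] == 1L), n_eligible = nrow(e))
}
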