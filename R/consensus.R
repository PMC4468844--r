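#' Assign reads to target regions by primer prefix
#'
#' Read 2 of each pair starts with the target-specific primer; a read is
#' assigned to the unique target whose primer matches the read-2 prefix
#' within `max_primer_mismatch` (default 2), else left unassigned. The
#' primer set is validated up front: two primers whose truncated
#' Hamming distance is at most `2 * max_primer_mismatch` could both
#' match one read and are rejected as an ambiguous design.
#'
#' @param seqs character vector of read-2 sequences.
#' @param target_primers named character vector, primer per target id.
#' @param max_primer_mismatch mismatch tolerance on the primer prefix.
#' @return character vector of target ids, NA when unassigned.
#' @export
assign_reads_to_targets <- function(seqs, target_primers,
                                    max_primer_mismatch = 2) {
  if (is.null(names(target_primers)) || !length(target_primers))
    stop_invalid("'target_primers' must be a named character vector")
  if (length(target_primers) > 1L) {
    for (i in seq_len(length(target_primers) - 1L))
      for (j in (i + 1L):length(target_primers)) {
        m <- min(nchar(target_primers[i]), nchar(target_primers[j]))
        d <- .hamming_pair(substr(target_primers[i], 1L, m),
                           substr(target_primers[j], 1L, m))
        if (d <= 2L * max_primer_mismatch)
          stop_invalid("ambiguous primer design: truncated distance must exceed 2*max_primer_mismatch")
      }
  }
  out <- rep(NA_character_, length(seqs))
  if (!length(seqs)) return(out)
  for (t in names(target_primers)) {
    p <- target_primers[[t]]
    long <- nchar(seqs) >= nchar(p) & is.na(out)
    if (!any(long)) next
    mm <- .mm_to_constant(seqs[long], p, 1L)
    out[which(long)[mm <= max_primer_mismatch]] <- t
  }
  out
}

#' Filter under-supported target groups and clusters
#'
#' Depth-dependent filtering applied after reads have been grouped by
#' barcode cluster and target: (cluster, target) groups with fewer than
#' `min_reads_per_target` reads are dropped, then clusters whose
#' surviving assigned reads total fewer than `min_cluster_reads` are
#' dropped entirely.
#'
#' @param assignments data.frame with at least `cluster_id` and
#'   `target_id` columns, one row per assigned read.
#' @param min_reads_per_target minimum reads per (cluster, target) group.
#' @param min_cluster_reads minimum surviving reads per cluster.
#' @return list with `retained` (the filtered data.frame) and `report`
#'   (reads and groups/clusters removed per rule).
#' @export
filter_clusters <- function(assignments, min_reads_per_target = 3,
                            min_cluster_reads = 5) {
  key <- paste(assignments$cluster_id, assignments$target_id, sep = "\r")
  grp_n <- table(key)
  small_grp <- names(grp_n)[grp_n < min_reads_per_target]
  keep1 <- !(key %in% small_grp)
  reads_dropped_target <- sum(!keep1)
  a1 <- assignments[keep1, , drop = FALSE]
  cl_n <- table(a1$cluster_id)
  small_cl <- names(cl_n)[cl_n < min_cluster_reads]
  keep2 <- !(a1$cluster_id %in% small_cl)
  retained <- a1[keep2, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       report = list(
         n_reads_in = nrow(assignments),
         n_reads_retained = nrow(retained),
         n_target_groups_dropped = length(small_grp),
         n_reads_dropped_small_target_group = reads_dropped_target,
         n_clusters_dropped = length(small_cl),
         n_reads_dropped_small_cluster = sum(!keep2)))
}

#' Sub-cluster a target group's reads into variant groups
#'
#' Greedy abundance-seeded grouping of read sequences (same algorithm
#' shape as [cluster_barcodes()]) with a per-pair mismatch ceiling of
#' `max_mismatch_fraction` times the compared length; comparisons are
#' truncated to the shorter read. At the default 2% threshold,
#' sequencing errors collapse onto one variant while distinct template
#' molecules (e.g. 16S regions of different species at a few percent
#' divergence) separate.
#'
#' @param reads character vector of read sequences from one (cluster,
#'   target) group.
#' @param max_mismatch_fraction per-base mismatch tolerance.
#' @return data.frame of variant groups sorted by decreasing size:
#'   `variant_id`, `representative` (most abundant read sequence),
#'   `n_reads`; with attribute `assignment`, the variant index of each
#'   input read.
#' @export
subcluster_reads <- function(reads, max_mismatch_fraction = 0.02) {
  empty <- data.frame(variant_id = integer(0), representative = character(0),
                      n_reads = integer(0), stringsAsFactors = FALSE)
  if (!length(reads)) return(structure(empty, assignment = integer(0)))
  tab <- table(reads)
  uq <- names(tab)
  cnt <- as.numeric(tab)
  cl <- .iterative_cluster(uq, cnt,
                           function(li, lc) max_mismatch_fraction * pmin(li, lc))
  rep_of <- vapply(split(seq_along(uq), cl), function(i) {
    i <- i[order(-cnt[i], uq[i], method = "radix")]
    uq[i[1L]]
  }, character(1))
  size <- vapply(split(cnt, cl), sum, 0)
  ord <- order(-size, rep_of, method = "radix")
  rank_of <- integer(length(ord))
  rank_of[ord] <- seq_along(ord)
  groups <- data.frame(variant_id = seq_along(ord),
                       representative = rep_of[ord],
                       n_reads = as.integer(size[ord]),
                       stringsAsFactors = FALSE)
  structure(groups, assignment = rank_of[cl][match(reads, uq)])
}

#' Call a positional majority consensus
#'
#' Per-position majority base over the group's reads; positions beyond a
#' read's length are ignored, ties go to the lexicographically smallest
#' base, and the consensus length is the modal read length (smallest on
#' ties). No multiple alignment is attempted: the error model is
#' substitution-only, so reads of one variant are positionally
#' comparable.
#'
#' @param reads non-empty character vector of read sequences.
#' @return the consensus sequence.
#' @export
call_consensus <- function(reads) {
  if (!length(reads)) stop_invalid("cannot call a consensus of zero reads")
  if (length(reads) == 1L) return(reads)
  lens <- nchar(reads)
  lt <- table(lens)
  L <- min(as.integer(names(lt)[lt == max(lt)]))
  maxL <- max(lens)
  ch <- strsplit(reads, "", fixed = TRUE)
  M <- vapply(ch, function(x) c(x, rep(NA_character_, maxL - length(x))),
              character(maxL))
  M <- matrix(M, nrow = maxL)[seq_len(L), , drop = FALSE]
  cnt <- vapply(DNA_BASES, function(b) rowSums(M == b, na.rm = TRUE),
                numeric(L))
  cnt <- matrix(cnt, nrow = L)
  pick <- max.col(cnt, ties.method = "first")  # columns ordered A,C,G,T
  paste(DNA_BASES[pick], collapse = "")
}

#' Classify a cluster's amplification clonality
#'
#' A barcode cluster shows monoclonal amplification when, for every
#' target present, the largest variant group holds at least
#' `dominant_threshold` (default 90%) of that target's reads; otherwise
#' it is polyclonal (reads from more than one founding molecule).
#'
#' @param target_groups named list, per target id a numeric vector of
#'   variant-group read counts (or the data.frame from
#'   [subcluster_reads()]).
#' @param dominant_threshold minimum dominant-variant read share.
#' @return `"monoclonal"` or `"polyclonal"`.
#' @export
classify_amplification_clonality <- function(target_groups,
                                             dominant_threshold = 0.90) {
  ok <- vapply(target_groups, function(g) {
    if (is.data.frame(g)) g <- g$n_reads
    max(g) >= dominant_threshold * sum(g)
  }, logical(1))
  if (all(ok)) "monoclonal" else "polyclonal"
}
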