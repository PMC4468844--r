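# Independent oracles used across tests.

# Naive transcription of the iterative abundance-seeded grouping
# procedure, written with plain loops and all-pairs distances so it
# shares no code with cluster_barcodes(). Returns a list of clusters,
# each with the seed (most abundant member, ties lexicographic), the
# sorted member set and the total read count.
oracle_cluster_barcodes <- function(counts, max_mismatch) {
  bc <- names(counts)
  ham <- function(a, b) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    sum(x != y)
  }
  items <- lapply(seq_along(bc), function(i)
    list(rep = bc[i], count = as.numeric(counts[i]), members = bc[i]))
  repeat {
    n0 <- length(items)
    reps <- vapply(items, function(x) x$rep, "")
    cnts <- vapply(items, function(x) x$count, 0)
    items <- items[order(-cnts, reps)]
    assigned <- rep(NA_integer_, length(items))
    for (i in seq_along(items)) {
      if (!is.na(assigned[i])) next
      assigned[i] <- i
      if (i < length(items)) {
        for (j in (i + 1L):length(items)) {
          if (is.na(assigned[j]) &&
              ham(items[[i]]$rep, items[[j]]$rep) <= max_mismatch)
            assigned[j] <- i
        }
      }
    }
    items <- lapply(unique(assigned), function(s) {
      mem <- items[assigned == s]
      list(rep = items[[s]]$rep,
           count = sum(vapply(mem, function(x) x$count, 0)),
           members = unlist(lapply(mem, function(x) x$members)))
    })
    if (length(items) == n0) break
  }
  lapply(items, function(it) {
    mc <- as.numeric(counts[it$members])
    o <- order(-mc, it$members)
    list(seed = it$members[o[1]], members = sort(it$members),
         n_reads = sum(mc))
  })
}

# canonical form of a clustering for comparison: member sets keyed by
# seed, plus totals
canonical_clustering <- function(seeds, member_sets, totals) {
  o <- order(seeds)
  list(seeds = seeds[o],
       members = lapply(member_sets[o], sort),
       totals = round(totals[o], 9))
}

canonical_from_barcode_clusters <- function(cl) {
  mem <- split(cl$members$barcode, cl$members$cluster_id)
  mem <- mem[cl$clusters$cluster_id]
  canonical_clustering(cl$clusters$seed_barcode, unname(mem),
                       cl$clusters$n_reads)
}

canonical_from_oracle <- function(oc) {
  canonical_clustering(vapply(oc, function(x) x$seed, ""),
                       lapply(oc, function(x) x$members),
                       vapply(oc, function(x) x$n_reads, 0))
}

random_barcode_instance <- function(n_distinct, len = 6, max_count = 50) {
  bc <- unique(replicate(n_distinct * 2, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  bc <- bc[seq_len(min(n_distinct, length(bc)))]
  stats::setNames(sample.int(max_count, length(bc), replace = TRUE), bc)
}
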