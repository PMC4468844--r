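#' Hamming distance between equal-length sequences
#'
#' Mismatch counting throughout the package is Hamming-style: barcodes
#' are fixed length and tolerances are stated as numbers of mismatching
#' positions, not edits.
#'
#' @param a,b character sequences of equal length (vectorised;
#'   recycled pairwise).
#' @return integer vector of mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop_invalid("sequences must have equal length for Hamming distance")
  vapply(seq_len(n), function(i) .hamming_pair(a[i], b[i]), 0L)
}

#' Read-1 layout for barcode extraction
#'
#' Describes where the bead barcode sits on read 1: an optional fixed
#' `offset` (e.g. a well tag), the 5' handle, `barcode_length` degenerate
#' bases, then the 3' handle. At most `handle_max_mismatch` mismatches
#' are tolerated across both handles combined (default 4).
#'
#' @param handle_5p,handle_3p fixed handle sequences.
#' @param barcode_length barcode length in nt.
#' @param offset bases preceding the 5' handle on read 1.
#' @param handle_max_mismatch combined handle mismatch tolerance.
#' @return a `read_layout` list.
#' @export
read_layout <- function(handle_5p, handle_3p, barcode_length = 15,
                        offset = 0, handle_max_mismatch = 4) {
  structure(list(handle_5p = handle_5p, handle_3p = handle_3p,
                 barcode_length = as.integer(barcode_length),
                 offset = as.integer(offset),
                 handle_max_mismatch = as.integer(handle_max_mismatch)),
            class = "read_layout")
}

# mismatches of a constant string against a same-length substring of
# each read, vectorised
.mm_to_constant <- function(seqs, const, start) {
  sub <- substr(seqs, start, start + nchar(const) - 1L)
  M <- .char_matrix(sub)
  as.integer(colSums(M != strsplit(const, "", fixed = TRUE)[[1L]]))
}

#' Extract bead barcodes from read-1 sequences
#'
#' Locates the two handles at their fixed offsets and, when their
#' combined mismatch count is within the layout tolerance, returns the
#' intervening barcode. Reads failing the check are rejected with a
#' reason code (`"too_short"` or `"handle_mismatch"`) and excluded from
#' all downstream counts.
#'
#' @param seqs character vector of read-1 sequences.
#' @param layout a [read_layout()].
#' @return data.frame with one row per read: `barcode` (NA if rejected),
#'   `handle_mismatches`, `status` ("ok"/"rejected"), `reason`.
#' @export
extract_barcodes <- function(seqs, layout) {
  stopifnot(inherits(layout, "read_layout"))
  n <- length(seqs)
  need <- layout$offset + nchar(layout$handle_5p) + layout$barcode_length +
    nchar(layout$handle_3p)
  out <- data.frame(barcode = rep(NA_character_, n),
                    handle_mismatches = rep(NA_integer_, n),
                    status = rep("rejected", n),
                    reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  long <- nchar(seqs) >= need
  out$reason[!long] <- "too_short"
  if (any(long)) {
    s <- seqs[long]
    h5_start <- layout$offset + 1L
    bc_start <- h5_start + nchar(layout$handle_5p)
    h3_start <- bc_start + layout$barcode_length
    mm <- .mm_to_constant(s, layout$handle_5p, h5_start) +
      .mm_to_constant(s, layout$handle_3p, h3_start)
    ok <- mm <= layout$handle_max_mismatch
    out$handle_mismatches[long] <- mm
    idx <- which(long)
    out$barcode[idx[ok]] <- substr(s[ok], bc_start, h3_start - 1L)
    out$status[idx[ok]] <- "ok"
    out$reason[idx[!ok]] <- "handle_mismatch"
  }
  out
}

#' Demultiplex reads to wells by tag prefix
#'
#' Each read is assigned to the unique well whose tag lies within
#' `max_mismatch` of the read's tag prefix (default 2, as used for
#' predefined well barcodes); otherwise it is left unassigned. The tag
#' set must be unambiguous: equal lengths and pairwise Hamming distance
#' greater than `2 * max_mismatch`.
#'
#' @param seqs character vector of read-1 sequences (tag at position 1).
#' @param well_tags character vector of well tag sequences.
#' @param max_mismatch per-tag mismatch tolerance.
#' @return integer vector of well indices into `well_tags`, NA when
#'   unassigned.
#' @export
demultiplex_wells <- function(seqs, well_tags, max_mismatch = 2) {
  if (length(unique(nchar(well_tags))) != 1L)
    stop_invalid("well tags must have equal length")
  L <- nchar(well_tags[1L])
  if (length(well_tags) > 1L) {
    for (i in seq_len(length(well_tags) - 1L))
      for (j in (i + 1L):length(well_tags))
        if (.hamming_pair(well_tags[i], well_tags[j]) <= 2L * max_mismatch)
          stop_invalid("ambiguous well tag set: pairwise distance must exceed 2*max_mismatch")
  }
  assign <- rep(NA_integer_, length(seqs))
  long <- nchar(seqs) >= L
  if (!any(long)) return(assign)
  D <- vapply(well_tags, function(tg) .mm_to_constant(seqs[long], tg, 1L),
              integer(sum(long)))
  D <- matrix(D, nrow = sum(long))
  best <- max.col(-D, ties.method = "first")
  hit <- D[cbind(seq_len(nrow(D)), best)] <= max_mismatch
  assign[which(long)[hit]] <- best[hit]
  assign
}

# One greedy sweep: rank items by descending count (ties: lexicographic),
# make each unassigned item a seed and absorb every later unassigned item
# within the threshold. thr_fun(len_seed, len_cands) gives the per-pair
# mismatch ceiling; comparisons are truncated to the shorter sequence.
.greedy_pass <- function(seqs, counts, thr_fun) {
  n <- length(seqs)
  ord <- order(-counts, seqs, method = "radix")
  s <- seqs[ord]
  lens <- nchar(s)
  same_len <- length(unique(lens)) == 1L
  M <- if (same_len) .char_matrix(s) else NULL
  seed_of <- integer(n)
  for (i in seq_len(n)) {
    if (seed_of[i] != 0L) next
    seed_of[i] <- i
    cand <- which(seed_of == 0L)
    if (!length(cand)) next
    if (same_len) {
      d <- .hamming_to_matrix(M[, i], M, cand)
    } else {
      m <- pmin(lens[cand], lens[i])
      d <- vapply(seq_along(cand), function(j)
        .hamming_pair(substr(s[cand[j]], 1L, m[j]), substr(s[i], 1L, m[j])),
        0L)
    }
    thr <- thr_fun(lens[i], lens[cand])
    seed_of[cand[d <= thr]] <- i
  }
  out <- integer(n)
  out[ord] <- ord[seed_of]
  out
}

# Iterate greedy passes on seeds-with-aggregated-counts until the number
# of clusters stops changing. Returns the cluster index of each input.
.iterative_cluster <- function(seqs, counts, thr_fun) {
  groups <- as.list(seq_along(seqs))
  reps <- seqs
  agg <- counts
  repeat {
    n0 <- length(reps)
    a <- .greedy_pass(reps, agg, thr_fun)
    seeds <- unique(a)
    groups <- lapply(seeds, function(si) unlist(groups[a == si], use.names = FALSE))
    agg <- vapply(seeds, function(si) sum(agg[a == si]), 0)
    reps <- reps[seeds]
    if (length(reps) == n0) break
  }
  cl <- integer(length(seqs))
  for (g in seq_along(groups)) cl[groups[[g]]] <- g
  cl
}

#' Cluster barcode sequences with mismatch tolerance
#'
#' The iterative abundance-seeded grouping that defines barcode
#' clusters: distinct barcodes are ranked by read count (ties broken
#' lexicographically), each barcode in turn seeds a cluster and absorbs
#' every lower-ranked unassigned barcode within `max_mismatch` of it;
#' cluster counts are then aggregated onto the seeds and the procedure
#' repeats on the seeds until the number of clusters no longer changes.
#' The default tolerance is 2 mismatches. Each cluster stands for one
#' amplicon-carrying bead.
#'
#' @param counts either a named numeric vector (names = barcodes, values
#'   = read counts) or a character vector of per-read barcodes, which is
#'   tabulated.
#' @param max_mismatch Hamming mismatch tolerance for grouping.
#' @return an object of class `barcode_clusters`: list with `clusters`
#'   (data.frame `cluster_id`, `seed_barcode`, `n_barcodes`, `n_reads`)
#'   and `members` (data.frame `barcode`, `count`, `cluster_id`).
#' @export
cluster_barcodes <- function(counts, max_mismatch = 2) {
  if (is.character(counts)) {
    tab <- table(counts)
    counts <- stats::setNames(as.numeric(tab), names(tab))
  }
  bc <- names(counts)
  cnt <- as.numeric(counts)
  if (length(bc) && length(unique(nchar(bc))) != 1L)
    stop_invalid("barcodes must all have the same length")
  if (!length(bc)) {
    return(structure(list(
      clusters = data.frame(cluster_id = character(0),
                            seed_barcode = character(0),
                            n_barcodes = integer(0), n_reads = numeric(0)),
      members = data.frame(barcode = character(0), count = numeric(0),
                           cluster_id = character(0)),
      max_mismatch = max_mismatch), class = "barcode_clusters"))
  }
  cl <- .iterative_cluster(bc, cnt, function(li, lc) max_mismatch)
  # seed = most abundant member, ties to the lexicographically smaller
  seed <- vapply(split(seq_along(bc), cl), function(i) {
    i <- i[order(-cnt[i], bc[i], method = "radix")]
    bc[i[1L]]
  }, character(1))
  tot <- vapply(split(cnt, cl), sum, 0)
  nbar <- tabulate(cl)
  ord <- order(-tot, seed, method = "radix")
  cluster_id <- sprintf("bc%05d", seq_along(ord))
  id_of <- character(length(ord))
  id_of[ord] <- cluster_id
  structure(list(
    clusters = data.frame(cluster_id = cluster_id,
                          seed_barcode = seed[ord],
                          n_barcodes = nbar[ord],
                          n_reads = tot[ord], stringsAsFactors = FALSE),
    members = data.frame(barcode = bc, count = cnt,
                         cluster_id = id_of[cl], stringsAsFactors = FALSE),
    max_mismatch = max_mismatch), class = "barcode_clusters")
}

#' @export
print.barcode_clusters <- function(x, ...) {
  cat(sprintf("%d barcode clusters from %d distinct barcodes (%s reads), max_mismatch = %d\n",
              nrow(x$clusters), nrow(x$members),
              format(sum(x$clusters$n_reads), big.mark = ","), x$max_mismatch))
  invisible(x)
}

#' Classify the clonality of one well's barcode content
#'
#' Automated surrogate for the manual evaluation of a sorted well's
#' barcode distribution: clusters holding at least `min_fraction` of the
#' well's reads are counted; zero such clusters is `"empty"`, one
#' `"monoclonal"`, two or more `"polyclonal"`.
#'
#' @param cluster_reads numeric vector of per-cluster read counts in the
#'   well, or a `barcode_clusters` object.
#' @param min_fraction minimum read share for a cluster to count.
#' @return one of `"empty"`, `"monoclonal"`, `"polyclonal"`.
#' @export
classify_well_clonality <- function(cluster_reads, min_fraction = 0.10) {
  if (inherits(cluster_reads, "barcode_clusters"))
    cluster_reads <- cluster_reads$clusters$n_reads
  tot <- sum(cluster_reads)
  if (tot == 0) return("empty")
  k <- sum(cluster_reads >= min_fraction * tot)
  if (k == 0L) "empty" else if (k == 1L) "monoclonal" else "polyclonal"
}
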