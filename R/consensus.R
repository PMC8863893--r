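# Stages 2-4: merge read pairs into amplicons, cluster 16S sequences within
# each barcode, call a quality-weighted representative sequence (RepSeq) per
# group, and filter errors down to Bar sequences.

.phred_int <- function(q) as.integer(charToRaw(q)) - 33L

# Core ungapped overlap merge of one (i1, revcomp(r2)) pair. Sequences are
# handled as integer byte vectors. Returns NULL when no acceptable overlap
# exists.
.merge_core <- function(a_raw, qa, b_raw, qb, min_overlap, max_mismatch_frac) {
  a <- as.integer(a_raw); b <- as.integer(b_raw)
  la <- length(a); lb <- length(b)
  omax <- min(la, lb)
  if (omax < min_overlap) return(NULL)

  score_at <- function(o) sum(a[(la - o + 1L):la] == b[1:o])

  best_o <- 0L; best_score <- -1L
  # Fast path: locate the terminal 20-mer of the forward read inside the
  # reverse-complemented mate to propose candidate overlaps; exact for
  # error-free read ends, which dominate.
  seed_len <- 20L
  if (la >= seed_len) {
    seed <- rawToChar(a_raw[(la - seed_len + 1L):la])
    bs <- rawToChar(b_raw)
    hits <- gregexpr(seed, bs, fixed = TRUE)[[1L]]
    if (hits[1L] != -1L) {
      for (p in hits) {
        o <- p + seed_len - 1L
        if (o < min_overlap || o > omax) next
        sc <- score_at(o)
        if (sc > best_score || (sc == best_score && o > best_o)) {
          best_score <- sc; best_o <- o
        }
      }
    }
  }
  ok <- best_o > 0L && (best_o - best_score) / best_o <= max_mismatch_frac
  if (!ok) {
    # Exhaustive scan over all admissible overlaps.
    best_o <- 0L; best_score <- -1L
    for (o in min_overlap:omax) {
      sc <- score_at(o)
      if (sc > best_score || (sc == best_score && o > best_o)) {
        best_score <- sc; best_o <- o
      }
    }
    if ((best_o - best_score) / best_o > max_mismatch_frac) return(NULL)
  }

  o <- best_o
  ia <- (la - o + 1L):la
  ov_a <- a[ia]; ov_b <- b[1:o]
  ov_qa <- qa[ia]; ov_qb <- qb[1:o]
  agree <- ov_a == ov_b
  take_a <- agree | (ov_qa >= ov_qb) # ties resolved toward the forward read
  ov_seq <- ifelse(take_a, ov_a, ov_b)
  ov_q <- ifelse(agree, pmax(ov_qa, ov_qb), ifelse(take_a, ov_qa, ov_qb))
  list(seq = rawToChar(as.raw(c(a[seq_len(la - o)], ov_seq,
                                b[seq_len(lb - o) + o]))),
       qual = c(qa[seq_len(la - o)], ov_q, qb[seq_len(lb - o) + o]),
       overlap = o,
       mismatches = o - best_score)
}

#' Merge one read pair into an amplicon
#'
#' The reverse read is reverse-complemented, then the best ungapped overlap
#' of at least `min_overlap` bases is chosen by maximal matching bases
#' (ties toward the longer overlap). Within the overlap each disagreeing
#' base is taken from the higher-quality read; agreeing bases keep the
#' maximum of the two qualities. Pairs whose best overlap exceeds
#' `max_overlap_mismatch_frac` mismatches are rejected (NULL).
#'
#' @param i1,qi1 Forward 16S read and its Phred+33 quality string.
#' @param r2,q2 Reverse 16S read (as sequenced) and quality string.
#' @param min_overlap Minimum acceptable overlap, bases. Default 30.
#' @param max_overlap_mismatch_frac Maximum mismatch fraction inside the
#'   overlap. Default 0.1.
#' @return List with `sequence`, `quality` (Phred+33 string), `overlap`,
#'   `mismatches`; or NULL on rejection.
#' @export
merge_pair <- function(i1, qi1, r2, q2, min_overlap = 30L,
                       max_overlap_mismatch_frac = 0.1) {
  b <- .revcomp(r2)
  qb <- rev(.phred_int(q2))
  res <- .merge_core(charToRaw(i1), .phred_int(qi1), charToRaw(b), qb,
                     as.integer(min_overlap), max_overlap_mismatch_frac)
  if (is.null(res)) return(NULL)
  list(sequence = res$seq, quality = .phred_char(res$qual),
       overlap = res$overlap, mismatches = res$mismatches)
}

#' Merge all read pairs of a run
#'
#' Vectorized driver for [merge_pair()] that deduplicates identical
#' (read, quality) pairs before merging, preserving per-read rows in the
#' output.
#'
#' @param triplets Read triplets from [parse_run()] or [simulate_reads()].
#' @inheritParams merge_pair
#' @return data.frame with one row per input read: `read_id`, `merged`
#'   (logical), `sequence`, `quality`, `overlap`.
#' @export
merge_pairs <- function(triplets, min_overlap = 30L,
                        max_overlap_mismatch_frac = 0.1) {
  n <- nrow(triplets)
  if (!n) {
    return(data.frame(read_id = character(0), merged = logical(0),
                      sequence = character(0), quality = character(0),
                      overlap = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(triplets$i1, triplets$qi1, triplets$r2, triplets$q2, sep = "\r")
  uk <- !duplicated(key)
  uidx <- which(uk)
  res <- vector("list", length(uidx))
  for (j in seq_along(uidx)) {
    i <- uidx[j]
    res[[j]] <- merge_pair(triplets$i1[i], triplets$qi1[i],
                           triplets$r2[i], triplets$q2[i],
                           min_overlap, max_overlap_mismatch_frac)
  }
  map <- match(key, key[uidx])
  merged_ok <- !vapply(res, is.null, logical(1))
  seqs <- ifelse(merged_ok, vapply(res, function(x) if (is.null(x)) "" else x$sequence, character(1)), "")
  quals <- ifelse(merged_ok, vapply(res, function(x) if (is.null(x)) "" else x$quality, character(1)), "")
  ovl <- ifelse(merged_ok, vapply(res, function(x) if (is.null(x)) NA_integer_ else x$overlap, integer(1)), NA_integer_)
  data.frame(read_id = triplets$read_id,
             merged = merged_ok[map],
             sequence = seqs[map],
             quality = quals[map],
             overlap = ovl[map],
             stringsAsFactors = FALSE)
}

#' Cluster amplicons of one barcode by sequence identity
#'
#' Greedy abundance-ordered clustering (count descending, lexicographic
#' ties) by Levenshtein distance, as for barcodes. The default distance 0
#' groups exact sequence types: single-base 16S variants of a multi-copy
#' genome then stay separate within every droplet and are reunited later by
#' the co-occurrence test, while sequencing-error reads form low-support
#' groups removed by [filter_errors()].
#'
#' @param sequences Character vector of merged amplicons of one barcode
#'   cluster.
#' @param max_intra_distance Levenshtein threshold for joining. Default 0.
#' @return Integer vector of group indices (1-based, densely numbered in
#'   founding order) parallel to `sequences`.
#' @export
cluster_within_barcode <- function(sequences, max_intra_distance = 0L) {
  if (!length(sequences)) return(integer(0))
  res <- cluster_barcodes_generic(sequences, max_intra_distance)
  res
}

# Shared greedy clusterer over arbitrary-length sequences; returns group
# index per input element.
cluster_barcodes_generic <- function(sequences, max_dist) {
  tab <- table(sequences)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- .abundance_order(counts)
  seqs <- names(counts)[ord]
  reps <- character(0)
  assign_idx <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    j <- integer(0)
    if (length(reps)) {
      if (max_dist == 0L) {
        hit <- match(seqs[i], reps)
        if (!is.na(hit)) j <- hit
      } else {
        d <- utils::adist(seqs[i], reps)[1L, ]
        j <- which(d <= max_dist)
      }
    }
    if (length(j)) {
      assign_idx[i] <- j[1L]
    } else {
      reps <- c(reps, seqs[i])
      assign_idx[i] <- length(reps)
    }
  }
  assign_idx[match(sequences, seqs)]
}

#' Call the representative sequence (RepSeq) of an amplicon group
#'
#' Per-position weighted vote over the group: each read contributes weight
#' 1 - 10^(-Q/10) for its base at that position. Groups of heterogeneous
#' length use the modal length as the consensus frame; off-length members
#' vote only on the positions they cover. Ties go to the base of the
#' most-supported full sequence (lexicographic on further ties).
#'
#' @param sequences Character vector of amplicons in one group.
#' @param qualities Parallel Phred+33 quality strings.
#' @return List with `sequence`, `read_support`, `mean_quality`.
#' @export
call_repseq <- function(sequences, qualities) {
  n <- length(sequences)
  stopifnot(n >= 1L, length(qualities) == n)
  mq <- mean(unlist(lapply(qualities, .phred_int)))
  if (length(unique(sequences)) == 1L) {
    return(list(sequence = sequences[1L], read_support = n, mean_quality = mq))
  }
  lens <- nchar(sequences)
  lt <- table(lens)
  modal_len <- max(as.integer(names(lt)[lt == max(lt)]))
  # Most-supported full sequence at the modal length (count desc, lex asc)
  # used to break per-position ties.
  st <- table(sequences[lens == modal_len])
  anchor <- names(st)[.abundance_order(stats::setNames(as.integer(st), names(st)))][1L]
  anchor_raw <- charToRaw(anchor)

  weights <- matrix(0, nrow = 4L, ncol = modal_len,
                    dimnames = list(.BASES, NULL))
  base_raw <- vapply(.BASES, function(b) charToRaw(b), raw(1))
  for (i in seq_len(n)) {
    L <- min(lens[i], modal_len)
    s <- charToRaw(sequences[i])[seq_len(L)]
    w <- 1 - 10^(-.phred_int(qualities[i])[seq_len(L)] / 10)
    for (k in seq_along(.BASES)) {
      sel <- s == base_raw[k]
      if (any(sel)) {
        idx <- which(sel)
        weights[k, idx] <- weights[k, idx] + w[idx]
      }
    }
  }
  cons <- character(modal_len)
  for (p in seq_len(modal_len)) {
    wp <- weights[, p]
    top <- which(wp == max(wp))
    if (length(top) > 1L) {
      ab <- match(rawToChar(anchor_raw[p]), .BASES)
      cons[p] <- if (!is.na(ab) && ab %in% top) .BASES[ab] else .BASES[top[1L]]
    } else {
      cons[p] <- .BASES[top]
    }
  }
  list(sequence = paste(cons, collapse = ""), read_support = n,
       mean_quality = mq)
}

#' Remove error-derived RepSeqs and identify Bar sequences
#'
#' Within each barcode cluster, a RepSeq is discarded when its read support
#' is below `min_reads_per_repseq` or below `min_minor_fraction` of the
#' dominant RepSeq's support in that barcode (sequencing-error sequence
#' types are rare and low-support). A surviving sequence must then be seen
#' in at least `min_cell_support` barcode clusters to become a Bar
#' sequence. Bar ids are assigned by descending barcode support, then
#' lexicographic sequence.
#'
#' @param repseqs data.frame with `barcode_cluster_id`, `sequence`,
#'   `read_support` (one row per RepSeq).
#' @param min_reads_per_repseq Minimum reads behind a RepSeq. Default 3.
#' @param min_cell_support Minimum distinct barcode clusters behind a Bar
#'   sequence. Default 2.
#' @param min_minor_fraction Minimum support relative to the dominant
#'   RepSeq of the same barcode. Default 0.1.
#' @return List with `bar_sequences` (data.frame `bar_id`, `sequence`,
#'   `n_barcodes`) and `assignment` (data.frame `barcode_cluster_id`,
#'   `bar_id`, `read_support`).
#' @export
filter_errors <- function(repseqs, min_reads_per_repseq = 3L,
                          min_cell_support = 2L, min_minor_fraction = 0.1) {
  empty <- list(
    bar_sequences = data.frame(bar_id = character(0), sequence = character(0),
                               n_barcodes = integer(0), stringsAsFactors = FALSE),
    assignment = data.frame(barcode_cluster_id = character(0),
                            bar_id = character(0), read_support = integer(0),
                            stringsAsFactors = FALSE))
  if (!nrow(repseqs)) {
    warning("no RepSeqs supplied; empty outputs")
    return(empty)
  }
  dominant <- stats::ave(repseqs$read_support, repseqs$barcode_cluster_id,
                         FUN = max)
  keep <- repseqs$read_support >= min_reads_per_repseq &
    repseqs$read_support >= min_minor_fraction * dominant
  surv <- repseqs[keep, , drop = FALSE]
  if (!nrow(surv)) {
    warning("no RepSeqs survive the per-barcode filters; empty outputs")
    return(empty)
  }
  support <- tapply(surv$barcode_cluster_id, surv$sequence,
                    function(x) length(unique(x)))
  ok_seq <- names(support)[support >= min_cell_support]
  surv <- surv[surv$sequence %in% ok_seq, , drop = FALSE]
  if (!nrow(surv)) {
    warning("no sequences reach the barcode-support threshold; empty outputs")
    return(empty)
  }
  nb <- stats::setNames(as.integer(support[ok_seq]), ok_seq)
  ord <- .abundance_order(nb)
  bar <- data.frame(bar_id = sprintf("Bar%04d", seq_along(ok_seq)),
                    sequence = names(nb)[ord],
                    n_barcodes = as.integer(nb[ord]),
                    stringsAsFactors = FALSE)
  # distinct groups of one barcode may converge on the same consensus
  # sequence; collapse them, summing read support
  agg <- stats::aggregate(read_support ~ barcode_cluster_id + sequence,
                          data = surv, FUN = sum)
  assignment <- data.frame(
    barcode_cluster_id = agg$barcode_cluster_id,
    bar_id = bar$bar_id[match(agg$sequence, bar$sequence)],
    read_support = agg$read_support,
    stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$barcode_cluster_id,
                                 assignment$bar_id), , drop = FALSE]
  rownames(assignment) <- NULL
  list(bar_sequences = bar, assignment = assignment)
}
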