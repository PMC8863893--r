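# Stage 1: parse raw runs, validate cellular barcodes, reconstruct droplets
# by clustering barcode reads.

#' Parse a run of three synchronized FASTQ files
#'
#' R1 holds the 30 nt barcode read, I1 the 16S forward read and R2 the 16S
#' reverse read of each molecule, matched by record order. Gzip-compressed
#' files are accepted. Record-count or id mismatches across the files are
#' errors naming the first divergent record.
#'
#' @param r1_path,i1_path,r2_path FASTQ paths.
#' @return data.frame of read triplets (`read_id`, `r1`, `q1`, `i1`, `qi1`,
#'   `r2`, `q2`).
#' @export
parse_run <- function(r1_path, i1_path, r2_path) {
  read_fq <- function(p) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
    Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
  }
  r1 <- read_fq(r1_path)
  i1 <- read_fq(i1_path)
  r2 <- read_fq(r2_path)
  ns <- c(length(r1), length(i1), length(r2))
  if (length(unique(ns)) != 1L) {
    stop(sprintf(paste0("FASTQ files are not synchronized: %d (R1), %d (I1), ",
                        "%d (R2) records; first divergence at record %d"),
                 ns[1], ns[2], ns[3], min(ns) + 1L))
  }
  first_token <- function(x) sub("[ \t].*$", "", x)
  id1 <- first_token(names(r1)); id2 <- first_token(names(i1))
  id3 <- first_token(names(r2))
  bad <- which(id1 != id2 | id1 != id3)
  if (length(bad)) {
    stop(sprintf("read id mismatch across FASTQ files at record %d ('%s'/'%s'/'%s')",
                 bad[1], id1[bad[1]], id2[bad[1]], id3[bad[1]]))
  }
  data.frame(read_id = id1,
             r1 = as.character(r1), q1 = as.character(S4Vectors::mcols(r1)$qualities),
             i1 = as.character(i1), qi1 = as.character(S4Vectors::mcols(i1)$qualities),
             r2 = as.character(r2), q2 = as.character(S4Vectors::mcols(r2)$qualities),
             stringsAsFactors = FALSE)
}

.hamming <- function(a, b) {
  # equal-length character vectors, vectorized over a
  if (!length(a)) return(integer(0))
  mapply(function(x, y) {
    sum(charToRaw(x) != charToRaw(y))
  }, a, MoreArgs = list(y = b), USE.NAMES = FALSE)
}

#' Extract and validate cellular barcodes from R1 reads
#'
#' A 30 nt barcode read is 24 random bases followed by a 6-base fixed tag.
#' A read is accepted when its tag matches one of the four designed tags
#' within `max_tag_mismatch` substitutions; reads with ambiguous bases (N)
#' in the random portion are rejected when `reject_ambiguous` is TRUE.
#'
#' @param r1 Character vector of 30 nt barcode reads.
#' @param max_tag_mismatch Maximum tag substitutions tolerated. Default 1.
#' @param reject_ambiguous Reject reads with N in the random portion.
#' @return data.frame with `random` (24 nt portion), `tag_id` (1-4 or NA),
#'   `accepted`, `reason`.
#' @export
extract_barcodes <- function(r1, max_tag_mismatch = 1L, reject_ambiguous = TRUE) {
  if (!length(r1)) {
    return(data.frame(random = character(0), tag_id = integer(0),
                      accepted = logical(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(nchar(r1) != 30L)) stop("barcode reads must be exactly 30 nt")
  random <- substr(r1, 1L, 24L)
  tag <- substr(r1, 25L, 30L)
  mm <- sapply(.BARCODE_TAGS, function(t) .hamming(tag, t))
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1L)
  best <- max.col(-mm, ties.method = "first")
  best_mm <- mm[cbind(seq_along(tag), best)]
  tag_ok <- best_mm <= max_tag_mismatch
  n_ok <- !grepl("N", random, fixed = TRUE)
  accepted <- tag_ok & (!reject_ambiguous | n_ok)
  reason <- rep("", length(r1))
  reason[!tag_ok] <- "tag_mismatch"
  reason[tag_ok & !accepted] <- "ambiguous_base"
  data.frame(random = random,
             tag_id = ifelse(tag_ok, best, NA_integer_),
             accepted = accepted,
             reason = reason,
             stringsAsFactors = FALSE)
}

# Deterministic ordering used by every greedy clusterer: abundance
# descending, then lexicographic ascending.
.abundance_order <- function(counts) {
  order(-counts, names(counts), method = "radix")
}

#' Greedy abundance-ordered clustering of barcode sequences
#'
#' Unique sequences are visited in order of descending read count (ties
#' broken lexicographically); each joins the first existing cluster whose
#' representative lies within `max_edit_distance` (Levenshtein), otherwise
#' it founds a new cluster. The representative of a cluster is its founding
#' (most abundant) sequence, so the procedure is deterministic and
#' bit-reproducible.
#'
#' @param barcodes Character vector (multiset) of 24 nt barcode random
#'   portions, one entry per accepted read.
#' @param max_edit_distance Levenshtein threshold for joining. Default 2:
#'   random 24-mers essentially never collide within distance 2 while
#'   substitution errors rarely exceed it.
#' @return List with `clusters` (data.frame `cluster_id`, `representative`,
#'   `size`), `membership` (data.frame `sequence`, `cluster_id` over unique
#'   sequences) and `read_cluster` (cluster id per input read).
#' @export
cluster_barcodes <- function(barcodes, max_edit_distance = 2L) {
  stopifnot(max_edit_distance >= 0)
  if (!length(barcodes)) {
    return(list(clusters = data.frame(cluster_id = character(0),
                                      representative = character(0),
                                      size = integer(0), stringsAsFactors = FALSE),
                membership = data.frame(sequence = character(0),
                                        cluster_id = character(0),
                                        stringsAsFactors = FALSE),
                read_cluster = character(0)))
  }
  tab <- table(barcodes)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- .abundance_order(counts)
  seqs <- names(counts)[ord]
  counts <- counts[ord]

  reps <- character(0)
  assign_idx <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    if (length(reps)) {
      if (max_edit_distance == 0L) {
        hit <- match(seqs[i], reps)
        j <- if (is.na(hit)) integer(0) else hit
      } else {
        d <- utils::adist(seqs[i], reps)[1L, ]
        j <- which(d <= max_edit_distance)
      }
      if (length(j)) {
        assign_idx[i] <- j[1L]
        next
      }
    }
    reps <- c(reps, seqs[i])
    assign_idx[i] <- length(reps)
  }

  sizes <- as.integer(tapply(counts, assign_idx, sum))
  # Label clusters by size descending then representative ascending.
  lab_ord <- order(-sizes, reps, method = "radix")
  ids <- character(length(reps))
  ids[lab_ord] <- sprintf("BC%05d", seq_along(reps))
  clusters <- data.frame(cluster_id = ids,
                         representative = reps,
                         size = sizes,
                         stringsAsFactors = FALSE)
  clusters <- clusters[lab_ord, , drop = FALSE]
  rownames(clusters) <- NULL
  membership <- data.frame(sequence = seqs,
                           cluster_id = ids[assign_idx],
                           stringsAsFactors = FALSE)
  list(clusters = clusters,
       membership = membership,
       read_cluster = membership$cluster_id[match(barcodes, membership$sequence)])
}
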