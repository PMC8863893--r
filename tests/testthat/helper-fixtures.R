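# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no data files.

# Map recovered cOTU counts back to strain ids by variant sequence identity.
strain_counts_from_result <- function(result, community) {
  tv <- community_variants(community)
  strain_of <- tv$strain_id[match(result$cotus$sequence, tv$sequence)]
  cmap <- tapply(strain_of, result$cotus$cotu_id,
                 function(x) unique(stats::na.omit(x))[1])
  counts <- stats::setNames(as.numeric(result$counts$cell_count),
                            unname(cmap[result$counts$cotu_id]))
  counts[!is.na(names(counts))]
}

# A small encapsulation sharing the fixture's occupancy regime but with
# fewer droplets, for fast end-to-end tests.
small_encapsulation <- function(n_droplets = 5000) {
  mock_encapsulation(n_droplets = n_droplets,
                     n_barcodes = round(0.14 * n_droplets),
                     n_cells = round(0.21 * n_droplets))
}

# Hand-built read triplet around a template: exact reads, constant quality.
perfect_triplet <- function(template, barcode, read_len = 295L, q = 37L) {
  qc <- function(n) strrep(rawToChar(as.raw(q + 33L)), n)
  L <- nchar(template)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(template, L - read_len + 1L, L))))
  data.frame(read_id = "T1",
             r1 = barcode, q1 = qc(nchar(barcode)),
             i1 = substr(template, 1L, read_len), qi1 = qc(read_len),
             r2 = r2, q2 = qc(read_len),
             stringsAsFactors = FALSE)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
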