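# small, fast simulation config used across test files
test_config <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 1, chrom_length = 2e5, causal_pos = 1e5,
                   ems_rate = 1e-4, ems_spectrum = 0.99, error_rate = 0,
                   depth_mean = 21, bulk_size = 15, recomb_rate = 1,
                   genes_per_mb = 60, seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# one shared error-free dataset, built once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_mutmap(test_config())
    cache
  }
})

# toy gene + sequence with known codons, for annotation tests:
# plus strand, 2 exons (9 + 6 bp CDS), intron of 10 bp.
# CDS = ATG TCT GCT | GGA TAA  -> protein M S A G
toy_locus <- function() {
  exon1 <- "ATGTCTGCT"
  exon2 <- "GGATAA"
  intron <- "GTAAGCTTAG"   # starts GT, ends AG
  seq <- paste0("AAAA", exon1, intron, exon2, "TTTT")
  exons <- data.frame(start = c(5, 5 + 9 + 10), end = c(13, 5 + 9 + 10 + 5))
  g <- gene_model("toy", "chrT", "+", exons)
  list(sequences = c(chrT = seq), model = g)
}

# mirror a plus-strand locus: reverse-complement the chromosome and flip
# coordinates, giving the equivalent minus-strand gene
mirror_locus <- function(sequences, model, records) {
  L <- nchar(sequences[[model$chrom]])
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  seq2 <- sequences
  seq2[[model$chrom]] <- rc(sequences[[model$chrom]])
  flip <- function(iv) data.frame(start = L - iv$end + 1, end = L - iv$start + 1)
  m2 <- gene_model(model$gene_id, model$chrom,
                   if (model$strand == "+") "-" else "+",
                   flip(model$exons), flip(model$cds))
  r2 <- records
  r2$pos <- L - records$pos + 1
  r2$ref <- chartr("ACGT", "TGCA", records$ref)
  r2$alt <- chartr("ACGT", "TGCA", records$alt)
  list(sequences = seq2, model = m2, records = r2)
}

# independent O(n * windows) rescan used to verify the sweep implementation
brute_force_scan <- function(records, chrom_lengths, window, step) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    rows <- lapply(starts, function(s) {
      e <- min(s + window - 1, len)
      sub <- records[records$chrom == ch & records$pos >= s &
                       records$pos <= e, ]
      def <- sub$snp_index[!is.na(sub$snp_index)]
      data.frame(chrom = ch, start = s, end = e, n_variants = nrow(sub),
                 mean_index = if (length(def) > 0) mean(def) else NA_real_)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

random_scan_instance <- function(seed) {
  set.seed(seed)
  lens <- c(chrA = sample(20000:60000, 1), chrB = sample(10000:40000, 1))
  recs <- do.call(rbind, lapply(names(lens), function(ch) {
    n <- sample(30:150, 1)
    data.frame(chrom = ch, pos = sort(sample.int(lens[[ch]], n)),
               snp_index = ifelse(runif(n) < 0.05, NA_real_, runif(n)))
  }))
  step <- sample(c(500, 1000, 2500), 1)
  window <- step * sample(2:10, 1)
  list(records = recs, lens = lens, window = window, step = step)
}
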