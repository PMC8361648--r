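#' Simulation configuration for a synthetic EMS / F2-bulk experiment
#'
#' Bundles every parameter of the synthetic data generator: genome layout,
#' EMS mutation load and spectrum, the placement of the causal locus, the
#' F2 bulk design and the sequencing model. The defaults mirror a typical
#' MutMap experiment in a selfing crop: a bulk of 15 recessive-phenotype F2
#' individuals sequenced to about 21x, with 99% of EMS lesions being the
#' canonical G>A / C>T transitions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of every chromosome in bp.
#' @param ems_rate expected EMS mutations per bp (homozygous in the mutant
#'   line).
#' @param ems_spectrum fraction of mutations that are canonical G>A or C>T
#'   transitions, in `[0, 1]`.
#' @param causal_chrom chromosome index (1-based) carrying the causal locus.
#' @param causal_pos 1-based position of the causal SNP.
#' @param bulk_size number of mutant-phenotype F2 individuals pooled.
#' @param depth_mean expected read depth per site in the bulk (Poisson mean).
#' @param error_rate per-read miscall probability, in `[0, 1]`.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (chromosome map length in Morgans; Haldane model, no interference).
#' @param genes_per_mb target density of simulated gene models.
#' @param seed integer random seed; all stages derive their streams from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_mutmap()] for the one-call generator.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 2e6,
                       ems_rate = 2e-5,
                       ems_spectrum = 0.99,
                       causal_chrom = 1,
                       causal_pos = 1.3e6,
                       bulk_size = 15,
                       depth_mean = 21,
                       error_rate = 0.005,
                       recomb_rate = 1,
                       genes_per_mb = 40,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    ems_rate = as.numeric(ems_rate),
    ems_spectrum = as.numeric(ems_spectrum),
    causal_chrom = as.integer(causal_chrom),
    causal_pos = as.numeric(causal_pos),
    bulk_size = as.integer(bulk_size),
    depth_mean = as.numeric(depth_mean),
    error_rate = as.numeric(error_rate),
    recomb_rate = as.numeric(recomb_rate),
    genes_per_mb = as.numeric(genes_per_mb),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chromosomes >= 1,
    cfg$chrom_length >= 1,
    cfg$ems_rate >= 0, cfg$ems_rate <= 1,
    cfg$ems_spectrum >= 0, cfg$ems_spectrum <= 1,
    cfg$bulk_size >= 1,
    cfg$depth_mean >= 0,
    cfg$error_rate >= 0, cfg$error_rate <= 1,
    cfg$recomb_rate >= 0,
    cfg$genes_per_mb >= 0,
    is.finite(cfg$seed)
  )
  if (cfg$causal_chrom < 1 || cfg$causal_chrom > cfg$n_chromosomes)
    stop("causal_chrom outside the simulated genome")
  if (cfg$causal_pos < 1 || cfg$causal_pos > cfg$chrom_length)
    stop("causal_pos outside the chromosome bounds")
  if (cfg$seed > 2^31 - 10 || cfg$seed < 0)
    stop("seed must be a non-negative 32-bit integer")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("EMS / F2-bulk simulation config\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp\n",
              x$n_chromosomes, format(x$chrom_length, big.mark = ",")))
  cat(sprintf("  EMS: rate %.2g /bp, canonical transition fraction %.2f\n",
              x$ems_rate, x$ems_spectrum))
  cat(sprintf("  causal locus: chr%d:%s\n", x$causal_chrom,
              format(x$causal_pos, big.mark = ",")))
  cat(sprintf("  bulk: %d F2 individuals, depth ~Pois(%.1f), error %.3g\n",
              x$bulk_size, x$depth_mean, x$error_rate))
  cat(sprintf("  recombination: %.2g Morgan/chromosome (Haldane), seed %d\n",
              x$recomb_rate, x$seed))
  invisible(x)
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

# Layout of the gene forced to span the causal locus: three plus-strand
# exons (300 + 300 + 150 bp CDS, 200 bp introns) with the causal SNP at CDS
# offset 500, i.e. codon position 2 of residue 167. The reference codon is
# rewritten to TCT (Ser) so the forced C>T lesion yields the nonsynonymous
# S>F change, and the final codon to TAA so the CDS terminates.
causal_gene_layout <- function(causal_pos) {
  s <- causal_pos - 699
  list(
    start = s,
    exons = data.frame(
      start = c(s, s + 500, s + 1000),
      end = c(s + 299, s + 799, s + 1149)
    ),
    end = s + 1149,
    cds_offset = 500
  )
}

random_gene_structure <- function() {
  n_exons <- sample(2:5, 1)
  exon_len <- 3L * sample(40:150, n_exons, replace = TRUE)
  intron_len <- sample(80:300, max(n_exons - 1, 1), replace = TRUE)
  list(n_exons = n_exons, exon_len = exon_len,
       intron_len = intron_len[seq_len(n_exons - 1)])
}

#' Simulate a reference genome with gene models
#'
#' Generates uniform-random chromosome sequences and places non-overlapping
#' multi-exon gene models, always including one gene that spans the causal
#' locus with the causal site inside a coding exon at a known codon phase
#' (reference codon TCT, so a C>T change is nonsynonymous S>F). Output is
#' deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return a list with `sequences` (named character vector of chromosome
#'   sequences), `genes` (list of [gene_model()] objects), `chrom_lengths`
#'   (named vector) and `causal_gene` (the id of the gene spanning the
#'   causal locus).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sim_chrom_names(config)
  L <- config$chrom_length

  layout <- causal_gene_layout(config$causal_pos)
  if (layout$start < 1 || layout$end > L)
    stop(sprintf(paste0("cannot place causal gene: span %d..%d does not fit ",
                        "chromosome of length %d (need >= 699 bp upstream and ",
                        ">= 450 bp downstream of causal_pos)"),
                 as.integer(layout$start), as.integer(layout$end),
                 as.integer(L)))

  sequences <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))

  # rewrite the causal codon (TCT) and the terminal stop codon (TAA)
  cc <- chroms[config$causal_chrom]
  seq_cc <- sequences[[cc]]
  substr(seq_cc, config$causal_pos - 1, config$causal_pos + 1) <- "TCT"
  substr(seq_cc, layout$end - 2, layout$end) <- "TAA"
  sequences[[cc]] <- seq_cc

  genes <- list()
  occupied <- list()  # per chromosome: matrix of occupied (start, end)
  for (ch in chroms) occupied[[ch]] <- NULL

  causal_id <- "gene_chr0_0000"  # replaced below
  gi <- 0L
  add_gene <- function(ch, exons, strand) {
    gi <<- gi + 1L
    id <- sprintf("gene_%s_%04d", ch, gi)
    genes[[id]] <<- gene_model(id, ch, strand, exons)
    occupied[[ch]] <<- rbind(occupied[[ch]],
                             c(min(exons$start) - 50, max(exons$end) + 50))
    id
  }
  causal_id <- add_gene(cc, layout$exons, "+")

  n_target <- round(L / 1e6 * config$genes_per_mb)
  for (ch in chroms) {
    n_have <- if (ch == cc) 1L else 0L
    n_need <- max(0L, n_target - n_have)
    for (k in seq_len(n_need)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        st <- random_gene_structure()
        span <- sum(st$exon_len) + sum(st$intron_len)
        if (span >= L) next
        start <- sample.int(L - span, 1)
        ex_start <- start + c(0, cumsum(st$exon_len[-st$n_exons] +
                                          st$intron_len))
        exons <- data.frame(start = ex_start,
                            end = ex_start + st$exon_len - 1)
        occ <- occupied[[ch]]
        if (!is.null(occ) &&
            any(exons$start[1] <= occ[, 2] & exons$end[st$n_exons] >= occ[, 1]))
          next
        add_gene(ch, exons, sample(c("+", "-"), 1))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste0("gene placement failed on %s after 200 attempts: ",
                            "no non-overlapping interval available at density ",
                            "%.1f genes/Mb"), ch, config$genes_per_mb))
    }
  }
  # order genes by chromosome then start
  ord <- order(vapply(genes, function(g) g$chrom, character(1)),
               vapply(genes, function(g) g$start, numeric(1)))
  genes <- genes[ord]

  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)
  list(sequences = sequences, genes = genes,
       chrom_lengths = chrom_lengths, causal_gene = causal_id)
}

ems_canonical_alt <- function(ref) c(G = "A", C = "T")[ref]

#' Simulate homozygous EMS-induced mutations
#'
#' Draws the mutation count per chromosome as Binomial(length, `ems_rate`),
#' assigns a `ems_spectrum` fraction of them to canonical G>A / C>T
#' transitions (placed on G/C sites), and gives the remainder non-canonical
#' changes at random sites. The causal locus is always appended as a forced
#' canonical C>T transition inside the causal gene's coding exon. RNG draw
#' order (from seed + 1): per chromosome in order - total count, canonical
#' count, canonical site sample, other site sample, other alt alleles.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `causal`,
#'   sorted by (chrom, pos).
#' @export
simulate_ems_mutations <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), config$ems_rate >= 0)
  set.seed(config$seed + 1L)
  bases <- c("A", "C", "G", "T")
  out <- list()
  causal_chr <- sim_chrom_names(config)[config$causal_chrom]
  for (ch in sim_chrom_names(config)) {
    seq_ch <- genome$sequences[[ch]]
    L <- nchar(seq_ch)
    n <- stats::rbinom(1, L, config$ems_rate)
    n_canon <- stats::rbinom(1, n, config$ems_spectrum)
    n_other <- n - n_canon
    pos_c <- integer(0)
    if (n_canon > 0) {
      # oversample, keep G/C sites; top up until enough
      got <- integer(0)
      for (round in seq_len(100)) {
        cand <- sample.int(L, min(L, n_canon * 4L))
        cand <- setdiff(cand, got)
        b <- substring(seq_ch, cand, cand)
        got <- c(got, cand[b %in% c("G", "C")])
        if (length(got) >= n_canon) break
      }
      if (length(got) < n_canon)
        stop(sprintf("no G/C site available on %s for canonical mutations", ch))
      pos_c <- got[seq_len(n_canon)]
    }
    pos_o <- integer(0)
    if (n_other > 0) {
      got <- integer(0)
      for (round in seq_len(100)) {
        cand <- sample.int(L, n_other * 2L)
        cand <- setdiff(setdiff(cand, pos_c), got)
        got <- c(got, cand)
        if (length(got) >= n_other) break
      }
      pos_o <- got[seq_len(n_other)]
    }
    base_at <- function(p) if (length(p) == 0) character(0) else
      substring(seq_ch, p, p)
    ref_c <- base_at(pos_c)
    alt_c <- unname(ems_canonical_alt(ref_c))
    ref_o <- base_at(pos_o)
    alt_o <- vapply(ref_o, function(r) {
      excl <- c(r, if (r %in% c("G", "C")) unname(ems_canonical_alt(r)))
      sample(setdiff(bases, excl), 1)
    }, character(1), USE.NAMES = FALSE)
    pos_all <- c(pos_c, pos_o)
    df <- data.frame(chrom = rep(ch, length(pos_all)),
                     pos = pos_all,
                     ref = c(ref_c, ref_o),
                     alt = c(alt_c, alt_o),
                     causal = rep(FALSE, length(pos_all)),
                     stringsAsFactors = FALSE)
    if (ch == causal_chr) {
      df <- df[df$pos != config$causal_pos, , drop = FALSE]
      ref_causal <- substring(seq_ch, config$causal_pos, config$causal_pos)
      if (ref_causal != "C")
        stop("internal error: causal reference base is not C")
      df <- rbind(df, data.frame(chrom = ch, pos = config$causal_pos,
                                 ref = "C", alt = "T", causal = TRUE,
                                 stringsAsFactors = FALSE))
    }
    out[[ch]] <- df[order(df$pos), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one gamete from a selfed F1: per chromosome, Poisson(recomb_rate)
# crossovers at uniform positions, random starting haplotype; returns the
# mutant-haplotype indicator (0/1) at each queried Morgan position.
sim_gamete <- function(morgan_pos_by_chrom, recomb_rate) {
  lapply(morgan_pos_by_chrom, function(mp) {
    k <- stats::rpois(1, recomb_rate)
    xo <- if (k > 0) sort(stats::runif(k, 0, recomb_rate)) else numeric(0)
    start <- sample(0:1, 1)
    if (length(mp) == 0) return(integer(0))
    n_before <- findInterval(mp, xo)
    (start + n_before) %% 2L
  })
}

#' Simulate an F2 bulk of recessive-phenotype individuals
#'
#' Selfs a uniformly heterozygous F1 (mutant x wild-type cross) and keeps
#' simulating F2 individuals until `bulk_size` plants homozygous for the
#' causal mutation (the fully penetrant recessive phenotype) have been
#' collected. Meiosis follows the Haldane model: crossover counts are
#' Poisson(`recomb_rate`) per chromosome with uniform positions, so physical
#' distance maps linearly to Morgans.
#'
#' @param config a [sim_config()].
#' @param variants data.frame from [simulate_ems_mutations()]; must contain
#'   the causal locus (`causal == TRUE`).
#' @return an object of class `f2_bulk`: list with `genotypes` (integer
#'   matrix, variants x individuals, alt-allele dosage 0/1/2), `variants`,
#'   `phenotype` (all "mutant") and `n_simulated` (individuals drawn before
#'   the bulk was filled).
#' @export
simulate_f2_bulk <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  ci <- which(variants$causal)
  if (length(ci) != 1)
    stop("variants must contain exactly one causal locus")
  set.seed(config$seed + 2L)
  chroms <- sim_chrom_names(config)
  mp <- lapply(chroms, function(ch) {
    variants$pos[variants$chrom == ch] / config$chrom_length * config$recomb_rate
  })
  names(mp) <- chroms
  idx <- lapply(chroms, function(ch) which(variants$chrom == ch))
  names(idx) <- chroms

  n <- nrow(variants)
  geno <- matrix(0L, nrow = n, ncol = config$bulk_size)
  kept <- 0L
  n_sim <- 0L
  max_attempts <- 2000L * config$bulk_size
  while (kept < config$bulk_size) {
    if (n_sim >= max_attempts)
      stop("failed to collect the bulk: recessive individuals too rare")
    g1 <- sim_gamete(mp, config$recomb_rate)
    g2 <- sim_gamete(mp, config$recomb_rate)
    n_sim <- n_sim + 1L
    dosage <- integer(n)
    for (ch in chroms) dosage[idx[[ch]]] <- g1[[ch]] + g2[[ch]]
    if (dosage[ci] == 2L) {
      kept <- kept + 1L
      geno[, kept] <- dosage
    }
  }
  structure(list(genotypes = geno, variants = variants,
                 phenotype = rep("mutant", config$bulk_size),
                 n_simulated = n_sim),
            class = "f2_bulk")
}

#' Sample sequencing allele depths for the bulk
#'
#' Per variant, total depth is Poisson(`depth_mean`); each read is drawn
#' from a random bulk individual's genotype and miscalled with probability
#' `error_rate`. Zero-depth sites are retained and flagged, never dropped.
#' Parental libraries are emitted as hard genotype calls (wild type
#' homozygous reference, mutant homozygous alternate), which is all the
#' downstream homozygous-difference screen uses.
#'
#' @param bulk an `f2_bulk` from [simulate_f2_bulk()].
#' @param config the same [sim_config()].
#' @return data.frame: the variant table plus `wt_call`, `mut_call`,
#'   `bulk_ref`, `bulk_alt`, `zero_depth`.
#' @export
simulate_allele_depths <- function(bulk, config) {
  stopifnot(inherits(bulk, "f2_bulk"), inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  v <- bulk$variants
  n <- nrow(v)
  depth <- stats::rpois(n, config$depth_mean)
  # reads are i.i.d. draws of (individual, allele): alt prob = mean dosage / 2
  p_alt <- rowMeans(bulk$genotypes) / 2
  alt_true <- stats::rbinom(n, depth, p_alt)
  ref_true <- depth - alt_true
  e <- config$error_rate
  alt_obs <- stats::rbinom(n, alt_true, 1 - e) + stats::rbinom(n, ref_true, e)
  v$wt_call <- "hom_ref"
  v$mut_call <- "hom_alt"
  v$bulk_ref <- depth - alt_obs
  v$bulk_alt <- alt_obs
  v$zero_depth <- depth == 0L
  v
}

#' Run the whole synthetic generator
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_ems_mutations()], [simulate_f2_bulk()] and
#' [simulate_allele_depths()]. Deterministic given the config.
#'
#' @param config a [sim_config()].
#' @return list of class `mutmap_sim` with `config`, `genome`, `mutations`,
#'   `bulk` and `variants` (the allele-depth table consumed by the
#'   analysis modules).
#' @export
simulate_mutmap <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  mutations <- simulate_ems_mutations(config, genome)
  bulk <- simulate_f2_bulk(config, mutations)
  variants <- simulate_allele_depths(bulk, config)
  structure(list(config = config, genome = genome, mutations = mutations,
                 bulk = bulk, variants = variants),
            class = "mutmap_sim")
}

#' @export
print.mutmap_sim <- function(x, ...) {
  cat(sprintf("synthetic MutMap dataset: %d variants on %d chromosome(s), bulk of %d\n",
              nrow(x$variants), x$config$n_chromosomes, x$config$bulk_size))
  invisible(x)
}

## ---- writers -------------------------------------------------------------

#' Write simulated data to standard file formats
#'
#' Emits the reference FASTA, gene models as GFF3 (1-based inclusive,
#' gene/mRNA/exon/CDS hierarchy), a VCF v4.2 with per-sample GT:AD:DP for
#' the wild-type, mutant and bulk libraries, a TSV genotype matrix for the
#' bulk individuals, and a key=value config file.
#'
#' @param sim a `mutmap_sim` from [simulate_mutmap()].
#' @param dir output directory (created if absent).
#' @param samples named character vector with elements `wt`, `mut`, `bulk`
#'   giving the VCF sample names.
#' @return invisibly, a named list of the file paths written.
#' @export
write_simulation <- function(sim, dir,
                             samples = c(wt = "WT", mut = "mutant",
                                         bulk = "F2_bulk")) {
  stopifnot(inherits(sim, "mutmap_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "reference.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "variants.vcf"),
    genotypes = file.path(dir, "bulk_genotypes.tsv"),
    config = file.path(dir, "sim_config.txt")
  )
  write_sim_fasta(sim$genome, paths$fasta)
  write_sim_gff3(sim$genome, paths$gff3)
  write_sim_vcf(sim$variants, sim$genome$chrom_lengths, paths$vcf, samples)
  write_sim_genotypes(sim$bulk, paths$genotypes)
  write_sim_config(sim$config, paths$config)
  invisible(paths)
}

#' @rdname write_simulation
#' @param genome output of [simulate_genome()].
#' @param path output file path.
#' @export
write_sim_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

cds_phases <- function(widths) {
  # phase of each CDS piece in transcription order
  c(0L, (3L - cumsum(widths)[-length(widths)] %% 3L) %% 3L)
}

#' @rdname write_simulation
#' @export
write_sim_gff3 <- function(genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$chrom_lengths),
                     as.integer(genome$chrom_lengths)))
  for (g in genome$genes) {
    mrna <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\tmutmapr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, as.integer(g$start), as.integer(g$end), g$strand,
              g$gene_id),
      sprintf("%s\tmutmapr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, as.integer(g$start), as.integer(g$end), g$strand,
              mrna, g$gene_id))
    ex <- g$exons
    lines <- c(lines,
      sprintf("%s\tmutmapr\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom, as.integer(ex$start), as.integer(ex$end), g$strand,
              mrna))
    cds <- g$cds
    w <- cds$end - cds$start + 1
    ph <- cds_phases(if (g$strand == "+") w else rev(w))
    if (g$strand == "-") ph <- rev(ph)
    lines <- c(lines,
      sprintf("%s\tmutmapr\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
              g$chrom, as.integer(cds$start), as.integer(cds$end), g$strand,
              ph, mrna))
  }
  writeLines(lines, path)
  invisible(path)
}

naive_gt <- function(ref_d, alt_d) {
  ifelse(ref_d + alt_d == 0, "./.",
         ifelse(alt_d == 0, "0/0", ifelse(ref_d == 0, "1/1", "0/1")))
}

#' @rdname write_simulation
#' @param variants allele-depth table from [simulate_allele_depths()].
#' @param chrom_lengths named vector of chromosome lengths.
#' @export
write_sim_vcf <- function(variants, chrom_lengths, path,
                          samples = c(wt = "WT", mut = "mutant",
                                      bulk = "F2_bulk")) {
  stopifnot(all(c("wt", "mut", "bulk") %in% names(samples)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutmapr simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples[["wt"]], samples[["mut"]], samples[["bulk"]]),
          collapse = "\t")
  )
  pd <- 30L  # nominal parental hard-call depth
  wt_f <- sprintf("0/0:%d,0:%d", pd, pd)
  mut_f <- sprintf("1/1:0,%d:%d", pd, pd)
  bulk_f <- sprintf("%s:%d,%d:%d",
                    naive_gt(variants$bulk_ref, variants$bulk_alt),
                    variants$bulk_ref, variants$bulk_alt,
                    variants$bulk_ref + variants$bulk_alt)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s\t%s\t%s",
                  variants$chrom, as.integer(variants$pos),
                  ifelse(variants$causal, "causal", "."),
                  variants$ref, variants$alt, wt_f, mut_f, bulk_f)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_simulation
#' @param bulk an `f2_bulk`.
#' @export
write_sim_genotypes <- function(bulk, path) {
  g <- as.data.frame(bulk$genotypes)
  names(g) <- sprintf("ind_%02d", seq_len(ncol(g)))
  out <- cbind(bulk$variants[, c("chrom", "pos", "ref", "alt")], g)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_simulation
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  keys <- setdiff(names(config), NULL)
  writeLines(c("# mutmapr simulation config",
               sprintf("%s = %.15g", keys, unlist(config[keys]))), path)
  invisible(path)
}

#' Read back a simulation config file
#'
#' @param path file written by [write_sim_config()].
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  do.call(sim_config, as.list(vals))
}
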