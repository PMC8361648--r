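#' Gene model
#'
#' A transcript model: ordered, non-overlapping exons on one strand, with
#' CDS intervals (defaulting to the exons, i.e. no UTR). The total CDS
#' length must be a multiple of 3. Coordinates are 1-based inclusive
#' throughout, following the VCF/GFF convention.
#'
#' @param gene_id character id.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with `start`, `end` (1-based inclusive).
#' @param cds data.frame like `exons`; defaults to the exons.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1,
            strand %in% c("+", "-"),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch")
  cds_len <- sum(cds$end - cds$start + 1)
  if (cds_len %% 3 != 0)
    stop(sprintf("CDS length %d of %s is not a multiple of 3", cds_len,
                 gene_id))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds,
                 start = min(exons$start), end = max(exons$end),
                 n_exons = nrow(exons), cds_length = cds_len),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d (%s), %d exon(s), %d intron(s), CDS %d bp\n",
              x$gene_id, x$chrom, as.integer(x$start), as.integer(x$end),
              x$strand, x$n_exons, x$n_exons - 1L, x$cds_length))
  invisible(x)
}

#' Intron intervals of a gene model
#'
#' @param model a [gene_model()].
#' @return data.frame of intron `start`, `end` (1-based inclusive); always
#'   one fewer row than there are exons.
#' @export
introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2)
    return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
}

gt_class <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% "1/1"] <- "hom_alt"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out
}

#' Read variant calls from a VCF
#'
#' Reads biallelic SNPs from a VCF v4.2 with per-sample AD. Indels and
#' multi-allelic records are skipped with a logged count (attribute
#' `skipped`). Coordinates stay 1-based. The bulk sample's AD field is
#' mapped to `bulk_ref` / `bulk_alt`; the parental samples contribute
#' genotype classes (`hom_ref`, `het`, `hom_alt`, `missing`).
#'
#' @param path VCF file.
#' @param wt_sample,mut_sample,bulk_sample sample names in the VCF.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `wt_call`,
#'   `mut_call`, `bulk_ref`, `bulk_alt`, `zero_depth`, `causal` (TRUE where
#'   the ID field is "causal", a simulator convention), with attribute
#'   `skipped` (named counts of indel and multiallelic records).
#' @export
read_variants <- function(path, wt_sample, mut_sample, bulk_sample) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  for (s in c(wt_sample, mut_sample, bulk_sample))
    if (!s %in% have)
      stop(sprintf("sample '%s' not present in %s (samples: %s)", s, path,
                   paste(have, collapse = ", ")))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT)
  snp <- !multi & fix$REF %in% bases & fix$ALT %in% bases
  skipped <- c(indel = sum(!snp & !multi), multiallelic = sum(multi))
  if (any(!snp))
    message(sprintf("skipped %d non-SNP record(s) (%d indel/MNV, %d multiallelic)",
                    sum(!snp), skipped[["indel"]], skipped[["multiallelic"]]))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (all(is.na(ad[, bulk_sample])))
    stop(sprintf("bulk sample '%s' has no AD field", bulk_sample))
  idx <- which(snp)
  ad_bulk <- strsplit(ad[idx, bulk_sample], ",", fixed = TRUE)
  bad <- which(lengths(ad_bulk) != 2)
  if (length(bad) > 0)
    stop(sprintf("malformed AD for sample '%s' at record %d (%s:%s)",
                 bulk_sample, idx[bad[1]], fix$CHROM[idx[bad[1]]],
                 fix$POS[idx[bad[1]]]))
  ad_num <- suppressWarnings(
    matrix(as.integer(unlist(ad_bulk)), ncol = 2, byrow = TRUE))
  if (anyNA(ad_num))
    stop(sprintf("non-numeric AD for sample '%s'", bulk_sample))
  out <- data.frame(
    chrom = fix$CHROM[idx],
    pos = as.numeric(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = fix$ALT[idx],
    wt_call = gt_class(gt[idx, wt_sample]),
    mut_call = gt_class(gt[idx, mut_sample]),
    bulk_ref = ad_num[, 1],
    bulk_alt = ad_num[, 2],
    stringsAsFactors = FALSE
  )
  out$zero_depth <- out$bulk_ref + out$bulk_alt == 0L
  out$causal <- !is.na(fix$ID[idx]) & fix$ID[idx] == "causal"
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read variant calls from the allele-count TSV dialect
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `wt_gt`, `mut_gt`, `bulk_ref`,
#' `bulk_alt`. Genotypes may be VCF-style ("0/0") or class labels
#' ("hom_ref").
#'
#' @param path TSV file.
#' @return data.frame in the same shape as [read_variants()].
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "wt_gt", "mut_gt",
            "bulk_ref", "bulk_alt")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  as_class <- function(x) {
    ifelse(x %in% c("hom_ref", "het", "hom_alt", "missing"), x, gt_class(x))
  }
  out <- data.frame(chrom = d$chrom, pos = as.numeric(d$pos),
                    ref = d$ref, alt = d$alt,
                    wt_call = as_class(d$wt_gt),
                    mut_call = as_class(d$mut_gt),
                    bulk_ref = as.integer(d$bulk_ref),
                    bulk_alt = as.integer(d$bulk_alt),
                    stringsAsFactors = FALSE)
  out$zero_depth <- out$bulk_ref + out$bulk_alt == 0L
  out[order(out$chrom, out$pos), ]
}

#' Keep homozygous parental differences
#'
#' Retains sites where the mutant library is homozygous for the alternate
#' allele and the wild-type library homozygous for the reference. These are
#' the mutant-origin loci at which the bulk SNP index is informative; sites
#' where the wild-type progenitor itself differs from the reference genome
#' are background, not candidates.
#'
#' @param records variant data.frame with `wt_call` and `mut_call`.
#' @return the filtered data.frame, with attribute `n_dropped`.
#' @export
homozygous_differences <- function(records) {
  stopifnot(all(c("wt_call", "mut_call") %in% names(records)))
  keep <- records$wt_call == "hom_ref" & records$mut_call == "hom_alt"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Map a genomic position into CDS coordinates
#'
#' Strand-aware cumulative-exon mapping. Positions in introns return a
#' non-coding status plus the distance to the nearest exon boundary (1 for
#' the base immediately past a donor/acceptor site); positions outside the
#' gene span are intergenic; exonic positions outside the CDS are UTR.
#'
#' @param model a [gene_model()].
#' @param pos 1-based genomic position on the model's chromosome.
#' @return list with `status` ("coding", "intronic", "utr", "intergenic"),
#'   `cds_offset` (1-based, NA unless coding) and `boundary_dist` (NA unless
#'   intronic).
#' @export
map_genomic_to_cds <- function(model, pos) {
  stopifnot(inherits(model, "gene_model"), length(pos) == 1)
  if (pos < model$start || pos > model$end)
    return(list(status = "intergenic", cds_offset = NA_real_,
                boundary_dist = NA_real_))
  cds <- model$cds
  i <- which(pos >= cds$start & pos <= cds$end)
  if (length(i) == 1) {
    w <- cds$end - cds$start + 1
    before <- if (i > 1) sum(w[seq_len(i - 1)]) else 0
    off_plus <- before + (pos - cds$start[i]) + 1
    off <- if (model$strand == "+") off_plus else sum(w) - off_plus + 1
    return(list(status = "coding", cds_offset = off, boundary_dist = NA_real_))
  }
  ex <- model$exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (in_exon)
    return(list(status = "utr", cds_offset = NA_real_,
                boundary_dist = NA_real_))
  # intronic: distance to the nearest flanking exon boundary
  prev_end <- max(ex$end[ex$end < pos])
  next_start <- min(ex$start[ex$start > pos])
  list(status = "intronic", cds_offset = NA_real_,
       boundary_dist = min(pos - prev_end, next_start - pos))
}

#' Map a CDS offset back to its genomic position
#'
#' Inverse of [map_genomic_to_cds()] for coding positions.
#'
#' @param model a [gene_model()].
#' @param offset 1-based CDS offset.
#' @return 1-based genomic position.
#' @export
map_cds_to_genomic <- function(model, offset) {
  stopifnot(inherits(model, "gene_model"), offset >= 1,
            offset <= model$cds_length)
  cds <- model$cds
  w <- cds$end - cds$start + 1
  off_plus <- if (model$strand == "+") offset else model$cds_length - offset + 1
  cum <- cumsum(w)
  i <- which(off_plus <= cum)[1]
  before <- if (i > 1) cum[i - 1] else 0
  cds$start[i] + (off_plus - before) - 1
}

#' Convert a CDS offset to residue index and codon position
#'
#' @param offset 1-based CDS offset(s).
#' @return data.frame with `residue` (= ceiling(offset/3)) and `codon_pos`
#'   (1, 2 or 3).
#' @export
cds_offset_to_residue <- function(offset) {
  if (any(offset < 1)) stop("CDS offset must be >= 1")
  data.frame(residue = ceiling(offset / 3),
             codon_pos = ((offset - 1) %% 3) + 1)
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Translate a coding sequence
#'
#' Standard genetic code, codon-by-codon. A trailing stop codon is removed
#' (so a 2,715 bp CDS ending in a stop yields 904 residues). An internal
#' stop raises an error unless `truncate_at_stop = TRUE`, in which case the
#' protein is truncated there -- useful for reasoning about
#' frameshift/premature-stop mutant alleles.
#'
#' @param cds character coding sequence; length must be a multiple of 3.
#' @param truncate_at_stop allow internal stops and truncate.
#' @return the protein sequence (single character string, no stop symbol).
#' @export
translate_cds <- function(cds, truncate_at_stop = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0)
    stop(sprintf("CDS length %d is not a positive multiple of 3", n))
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa))
    stop(sprintf("invalid codon '%s' at codon %d", codons[which(is.na(aa))[1]],
                 which(is.na(aa))[1]))
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal <- which(aa == "*")
  if (length(internal) > 0) {
    if (!truncate_at_stop)
      stop(sprintf("internal stop codon at residue %d", internal[1]))
    aa <- aa[seq_len(internal[1] - 1)]
  }
  paste(aa, collapse = "")
}

#' EMS-typical transition flag
#'
#' TRUE iff the change is one of the canonical EMS lesions G>A or C>T
#' (alkylation of guanine followed by mispairing).
#'
#' @param ref,alt single reference / alternate bases (vectorised).
#' @return logical vector.
#' @export
ems_typical <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Variant effect classes counted as "large effect"
#'
#' Coding or splice changes expected to alter protein function.
#' @export
large_effect_classes <- c("nonsynonymous", "stop_gain", "stop_loss",
                          "splicing")

#' Annotate variant effects against gene models
#'
#' Classifies each SNP by translating the reference and alternate codons
#' with the standard genetic code: `synonymous`, `nonsynonymous`,
#' `stop_gain`, `stop_loss`; intronic SNPs within `splice_margin` bp of an
#' exon boundary (the canonical donor/acceptor dinucleotides at the default
#' of 2) are `splicing`; the rest are `intronic`, `UTR` or `intergenic`.
#' Annotation is strand-aware, and the reference base at each position is
#' checked against the sequence (mismatch is a data-consistency error).
#'
#' @param records variant data.frame (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param models list of [gene_model()] objects.
#' @param sequences named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param splice_margin bp from an exon boundary within which an intronic
#'   SNP is called `splicing`.
#' @return `records` with added columns `gene_id`, `effect`, `aa_ref`,
#'   `aa_pos`, `aa_alt`, `ems_typical`.
#' @export
annotate_effect <- function(records, models, sequences, splice_margin = 2) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  g_chrom <- vapply(models, function(g) g$chrom, character(1))
  g_start <- vapply(models, function(g) g$start, numeric(1))
  g_end <- vapply(models, function(g) g$end, numeric(1))
  n <- nrow(records)
  gene_id <- rep(NA_character_, n)
  effect <- rep("intergenic", n)
  aa_ref <- rep(NA_character_, n)
  aa_pos <- rep(NA_real_, n)
  aa_alt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ch <- records$chrom[i]
    pos <- records$pos[i]
    ref_base <- substring(sequences[[ch]], pos, pos)
    if (ref_base != records$ref[i])
      stop(sprintf("reference mismatch at %s:%d: sequence has %s, record has %s",
                   ch, as.integer(pos), ref_base, records$ref[i]))
    hit <- which(g_chrom == ch & g_start <= pos & g_end >= pos)
    if (length(hit) == 0) next
    g <- models[[hit[1]]]
    gene_id[i] <- g$gene_id
    m <- map_genomic_to_cds(g, pos)
    if (m$status == "intronic") {
      effect[i] <- if (m$boundary_dist <= splice_margin) "splicing" else
        "intronic"
      next
    }
    if (m$status == "utr") {
      effect[i] <- "UTR"
      next
    }
    rc <- cds_offset_to_residue(m$cds_offset)
    codon_off <- (rc$residue - 1) * 3 + 1:3
    gpos <- vapply(codon_off, function(o) map_cds_to_genomic(g, o), numeric(1))
    plus_bases <- substring(sequences[[ch]], gpos, gpos)
    codon_ref <- if (g$strand == "+") plus_bases else comp_base(plus_bases)
    alt_in_cds <- if (g$strand == "+") records$alt[i] else
      comp_base(records$alt[i])
    codon_alt <- codon_ref
    codon_alt[rc$codon_pos] <- alt_in_cds
    ref_aa <- unname(Biostrings::GENETIC_CODE[paste(codon_ref, collapse = "")])
    alt_aa <- unname(Biostrings::GENETIC_CODE[paste(codon_alt, collapse = "")])
    effect[i] <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gain"
      else if (ref_aa == "*") "stop_loss"
      else "nonsynonymous"
    aa_ref[i] <- ref_aa
    aa_pos[i] <- rc$residue
    aa_alt[i] <- alt_aa
  }
  records$gene_id <- gene_id
  records$effect <- effect
  records$aa_ref <- aa_ref
  records$aa_pos <- aa_pos
  records$aa_alt <- aa_alt
  records$ems_typical <- ems_typical(records$ref, records$alt)
  records
}

#' Read gene models from GFF3
#'
#' Builds [gene_model()] objects from a GFF3 file with a
#' gene/mRNA/exon/CDS hierarchy (one transcript per gene).
#'
#' @param path GFF3 file.
#' @return named list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path)
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  d$Parent <- vapply(d$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[[1]]), character(1))
  genes <- d[d$type == "gene", ]
  mrnas <- d[d$type == "mRNA", ]
  out <- list()
  for (k in seq_len(nrow(genes))) {
    gid <- genes$ID[k]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, ][1, ]
    ex <- d[d$type == "exon" & !is.na(d$Parent) & d$Parent == tx$ID, ]
    cds <- d[d$type == "CDS" & !is.na(d$Parent) & d$Parent == tx$ID, ]
    out[[gid]] <- gene_model(
      gid, as.character(genes$seqnames[k]), as.character(genes$strand[k]),
      data.frame(start = ex$start, end = ex$end),
      if (nrow(cds) > 0) data.frame(start = cds$start, end = cds$end)
      else data.frame(start = ex$start, end = ex$end))
  }
  out
}

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write an annotated variant table
#'
#' @param records annotated variant data.frame.
#' @param path output TSV.
#' @export
write_annotated_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
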