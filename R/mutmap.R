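#' SNP index from bulk allele depths
#'
#' The SNP index is the fraction of bulk reads carrying the mutant
#' (alternate) allele: `alt / (alt + ref)`. It is ~0.5 at mutant-origin loci
#' unlinked to the selected causal mutation and approaches 1 at tightly
#' linked loci. Undefined (NA) when total depth is zero.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorised).
#' @return numeric vector in `[0, 1]`, NA where depth is zero.
#' @export
snp_index <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop("allele depths must be non-negative")
  total <- ref_depth + alt_depth
  ifelse(total > 0, alt_depth / total, NA_real_)
}

#' Add a `snp_index` column to a variant table
#'
#' @param records data.frame with `bulk_ref`, `bulk_alt`.
#' @return `records` with a `snp_index` column.
#' @export
add_snp_index <- function(records) {
  records$snp_index <- snp_index(records$bulk_ref, records$bulk_alt)
  records
}

#' Drop low-index variants
#'
#' Removes variants with SNP index below `min_index`; the boundary value is
#' kept ("index < 0.3 filtered out" means >= 0.3 is retained).
#' Undefined-index records (zero depth) are dropped and counted in the
#' `n_undefined_dropped` attribute, never silently.
#'
#' @param records data.frame with `snp_index`.
#' @param min_index retention threshold (default 0.3).
#' @return filtered data.frame with attributes `n_undefined_dropped` and
#'   `n_below_dropped`.
#' @export
filter_low_index <- function(records, min_index = 0.3) {
  stopifnot("snp_index" %in% names(records))
  undef <- is.na(records$snp_index)
  keep <- !undef & records$snp_index >= min_index
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_undefined_dropped") <- sum(undef)
  attr(out, "n_below_dropped") <- sum(!undef & !keep)
  out
}

#' Sliding-window scan of the SNP index
#'
#' Per chromosome, windows of `window` bp start at 1, 1 + `step`,
#' 1 + 2 `step`, ... while the start is within the chromosome; the last
#' windows are shortened at the chromosome end. Each window records the
#' number of variants it contains and the arithmetic mean of their SNP
#' indices (NA when the window holds no variant with a defined index -- an
#' empty window is absence of evidence, not an index of 0). Input must
#' already be sorted by (chrom, pos); unsorted input is an error rather
#' than being silently reordered.
#'
#' @param records data.frame with `chrom`, `pos`, `snp_index`, sorted.
#' @param chrom_lengths named numeric vector of chromosome lengths; all
#'   chromosomes to scan must be named here.
#' @param window window size in bp (default 1 Mb).
#' @param step step size in bp (default 10 kb); `window >= step > 0`.
#' @return data.frame of class `window_scan`: `chrom`, `start`, `end`
#'   (1-based inclusive), `n_variants`, `mean_index`.
#' @export
sliding_window_scan <- function(records, chrom_lengths,
                                window = 1e6, step = 1e4) {
  if (!(window >= step && step > 0))
    stop("need window >= step > 0")
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  stopifnot(all(c("chrom", "pos", "snp_index") %in% names(records)))
  extra <- setdiff(unique(records$chrom), names(chrom_lengths))
  if (length(extra) > 0)
    stop(sprintf("chromosome(s) missing from chrom_lengths: %s",
                 paste(extra, collapse = ", ")))
  ord <- order(match(records$chrom, unique(records$chrom)))
  if (is.unsorted(match(records$chrom, names(chrom_lengths))) ||
      any(tapply(records$pos, factor(records$chrom,
                                     levels = unique(records$chrom)),
                 is.unsorted)))
    stop("records must be sorted by (chrom, pos); refusing to sort silently")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window - 1, len)
    p <- records$pos[records$chrom == ch]
    si <- records$snp_index[records$chrom == ch]
    o <- order(p)
    p <- p[o]; si <- si[o]
    cs_n <- c(0, cumsum(!is.na(si)))
    cs_sum <- c(0, cumsum(ifelse(is.na(si), 0, si)))
    i_lo <- findInterval(starts - 1, p)
    i_hi <- findInterval(ends, p)
    n_var <- i_hi - i_lo
    n_def <- cs_n[i_hi + 1] - cs_n[i_lo + 1]
    s_def <- cs_sum[i_hi + 1] - cs_sum[i_lo + 1]
    data.frame(chrom = ch, start = starts, end = ends,
               n_variants = n_var,
               mean_index = ifelse(n_def > 0, s_def / n_def, NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_scan", "data.frame")
  res
}

#' Best-scoring window of a scan
#'
#' @param scan a [sliding_window_scan()] result.
#' @return the row(s) attaining the genome-wide maximum mean index.
#' @export
peak_window <- function(scan) {
  mx <- max(scan$mean_index, na.rm = TRUE)
  scan[!is.na(scan$mean_index) & scan$mean_index == mx, , drop = FALSE]
}

#' Candidate filter cascade
#'
#' Applies, in order: (1) retain SNP index = 1 -- either exactly, or within
#' one read of fixation (`index >= 1 - 1/depth`): at finite depth a truly
#' fixed locus shows a single non-alternate read whenever one read is
#' miscalled (probability about `depth * error_rate`), and a tolerance any
#' tighter than one read admits nothing beyond exact fixation at integer
#' counts; (2) the EMS-typicality filter -- `strict` drops non-G>A/C>T
#' changes, `permissive` keeps them (flagged), `off` skips the stage;
#' (3) retain large-effect classes (nonsynonymous, stop gain/loss,
#' splicing). Survivors are ordered by (chrom, pos) and per-stage retention
#' counts are recorded.
#'
#' @param records annotated variant data.frame with `snp_index`, `effect`,
#'   `ems_typical`.
#' @param index_mode "tolerant" (default) or "exact".
#' @param ems_filter "strict" (default), "permissive" or "off".
#' @return object of class `candidate_report`: list with `candidates`,
#'   `stage_counts` (named, monotone non-increasing) and `params`.
#' @export
candidate_screen <- function(records,
                             index_mode = c("tolerant", "exact"),
                             ems_filter = c("strict", "permissive", "off")) {
  index_mode <- match.arg(index_mode)
  ems_filter <- match.arg(ems_filter)
  stopifnot(all(c("snp_index", "effect", "ems_typical") %in% names(records)))
  counts <- c(input = nrow(records))

  idx <- records$snp_index
  keep1 <- if (index_mode == "exact") !is.na(idx) & idx == 1 else {
    depth <- records$bulk_ref + records$bulk_alt
    !is.na(idx) & depth > 0 & idx >= 1 - 1 / depth - 1e-12
  }
  s1 <- records[keep1, , drop = FALSE]
  counts <- c(counts, index_one = nrow(s1))

  s2 <- if (ems_filter == "strict") s1[s1$ems_typical, , drop = FALSE] else s1
  counts <- c(counts, ems_typical = nrow(s2))

  s3 <- s2[s2$effect %in% large_effect_classes, , drop = FALSE]
  counts <- c(counts, large_effect = nrow(s3))

  s3 <- s3[order(s3$chrom, s3$pos), , drop = FALSE]
  rownames(s3) <- NULL
  structure(list(candidates = s3, stage_counts = counts,
                 params = list(index_mode = index_mode,
                               ems_filter = ems_filter)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("MutMap candidate screen\n")
  cat(sprintf("  stage retention: %s\n",
              paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
                    collapse = " -> ")))
  cat(sprintf("  index mode '%s', EMS filter '%s'\n",
              x$params$index_mode, x$params$ems_filter))
  if (nrow(x$candidates) == 0) {
    cat("  no candidates\n")
  } else {
    cols <- intersect(c("gene_id", "chrom", "pos", "ref", "alt", "snp_index",
                        "effect", "aa_ref", "aa_pos", "aa_alt"),
                      names(x$candidates))
    print(x$candidates[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' Run the MutMap analysis pipeline on a variant table
#'
#' Fixed stage order: homozygous parental difference, effect annotation,
#' large-effect preselection (the loci at which the SNP index is worth
#' computing), SNP index, low-index filter, sliding-window scan of the
#' retained loci, and the candidate cascade.
#'
#' @param records variant table as from [read_variants()].
#' @param models list of [gene_model()] objects.
#' @param sequences named chromosome sequences.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window,step scan geometry in bp.
#' @param min_index low-index retention threshold.
#' @param index_mode,ems_filter passed to [candidate_screen()].
#' @param splice_margin passed to [annotate_effect()].
#' @param preselect_large_effect compute the index only at large-effect
#'   homozygous differences (default TRUE, the usual workflow); set FALSE
#'   to scan every homozygous difference.
#' @return list of class `mutmap_result`: `hom_diff` (annotated, indexed),
#'   `preselected`, `indexed` (post low-index filter), `scan`, `report`,
#'   `params`.
#' @export
mutmap_pipeline <- function(records, models, sequences, chrom_lengths,
                            window = 1e6, step = 1e4, min_index = 0.3,
                            index_mode = "tolerant", ems_filter = "strict",
                            splice_margin = 2,
                            preselect_large_effect = TRUE) {
  hom <- homozygous_differences(records)
  hom <- annotate_effect(hom, models, sequences, splice_margin = splice_margin)
  hom <- add_snp_index(hom)
  pre <- if (preselect_large_effect)
    hom[hom$effect %in% large_effect_classes, , drop = FALSE] else hom
  idx <- filter_low_index(pre, min_index = min_index)
  scan <- sliding_window_scan(idx, chrom_lengths, window = window, step = step)
  report <- candidate_screen(idx, index_mode = index_mode,
                             ems_filter = ems_filter)
  structure(list(hom_diff = hom, preselected = pre, indexed = idx,
                 scan = scan, report = report,
                 params = list(window = window, step = step,
                               min_index = min_index,
                               index_mode = index_mode,
                               ems_filter = ems_filter,
                               splice_margin = splice_margin,
                               preselect_large_effect =
                                 preselect_large_effect)),
            class = "mutmap_result")
}

#' @export
print.mutmap_result <- function(x, ...) {
  cat(sprintf("MutMap scan: %d homozygous differences, %d indexed loci, %d window(s)\n",
              nrow(x$hom_diff), nrow(x$indexed), nrow(x$scan)))
  print(x$report)
  invisible(x)
}

#' Write the candidate report, window track and run log
#'
#' The candidate table mirrors the usual published layout (gene id,
#' position, ref, alt, SNP index, variant class). The window track is a
#' BED-like TSV in 0-based half-open coordinates (`start0 = start - 1`,
#' `end` unchanged), so intervals re-convert losslessly to the 1-based
#' inclusive windows. The log records every stage count and parameter.
#'
#' @param result a `mutmap_result` from [mutmap_pipeline()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, a named list of paths (`candidates`, `windows`,
#'   `log`).
#' @export
write_report <- function(result, dir, prefix = "mutmap") {
  stopifnot(inherits(result, "mutmap_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(candidates = file.path(dir, paste0(prefix, "_candidates.tsv")),
                windows = file.path(dir, paste0(prefix, "_windows.bed")),
                log = file.path(dir, paste0(prefix, "_run.log")))
  cand <- result$report$candidates
  cols <- intersect(c("gene_id", "chrom", "pos", "ref", "alt", "snp_index",
                      "effect", "aa_ref", "aa_pos", "aa_alt", "ems_typical"),
                    names(cand))
  utils::write.table(cand[, cols, drop = FALSE], paths$candidates,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = result$scan$chrom,
                    start = as.integer(result$scan$start - 1),
                    end = as.integer(result$scan$end),
                    n_variants = result$scan$n_variants,
                    mean_index = result$scan$mean_index)
  utils::write.table(bed, paths$windows, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc <- result$report$stage_counts
  log_lines <- c(
    sprintf("mutmapr run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("param %s = %s", names(result$params),
            vapply(result$params, function(p) paste(format(p), collapse = ","),
                   character(1))),
    sprintf("count hom_diff = %d", nrow(result$hom_diff)),
    sprintf("count preselected_large_effect = %d", nrow(result$preselected)),
    sprintf("count low_index_dropped = %d",
            attr(result$indexed, "n_below_dropped") %||% NA_integer_),
    sprintf("count undefined_index_dropped = %d",
            attr(result$indexed, "n_undefined_dropped") %||% NA_integer_),
    sprintf("count stage_%s = %d", names(sc), sc),
    sprintf("count windows = %d", nrow(result$scan))
  )
  writeLines(log_lines, paths$log)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a window track written by [write_report()]
#'
#' Converts the 0-based half-open BED intervals back to 1-based inclusive
#' window coordinates.
#'
#' @param path the `*_windows.bed` file.
#' @return data.frame like a [sliding_window_scan()] result.
#' @export
read_windows_bed <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(chrom = d$chrom, start = d$start + 1, end = d$end,
                    n_variants = d$n_variants, mean_index = d$mean_index,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_scan", "data.frame")
  out
}
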