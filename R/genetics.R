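#' Chi-square test of a Mendelian segregation ratio
#'
#' Tests observed class counts against an expected ratio (3:1, 1:1, ...).
#' For two classes the Yates continuity correction is applied by default:
#' `sum((max(|O - E| - 0.5, 0))^2 / E)` with the correction clamped at zero
#' for a perfect fit. With `yates = FALSE` (or more than two classes) the
#' plain Pearson statistic is used. The statistic is compared with the 5%
#' critical value (3.84 at one degree of freedom).
#'
#' @param observed non-negative class counts (length >= 2).
#' @param ratio expected ratio terms, same length (e.g. `c(3, 1)`).
#' @param yates apply the continuity correction for 2-class tests.
#' @return object of class `seg_test`: `statistic`, `df`,
#'   `critical_value` (5% level), `p_value`, `reject`, `expected`, `method`.
#' @export
chi_square_segregation <- function(observed, ratio, yates = TRUE) {
  if (length(observed) < 2) stop("need at least two phenotype classes")
  if (length(ratio) != length(observed))
    stop("ratio must have one term per class")
  if (any(observed < 0)) stop("counts must be non-negative")
  if (any(ratio <= 0)) stop("ratio terms must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop("zero expected count")
  use_yates <- yates && length(observed) == 2
  stat <- if (use_yates)
    sum(pmax(abs(observed - expected) - 0.5, 0)^2 / expected)
  else
    sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  crit <- stats::qchisq(0.95, df)
  structure(list(statistic = stat, df = df, critical_value = crit,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 reject = stat > crit, observed = observed,
                 expected = expected,
                 method = if (use_yates) "Pearson chi-square with Yates continuity correction"
                          else "Pearson chi-square"),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  %s the expected ratio at the 5%% level (critical value %.2f)\n",
              if (x$reject) "inconsistent with" else "consistent with",
              x$critical_value))
  invisible(x)
}

#' Segregation ratio normalised to the second class
#'
#' @param observed counts of two phenotype classes.
#' @return list with `value` (first/second, rounded to 2 decimals) and
#'   `label` like `"3.05: 1"`.
#' @export
segregation_ratio <- function(observed) {
  if (length(observed) != 2) stop("segregation_ratio expects two classes")
  if (observed[2] == 0) stop("second class count is zero; ratio undefined")
  r <- round(observed[1] / observed[2], 2)
  list(value = r, label = sprintf("%.2f: 1", r))
}

parse_genotype <- function(gt) {
  a <- strsplit(gt, "[:/|]")
  bad <- which(lengths(a) != 2)
  if (length(bad) > 0)
    stop(sprintf("malformed genotype '%s' (expected e.g. 'C:T')", gt[bad[1]]))
  a
}

#' Genotype-phenotype co-segregation check
#'
#' KASP-style confirmation: counts mutant-phenotype individuals that are
#' NOT homozygous for the mutant-associated allele at the locus
#' (recombinants). The marker co-segregates when no recombinant exists.
#'
#' @param table data.frame with a phenotype column and one genotype column
#'   per locus (diploid calls like "T:T", "C:T").
#' @param locus name of the genotype column to check.
#' @param mutant_allele the allele associated with the mutant phenotype.
#' @param phenotype_col name of the phenotype column.
#' @param mutant_class phenotype label of mutant individuals.
#' @return list with `recombinants`, `cosegregates`, `n_mutant`.
#' @export
cosegregation_check <- function(table, locus, mutant_allele,
                                phenotype_col = "phenotype",
                                mutant_class = "mutant") {
  if (!locus %in% names(table))
    stop(sprintf("locus column '%s' not in table", locus))
  if (!phenotype_col %in% names(table))
    stop(sprintf("phenotype column '%s' not in table", phenotype_col))
  if (anyNA(table[[phenotype_col]])) stop("missing phenotype")
  alleles <- parse_genotype(table[[locus]])
  alphabet <- unique(unlist(alleles))
  if (!mutant_allele %in% alphabet)
    stop(sprintf("unknown allele symbol '%s' at locus %s (observed: %s)",
                 mutant_allele, locus, paste(alphabet, collapse = ", ")))
  is_mut <- table[[phenotype_col]] == mutant_class
  hom_mut <- vapply(alleles, function(a) all(a == mutant_allele), logical(1))
  recomb <- sum(is_mut & !hom_mut)
  list(recombinants = recomb, cosegregates = recomb == 0,
       n_mutant = sum(is_mut))
}

#' Simulate phenotype counts for a cross design
#'
#' Single fully penetrant recessive locus. `F2` offspring are a selfed F1
#' (alt dosage ~ Binomial(2, 1/2), mutant iff dosage 2); `BC1_mutant` is
#' F1 x mutant (dosage 1 + Bernoulli(1/2)); `BC1_wildtype` is F1 x wild
#' type (dosage never 2, so no mutants). Returns the class counts plus the
#' matching segregation chi-square where a non-degenerate ratio exists.
#'
#' @param n number of offspring.
#' @param generation cross design.
#' @param seed optional seed.
#' @return list with `counts` (named: wildtype, mutant), `expected_ratio`
#'   and `test` (a `seg_test`, or NULL for BC1 x wild type where every
#'   individual is expected wild-type).
#' @export
phenotype_ratio_simulation <- function(n,
                                       generation = c("F2", "BC1_mutant",
                                                      "BC1_wildtype"),
                                       seed = NULL) {
  generation <- match.arg(generation)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dosage <- switch(generation,
    F2 = stats::rbinom(n, 2, 0.5),
    BC1_mutant = 1L + stats::rbinom(n, 1, 0.5),
    BC1_wildtype = stats::rbinom(n, 1, 0.5))
  mutant <- dosage == 2L
  counts <- c(wildtype = sum(!mutant), mutant = sum(mutant))
  ratio <- switch(generation, F2 = c(3, 1), BC1_mutant = c(1, 1),
                  BC1_wildtype = NULL)
  test <- if (!is.null(ratio)) chi_square_segregation(counts, ratio) else NULL
  list(counts = counts, expected_ratio = ratio, test = test)
}
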