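#' Classify sequence variants
#'
#' Classes are the cross of singleton status (exactly one alternative
#' allele among the non-missing sequenced genotypes), novelty (known rs
#' identifier or not) and variant type from the ref/alt lengths (SNV,
#' insertion, deletion).
#'
#' @param variants `data.frame` with `ref`, `alt`, `rs_known` and either a
#'   `singleton` column or a genotype matrix via `geno`.
#' @param geno optional sequenced genotype matrix (samples x variants)
#'   from which singleton status is computed.
#' @return The input with `type`, `singleton` and `class` columns added;
#'   `class` is e.g. `"singleton:novel:insertion"`.
#' @export
classify_variants <- function(variants, geno = NULL) {
  type <- ifelse(nchar(variants$ref) == nchar(variants$alt), "SNV",
                 ifelse(nchar(variants$ref) < nchar(variants$alt),
                        "insertion", "deletion"))
  if (!is.null(geno)) {
    variants$singleton <- colSums(geno, na.rm = TRUE) == 1L
  }
  if (is.null(variants$singleton)) stop("singleton status unavailable")
  variants$type <- type
  variants$class <- paste(ifelse(variants$singleton, "singleton",
                                 "non-singleton"),
                          ifelse(variants$rs_known, "rs", "novel"),
                          type, sep = ":")
  variants
}

#' IBD2 discordance of one variant
#'
#' A generalized Mendelian check: for each sequenced pair whose IBD2
#' interval contains the variant's position, the two genotypes must agree.
#' Returns the number of informative pairs (both genotypes non-missing)
#' and the number of discordant pairs.
#'
#' @param geno the variant's genotypes over the sequenced samples (named
#'   by sample id).
#' @param chrom,bp the variant's position.
#' @param ibd2 `data.frame` of IBD2 intervals with columns `sample_i`,
#'   `sample_j`, `chrom`, `start_bp`, `end_bp`.
#' @return Named integer vector `c(n_pairs, n_discordant)`.
#' @export
ibd2_discordance <- function(geno, chrom, bp, ibd2) {
  cov <- ibd2$chrom == chrom & ibd2$start_bp <= bp & bp <= ibd2$end_bp
  n_pairs <- 0L; n_disc <- 0L
  if (any(cov)) {
    gi <- geno[ibd2$sample_i[cov]]
    gj <- geno[ibd2$sample_j[cov]]
    ok <- !is.na(gi) & !is.na(gj)
    n_pairs <- sum(ok)
    n_disc <- sum(gi[ok] != gj[ok])
  }
  c(n_pairs = n_pairs, n_discordant = n_disc)
}

#' IBD2 interval table for the sequenced subset
#'
#' Convenience wrapper collecting [ibd2_segments()] over all pairs of
#' sequenced samples into the bp-interval table [ibd2_discordance()]
#' consumes.
#'
#' @param store an [segment_store()].
#' @param sequenced sequenced sample ids.
#' @param pairs optional two-column matrix/data.frame of sample-id pairs to
#'   restrict to (defaults to all pairs of `sequenced`).
#' @return `data.frame` with `sample_i`, `sample_j`, `chrom`, `start_bp`,
#'   `end_bp`.
#' @export
ibd2_table <- function(store, sequenced, pairs = NULL) {
  if (is.null(pairs)) {
    ns <- length(sequenced)
    pairs <- cbind(rep(sequenced, times = (ns - 1L):0L),
                   sequenced[sequence((ns - 1L):0L) +
                               rep(seq_len(ns), times = (ns - 1L):0L)])
  }
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    seg <- ibd2_segments(store, c(pairs[r, 1], pairs[r, 2]))
    if (nrow(seg))
      out[[length(out) + 1L]] <-
        data.frame(sample_i = pairs[r, 1], sample_j = pairs[r, 2],
                   chrom = seg$chrom, start_bp = seg$start_bp,
                   end_bp = seg$end_bp)
  }
  if (!length(out))
    return(data.frame(sample_i = character(), sample_j = character(),
                      chrom = integer(), start_bp = numeric(),
                      end_bp = numeric()))
  do.call(rbind, out)
}

#' Per-class IBD2 discordance rate
#'
#' The class error rate is the total number of discordances divided by
#' the total number of covering IBD2 pairs across the class's variants;
#' `NA` when no pairs cover any variant of the class.
#'
#' @param variants classified variants (see [classify_variants()]).
#' @param geno sequenced genotype matrix (samples x variants).
#' @param ibd2 IBD2 interval table (see [ibd2_table()]).
#' @return `data.frame` per class: `class`, `n_variants`, `n_pairs`,
#'   `n_discordant`, `rate`.
#' @export
class_discordance_rate <- function(variants, geno, ibd2) {
  counts <- t(vapply(seq_len(nrow(variants)), function(v)
    ibd2_discordance(setNames(geno[, v], rownames(geno)),
                     variants$chrom[v], variants$bp[v], ibd2),
    c(n_pairs = 0L, n_discordant = 0L)))
  agg_p <- tapply(counts[, "n_pairs"], variants$class, sum)
  agg_d <- tapply(counts[, "n_discordant"], variants$class, sum)
  nv <- tapply(rep(1L, nrow(variants)), variants$class, sum)
  data.frame(class = names(agg_p), n_variants = as.integer(nv),
             n_pairs = as.integer(agg_p), n_discordant = as.integer(agg_d),
             rate = ifelse(agg_p > 0, agg_d / agg_p, NA_real_),
             row.names = NULL)
}

#' Default per-class call-rate cutoffs
#'
#' Non-singleton known (rs) variants: 0.9; non-singleton novel: 0.99;
#' singleton known: 0.99; singleton novel SNVs and deletions: 0.99;
#' singleton novel insertions: 0.9.
#'
#' @return Named numeric vector keyed by class string.
#' @export
default_class_cutoffs <- function() {
  c("non-singleton:rs:SNV" = 0.9, "non-singleton:rs:insertion" = 0.9,
    "non-singleton:rs:deletion" = 0.9,
    "non-singleton:novel:SNV" = 0.99, "non-singleton:novel:insertion" = 0.99,
    "non-singleton:novel:deletion" = 0.99,
    "singleton:rs:SNV" = 0.99, "singleton:rs:insertion" = 0.99,
    "singleton:rs:deletion" = 0.99,
    "singleton:novel:SNV" = 0.99, "singleton:novel:insertion" = 0.9,
    "singleton:novel:deletion" = 0.99)
}

#' Apply per-class call-rate cutoffs
#'
#' A variant passes when its call rate strictly exceeds its class's
#' cutoff. An optional per-variant high-quality flag is honored as a
#' prerequisite.
#'
#' @param variants classified variants with a `call_rate` column.
#' @param cutoffs named vector (class -> cutoff); defaults to
#'   [default_class_cutoffs()].
#' @param high_quality optional logical prerequisite per variant.
#' @return Logical pass/fail vector.
#' @export
apply_class_cutoffs <- function(variants, cutoffs = default_class_cutoffs(),
                                high_quality = NULL) {
  cut <- cutoffs[variants$class]
  if (anyNA(cut))
    stop("no cutoff configured for class(es): ",
         paste(unique(variants$class[is.na(cut)]), collapse = ", "))
  pass <- variants$call_rate > cut
  if (!is.null(high_quality)) pass <- pass & high_quality
  pass
}
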