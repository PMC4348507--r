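#' Marker map
#'
#' Ordered table of biallelic markers. Within a chromosome both base-pair
#' and centimorgan positions must be strictly increasing. When no genetic
#' map is available, cM is imputed at 1 cM/Mb (the genome-wide average),
#' with a message.
#'
#' @param chrom integer chromosome (1-22).
#' @param bp 1-based physical position.
#' @param cM genetic position; `NULL` to impute from bp.
#' @param ref,alt alleles.
#' @param id marker identifiers.
#' @return A `data.frame` of class `MarkerMap` sorted by (chrom, bp).
#' @export
marker_map <- function(chrom, bp, cM = NULL, ref = "A", alt = "G", id = NULL) {
  n <- length(bp)
  if (is.null(cM)) {
    message("no genetic map supplied; imputing cM as bp * 1e-6 (1 cM/Mb)")
    cM <- bp * 1e-6
  }
  if (is.null(id)) id <- sprintf("m%d", seq_len(n))
  map <- data.frame(chrom = as.integer(rep_len(chrom, n)), id = id,
                    bp = as.numeric(bp), cM = as.numeric(cM),
                    ref = rep_len(ref, n), alt = rep_len(alt, n),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (any(diff(sub$bp) <= 0) || any(diff(sub$cM) <= 0))
      stop("bp and cM must be strictly increasing within chromosome ", ch)
  }
  class(map) <- c("MarkerMap", "data.frame")
  map
}

# 1-based half-open column ranges [start, end) of each chromosome.
chrom_ranges <- function(map) {
  r <- rle(map$chrom)
  end <- cumsum(r$lengths)
  data.frame(chrom = r$values, start = end - r$lengths + 1L, end = end + 1L)
}

#' Genotype matrix
#'
#' Samples-by-markers matrix of alt-allele counts in `{0, 1, 2, NA}`.
#'
#' @param calls integer matrix, samples in rows, markers in columns.
#' @param samples character vector of sample ids.
#' @param map a [marker_map()].
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(calls, samples, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == length(samples), ncol(calls) == nrow(map))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be in {0, 1, 2, NA}")
  dimnames(calls) <- list(samples, map$id)
  structure(list(samples = as.character(samples), map = map, calls = calls),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers (%d chromosome(s)), %.2f%% missing\n",
              length(x$samples), nrow(x$map), length(unique(x$map$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read genotypes from VCF or PED/MAP
#'
#' VCF input is parsed with the vcfR package; only biallelic SNV-style
#' records are kept, and the number of excluded multiallelic sites is
#' reported with a warning. PED/MAP input follows the usual PLINK text
#' layout (`fid iid father mother sex pheno` then two allele columns per
#' marker).
#'
#' @param path input file (`.vcf` or the `.ped` of a `.ped`/`.map` pair).
#' @param format `"auto"`, `"vcf"` or `"pedmap"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "pedmap")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "pedmap"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_pedmap(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    warning(sum(multi), " multiallelic site(s) excluded")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix))[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  samples <- colnames(v@gt)[-1]
  sep <- gsub("[01.]", "", substr(gt, 1, 3))
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  calls <- a1 + a2
  dim(calls) <- dim(gt)
  map <- marker_map(chrom = suppressWarnings(as.integer(fix[, "CHROM"])),
                    bp = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"], id = fix[, "ID"])
  ord <- order(suppressWarnings(as.integer(fix[, "CHROM"])), as.numeric(fix[, "POS"]))
  genotype_matrix(t(calls[ord, , drop = FALSE]), samples, map)
}

read_genotypes_pedmap <- function(path) {
  ped_path <- sub("\\.map$", ".ped", path)
  if (!grepl("\\.ped$", ped_path)) ped_path <- paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  maptab <- read.table(map_path, colClasses = "character")
  m <- nrow(maptab)
  tab <- read.table(ped_path, colClasses = "character")
  if (ncol(tab) != 6 + 2 * m) stop("malformed PED file: column count")
  samples <- tab[[2]]
  # allele pairs coded 1/2 (or A/B); 0 = missing
  calls <- matrix(NA_integer_, length(samples), m)
  for (j in seq_len(m)) {
    a1 <- tab[[6 + 2 * j - 1]]
    a2 <- tab[[6 + 2 * j]]
    g <- (a1 == "2") + (a2 == "2")
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    calls[, j] <- g
  }
  cM <- as.numeric(maptab[[3]])
  map <- marker_map(chrom = as.integer(maptab[[1]]), bp = as.numeric(maptab[[4]]),
                    cM = if (all(cM == 0)) NULL else cM, id = maptab[[2]])
  genotype_matrix(calls, samples, map)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test conditional on the allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("all-zero genotype counts")
  nA <- 2L * nAA + nAa                       # minor or major; symmetric below
  rare <- min(nA, 2L * n - nA)
  het_obs <- nAa
  hets <- seq.int(rare %% 2L, rare, by = 2L) # feasible heterozygote counts
  # log-probabilities of each het count given allele counts (Levene)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) -
      lgamma(hom_common + 1) + h * log(2)
  }, 0.0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-12)])
}

# 3 x 3 x 3 lookup of Mendelian validity for complete trios, plus marginal
# tables for one missing member, built by enumerating transmissions.
mendel_tables <- function() {
  valid <- array(FALSE, c(3, 3, 3))
  for (f in 0:2) for (m in 0:2) for (c in 0:2) {
    fa <- unique(c(if (f >= 1) 1L else NULL, if (f <= 1) 0L else NULL))
    ma <- unique(c(if (m >= 1) 1L else NULL, if (m <= 1) 0L else NULL))
    ok <- any(outer(fa, ma, "+") == c)
    valid[f + 1, m + 1, c + 1] <- ok
  }
  valid
}
.mendel_valid <- mendel_tables()

#' Mendelian error counts per marker
#'
#' Counts, for each marker, the trios (both parents and child genotyped in
#' the pedigree) whose genotype triple is impossible under Mendelian
#' transmission. A missing genotype never counts as an error: a triple with
#' missing members is an error only if no completion of the missing
#' genotypes is Mendelian-consistent.
#'
#' @param G a [genotype_matrix()].
#' @param ped a [pedigree()]; trios are all children with both parents
#'   among `G`'s samples.
#' @return Integer vector of error counts, one per marker.
#' @export
mendelian_error_count <- function(G, ped) {
  trios <- trio_index(G, ped)
  m <- ncol(G$calls)
  if (nrow(trios) == 0) return(integer(m))
  errs <- integer(m)
  Fg <- G$calls[trios$father, , drop = FALSE]
  Mg <- G$calls[trios$mother, , drop = FALSE]
  Cg <- G$calls[trios$child, , drop = FALSE]
  for (t in seq_len(nrow(trios))) {
    errs <- errs + !trio_consistent(Fg[t, ], Mg[t, ], Cg[t, ])
  }
  errs
}

# vectorized over markers; missing handled by checking all completions
trio_consistent <- function(f, m, c) {
  n <- length(f)
  ok <- logical(n)
  for (i in seq_len(n)) {
    fs <- if (is.na(f[i])) 0:2 else f[i]
    ms <- if (is.na(m[i])) 0:2 else m[i]
    cs <- if (is.na(c[i])) 0:2 else c[i]
    ok[i] <- any(.mendel_valid[fs + 1, ms + 1, cs + 1])
  }
  ok
}

trio_index <- function(G, ped) {
  idx <- match(ped$id, G$samples)
  child <- which(!is.na(idx) & !is.na(match(ped$father, G$samples)) &
                   !is.na(match(ped$mother, G$samples)))
  data.frame(child = idx[child],
             father = match(ped$father[child], G$samples),
             mother = match(ped$mother[child], G$samples))
}

#' Framework marker quality control
#'
#' Removes markers with five or more Mendelian errors, an exact
#' Hardy-Weinberg p-value below 0.001, or a call rate below 95%; the
#' survivors are then restricted to minor allele frequency of at least 5%.
#' Samples with call rate at or below 95% are flagged (not removed). The
#' per-marker report records which rule fired.
#'
#' @param G a [genotype_matrix()].
#' @param ped a [pedigree()] (for Mendelian checks).
#' @param max_mendel markers with at least this many Mendelian errors are
#'   removed (default 5).
#' @param hwe_cut remove when HWE p < this (default 1e-3).
#' @param min_call_rate remove when marker call rate < this (default 0.95).
#' @param min_maf retain only MAF >= this (default 0.05). MAF is computed
#'   over all genotyped samples.
#' @return List with `genotypes` (filtered [genotype_matrix()]), `report`
#'   (per input marker: statistics and the rule that removed it, if any)
#'   and `flagged_samples`.
#' @export
framework_qc <- function(G, ped, max_mendel = 5L, hwe_cut = 1e-3,
                         min_call_rate = 0.95, min_maf = 0.05) {
  calls <- G$calls
  m <- ncol(calls)
  call_rate <- colMeans(!is.na(calls))
  nAA <- colSums(calls == 0L, na.rm = TRUE)
  nAa <- colSums(calls == 1L, na.rm = TRUE)
  naa <- colSums(calls == 2L, na.rm = TRUE)
  hwe <- vapply(seq_len(m), function(j) {
    if (nAA[j] + nAa[j] + naa[j] == 0) return(1.0)
    hwe_exact_p(nAA[j], nAa[j], naa[j])
  }, 0.0)
  mendel <- mendelian_error_count(G, ped)
  af <- (nAa + 2 * naa) / (2 * pmax(nAA + nAa + naa, 1L))
  maf <- pmin(af, 1 - af)

  rule <- rep("pass", m)
  rule[maf < min_maf] <- "maf"
  rule[call_rate < min_call_rate] <- "call_rate"
  rule[hwe < hwe_cut] <- "hwe"
  rule[mendel >= max_mendel] <- "mendel"
  keep <- rule == "pass"

  report <- data.frame(id = G$map$id, mendel_errors = mendel, hwe_p = hwe,
                       call_rate = call_rate, maf = maf, removed_by = rule,
                       stringsAsFactors = FALSE)
  sample_call <- rowMeans(!is.na(calls))
  flagged <- G$samples[sample_call <= 0.95]

  map2 <- G$map[keep, , drop = FALSE]
  rownames(map2) <- NULL
  class(map2) <- class(G$map)
  list(genotypes = genotype_matrix(calls[, keep, drop = FALSE], G$samples, map2),
       report = report, flagged_samples = flagged)
}
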