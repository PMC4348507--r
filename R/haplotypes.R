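#' Haplotype matrix
#'
#' Two haplotype rows per sample (slot 0 then slot 1) by ordered markers,
#' with alleles in `{0, 1, NA}`. Wherever both alleles are non-missing their
#' sum must equal the sample's genotype. The per-sample `po` flag records
#' parental origin of slot 0: `NA` unassigned, `0` slot-0-paternal, `1`
#' slot-0-maternal. For children phased through a genotyped father, slot 0
#' is paternal by construction.
#'
#' @param alleles integer matrix of dimension `2 * n_samples` x markers.
#' @param samples character vector of sample ids.
#' @param map a [marker_map()].
#' @param po integer vector per sample (see above).
#' @return An object of class `HaplotypeMatrix`.
#' @export
haplotype_matrix <- function(alleles, samples, map,
                             po = rep(NA_integer_, length(samples))) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  stopifnot(nrow(alleles) == 2 * length(samples), ncol(alleles) == nrow(map))
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 1L))
    stop("haplotype alleles must be in {0, 1, NA}")
  rownames(alleles) <- paste0(rep(samples, each = 2), c("_0", "_1"))
  structure(list(samples = as.character(samples), map = map,
                 alleles = alleles, po = po),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat(sprintf("HaplotypeMatrix: %d samples x %d markers, %.2f%% alleles unphased/missing\n",
              length(x$samples), nrow(x$map), 100 * mean(is.na(x$alleles))))
  invisible(x)
}

#' Haplotype row index for a sample and slot
#'
#' @param sample_index integer sample position(s).
#' @param slot 0 or 1.
#' @return Row index into the haplotype allele matrix.
#' @export
hap_index <- function(sample_index, slot) 2L * (sample_index - 1L) + slot + 1L

# inverse: sample position and slot of haplotype rows
hap_sample <- function(hap) (hap + 1L) %/% 2L
hap_slot <- function(hap) (hap - 1L) %% 2L

# empty (all-NA) haplotypes for a genotype matrix
empty_haplotypes <- function(G) {
  haplotype_matrix(matrix(NA_integer_, 2 * length(G$samples), ncol(G$calls)),
                   G$samples, G$map)
}

# verify hap sums reconcile with genotypes; used as a stage invariant
check_haplotypes <- function(H, G) {
  n <- length(H$samples)
  a0 <- H$alleles[hap_index(seq_len(n), 0L), , drop = FALSE]
  a1 <- H$alleles[hap_index(seq_len(n), 1L), , drop = FALSE]
  s <- a0 + a1
  bad <- !is.na(s) & !is.na(G$calls) & s != G$calls
  if (any(bad)) stop("haplotype/genotype inconsistency at ", sum(bad), " site(s)")
  invisible(TRUE)
}

#' Write a phased reference panel in HAPS/SAMPLE format
#'
#' One marker per row: `chrom id bp ref alt` followed by two 0/1 allele
#' columns per sample. Any unphased (missing) allele among the exported
#' samples is an error, naming the first offending site.
#'
#' @param H a [haplotype_matrix()].
#' @param samples sample ids to export (must be fully phased).
#' @param prefix output path prefix; writes `<prefix>.haps` and
#'   `<prefix>.sample`.
#' @return Invisibly, the two file paths.
#' @export
write_reference_panel <- function(H, samples, prefix) {
  idx <- match(samples, H$samples)
  if (anyNA(idx)) stop("unknown sample(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  rows <- as.vector(rbind(hap_index(idx, 0L), hap_index(idx, 1L)))
  A <- H$alleles[rows, , drop = FALSE]
  if (anyNA(A)) {
    miss <- which(colSums(is.na(A)) > 0)[1]
    stop("unphased allele(s) in exported samples at marker ", H$map$id[miss])
  }
  haps_path <- paste0(prefix, ".haps")
  sample_path <- paste0(prefix, ".sample")
  tab <- cbind(H$map$chrom, H$map$id, H$map$bp, H$map$ref, H$map$alt, t(A))
  write.table(tab, haps_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  sm <- rbind(c("ID_1", "ID_2", "missing"), c("0", "0", "0"),
              cbind(samples, samples, "0"))
  write.table(sm, sample_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(haps_path, sample_path))
}

#' Read a HAPS/SAMPLE reference panel
#'
#' Inverse of [write_reference_panel()].
#'
#' @param prefix path prefix used when writing.
#' @return A [haplotype_matrix()].
#' @export
read_reference_panel <- function(prefix) {
  tab <- read.table(paste0(prefix, ".haps"), colClasses = "character")
  sm <- read.table(paste0(prefix, ".sample"), header = TRUE,
                   colClasses = "character")[-1, , drop = FALSE]
  samples <- sm[[1]]
  map <- marker_map(chrom = as.integer(tab[[1]]), bp = as.numeric(tab[[3]]),
                    ref = tab[[4]], alt = tab[[5]], id = tab[[2]])
  A <- t(as.matrix(tab[, -(1:5), drop = FALSE]))
  storage.mode(A) <- "integer"
  haplotype_matrix(A, samples, map)
}

#' Write phased genotypes as VCF
#'
#' Phased sites use the `|` separator; sites where either allele is
#' unassigned are written unphased (`/`) from the genotype, or `./.` when
#' the genotype is missing.
#'
#' @param H a [haplotype_matrix()].
#' @param G the matching [genotype_matrix()] (for unphased sites).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(H, G, path) {
  n <- length(H$samples)
  m <- nrow(H$map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", H$samples), collapse = "\t")), con)
  a0 <- H$alleles[hap_index(seq_len(n), 0L), , drop = FALSE]
  a1 <- H$alleles[hap_index(seq_len(n), 1L), , drop = FALSE]
  unphased_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(m)) {
    phased <- !is.na(a0[, j]) & !is.na(a1[, j])
    g <- G$calls[, j]
    gt <- rep("./.", n)
    gt[!is.na(g)] <- unphased_code[g[!is.na(g)] + 1L]
    gt[phased] <- paste0(a0[phased, j], "|", a1[phased, j])
    writeLines(paste(c(H$map$chrom[j], H$map$bp[j], H$map$id[j], H$map$ref[j],
                       H$map$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
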