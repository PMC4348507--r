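#' HMM parameters for pairwise IBD detection
#'
#' @param phi kinship coefficient of the pair, the stationary prior of the
#'   IBD state (clipped internally to \[1e-4, 1 - 1e-4\]).
#' @param lambda transition rate per cM; defaults to
#'   [lambda_from_kinship()]`(phi)`.
#' @param eps per-allele genotyping error probability in (0, 0.5).
#' @param freq per-marker alt allele frequencies.
#' @return A list of class `HMMParams`.
#' @export
hmm_params <- function(phi, lambda = NULL, eps = 0.005, freq) {
  if (is.null(lambda)) lambda <- lambda_from_kinship(phi)
  stopifnot(phi >= 0, phi <= 0.5 + 1e-9, lambda > 0, eps > 0, eps < 0.5)
  structure(list(phi = phi, lambda = lambda, eps = eps, freq = freq),
            class = "HMMParams")
}

#' Default transition rate from kinship
#'
#' The expected IBD tract length shrinks with the number of meioses
#' separating a pair. We take `g = max(1, round(-log2(2 * phi)))` as an
#' effective meiosis count and set `lambda = g / 100` per cM, i.e. an
#' expected tract of `100 / g` cM.
#'
#' @param phi kinship coefficient.
#' @return Transition rate per cM.
#' @export
lambda_from_kinship <- function(phi) {
  phi <- pmin(pmax(phi, 1e-4), 0.4999)
  g <- pmax(1, round(-log2(2 * phi)))
  g / 100
}

#' Posterior probability of IBD along a haplotype pair
#'
#' Forward-backward posterior of the IBD state of a two-state HMM (IBD /
#' not IBD) over one chromosome. See [hmm_params()] for the model: the
#' stationary prior is the pair's kinship, transitions follow a
#' continuous-time two-state chain over genetic distance, and emissions
#' depend on whether the two alleles match (missing alleles are
#' uninformative).
#'
#' @param hapA,hapB equal-length allele vectors in `{0, 1, NA}` on a single
#'   chromosome.
#' @param map a [marker_map()] restricted to that chromosome (its `cM`
#'   column is used).
#' @param params an [hmm_params()] object.
#' @return Numeric vector of per-marker posteriors in \[0, 1\].
#' @export
hmm_posterior <- function(hapA, hapB, map, params) {
  if (length(hapA) != length(hapB))
    stop("haplotype vectors must have equal length")
  if (length(unique(map$chrom)) > 1)
    stop("hmm_posterior expects markers from a single chromosome")
  if (any(diff(map$cM) <= 0)) stop("cM positions must be strictly increasing")
  freq <- rep_len(params$freq, length(hapA))
  .fb_pair_posterior(as.integer(hapA), as.integer(hapB), as.numeric(map$cM),
                     as.numeric(freq), params$phi, params$lambda, params$eps)
}

#' Extract IBD segments from a posterior track
#'
#' Maximal runs of consecutive markers with posterior at or above
#' `threshold`; runs shorter than `min_markers` are discarded. Intervals
#' are half-open marker index ranges `[start, end)`.
#'
#' @param posterior per-marker IBD posteriors.
#' @param map the matching [marker_map()] (single chromosome).
#' @param threshold posterior cutoff (default 0.5).
#' @param min_markers minimum run length (default 10).
#' @return `data.frame` with `start`, `end`, `start_bp`, `end_bp`,
#'   `mean_posterior`.
#' @export
extract_segments <- function(posterior, map, threshold = 0.5,
                             min_markers = 10L) {
  stopifnot(all(posterior >= 0 & posterior <= 1))
  r <- rle(posterior >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_markers
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(start = starts, end = ends + 1L,
             start_bp = map$bp[starts], end_bp = map$bp[ends],
             mean_posterior = vapply(seq_along(starts), function(i)
               mean(posterior[starts[i]:ends[i]]), 0.0))
}

#' Number of haplotype pairs scanned for a cohort
#'
#' With two haplotypes per sample and within-individual pairs included,
#' `choose(2n, 2)` pairs are enumerated.
#'
#' @param n_samples number of diploid samples.
#' @param include_self include within-individual haplotype pairs
#'   (homozygosity-by-descent; default `TRUE`).
#' @return Pair count.
#' @export
n_haplotype_pairs <- function(n_samples, include_self = TRUE) {
  h <- 2 * as.numeric(n_samples)
  choose(h, 2) - if (include_self) 0 else n_samples
}

# P x 2 matrix of canonical (a < b) haplotype row pairs
haplotype_pairs <- function(n_samples, include_self = TRUE) {
  h <- 2L * n_samples
  a <- rep.int(seq_len(h - 1L), times = (h - 1L):1L)
  b <- sequence((h - 1L):1L) + a
  keep <- if (include_self) rep(TRUE, length(a)) else
    !(hap_sample(a) == hap_sample(b))
  cbind(a = a[keep], b = b[keep])
}

#' IBD segment store
#'
#' Canonicalized, de-duplicated table of IBD segments between haplotype
#' pairs, indexed by chromosome.
#'
#' @param segments `data.frame` with columns `hap_a`, `hap_b` (haplotype row
#'   indices), `chrom`, `start`, `end` (half-open global marker indices),
#'   `start_bp`, `end_bp`, `mean_posterior`.
#' @param samples sample ids (haplotype row `2i-1`/`2i` belong to sample `i`).
#' @param map the [marker_map()] the marker indices refer to.
#' @return An object of class `IBDSegmentStore`.
#' @export
segment_store <- function(segments, samples, map) {
  swap <- segments$hap_a > segments$hap_b
  if (any(swap)) {
    tmp <- segments$hap_a[swap]
    segments$hap_a[swap] <- segments$hap_b[swap]
    segments$hap_b[swap] <- tmp
  }
  key <- paste(segments$hap_a, segments$hap_b, segments$start, segments$end)
  segments <- segments[!duplicated(key), , drop = FALSE]
  segments <- segments[order(segments$chrom, segments$hap_a, segments$hap_b,
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  index <- new.env(parent = emptyenv())
  structure(list(segments = segments, samples = as.character(samples),
                 map = map, n_hap = 2L * length(samples), .index = index),
            class = "IBDSegmentStore")
}

#' @export
print.IBDSegmentStore <- function(x, ...) {
  cat(sprintf("IBDSegmentStore: %d segments over %d haplotypes (%d samples)\n",
              nrow(x$segments), x$n_hap, length(x$samples)))
  invisible(x)
}

#' Detect IBD segments between all haplotype pairs
#'
#' Runs the two-state HMM over every pair of haplotypes (within-individual
#' pairs included by default, where the prior becomes the individual's
#' inbreeding coefficient) and extracts segments where the IBD posterior
#' stays at or above `threshold` for at least `min_markers` markers.
#' Per-pair priors come from the pedigree kinship matrix and per-pair
#' transition rates from [lambda_from_kinship()] unless overridden.
#'
#' @param H a [haplotype_matrix()] (missing alleles allowed).
#' @param ped the [pedigree()] (kinship source); all of `H$samples` must be
#'   pedigree members.
#' @param eps per-allele error rate for the emission model.
#' @param threshold,min_markers segment extraction parameters.
#' @param include_self scan within-individual haplotype pairs too.
#' @param pairs optional P x 2 matrix of haplotype row pairs to restrict
#'   the scan.
#' @param freq optional per-marker alt frequencies; estimated from `H`
#'   when omitted.
#' @param lambda optional per-pair transition rates.
#' @return An [segment_store()] (`IBDSegmentStore`); the number of pairs
#'   scanned is recorded in its `n_pairs` attribute.
#' @export
pairwise_ibd <- function(H, ped, eps = 0.005, threshold = 0.5,
                         min_markers = 10L, include_self = TRUE,
                         pairs = NULL, freq = NULL, lambda = NULL) {
  n <- length(H$samples)
  if (is.null(pairs)) pairs <- haplotype_pairs(n, include_self)
  if (is.null(freq)) freq <- hap_allele_freq(H)
  K <- kinship_matrix(ped)
  sidx <- match(H$samples, ped$id)
  if (anyNA(sidx)) stop("samples absent from pedigree")
  sa <- sidx[hap_sample(pairs[, 1])]
  sb <- sidx[hap_sample(pairs[, 2])]
  phi <- K[cbind(sa, sb)]
  self <- sa == sb
  if (any(self)) phi[self] <- pmax(2 * K[cbind(sa[self], sb[self])] - 1, 0)
  phi <- pmin(pmax(phi, 0), 0.4999)
  if (is.null(lambda)) lambda <- lambda_from_kinship(phi)
  lambda <- rep_len(lambda, nrow(pairs))

  cr <- chrom_ranges(H$map)
  res <- .ibd_scan(H$alleles, pairs, phi, lambda, as.numeric(H$map$cM),
                   as.numeric(freq), eps, threshold, as.integer(min_markers),
                   as.integer(cr$start), as.integer(cr$end))
  seg <- data.frame(hap_a = res$hap_a, hap_b = res$hap_b,
                    chrom = cr$chrom[res$chrom_index],
                    start = res$start, end = res$end,
                    start_bp = H$map$bp[res$start],
                    end_bp = H$map$bp[res$end - 1L],
                    mean_posterior = res$mean_posterior)
  store <- segment_store(seg, H$samples, H$map)
  attr(store, "n_pairs") <- nrow(pairs)
  store
}

# alt allele frequency per marker from non-missing haplotype alleles,
# clipped away from 0/1 for emission stability
hap_allele_freq <- function(H, clip = 0.01) {
  f <- colMeans(H$alleles, na.rm = TRUE)
  f[is.nan(f)] <- 0.5
  pmin(pmax(f, clip), 1 - clip)
}

# segments of one haplotype pair (canonical order applied); rows are
# hash-indexed by pair on first use
pair_segments <- function(store, hap_a, hap_b) {
  a <- min(hap_a, hap_b); b <- max(hap_a, hap_b)
  s <- store$segments
  ix <- store$.index
  if (!is.null(ix)) {
    if (is.null(ix$rows))
      ix$rows <- split(seq_len(nrow(s)), paste(s$hap_a, s$hap_b))
    return(s[ix$rows[[paste(a, b)]], , drop = FALSE])
  }
  s[s$hap_a == a & s$hap_b == b, , drop = FALSE]
}

#' Fraction of the genome covered by IBD for a sample pair
#'
#' Union (not sum) of the genetic lengths of all segments over any of the
#' four haplotype pairings of the two samples, divided by the total map
#' length.
#'
#' @param store an [segment_store()].
#' @param pair character vector of two sample ids.
#' @param map the [marker_map()] (defaults to the store's).
#' @return Fraction in \[0, 1\].
#' @export
genome_ibd_fraction <- function(store, pair, map = store$map) {
  i <- match(pair[1], store$samples)
  j <- match(pair[2], store$samples)
  if (is.na(i) || is.na(j)) stop("sample pair not present in store")
  haps_i <- hap_index(i, 0:1)
  haps_j <- hap_index(j, 0:1)
  segs <- do.call(rbind, lapply(haps_i, function(a)
    do.call(rbind, lapply(haps_j, function(b) pair_segments(store, a, b)))))
  if (is.null(segs) || nrow(segs) == 0) return(0)
  covered <- 0
  for (ch in unique(segs$chrom)) {
    sub <- segs[segs$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end - 1L))
    covered <- covered +
      sum(map$cM[IRanges::end(ir)] - map$cM[IRanges::start(ir)])
  }
  total <- sum(vapply(split(map$cM, map$chrom), function(x) max(x) - min(x), 0.0))
  min(covered / total, 1)
}

#' IBD2 intervals for a sample pair
#'
#' Regions where the two individuals share both haplotypes: both disjoint
#' haplotype pairings (0-0 with 1-1, or 0-1 with 1-0) are simultaneously
#' IBD. Computed as interval intersections of the pairing-wise segment
#' sets, per chromosome.
#'
#' @param store an [segment_store()].
#' @param pair character vector of two sample ids.
#' @return `data.frame` with `chrom`, `start`, `end` (half-open marker
#'   indices), `start_bp`, `end_bp`.
#' @export
ibd2_segments <- function(store, pair) {
  i <- match(pair[1], store$samples)
  j <- match(pair[2], store$samples)
  if (is.na(i) || is.na(j)) stop("sample pair not present in store")
  empty <- data.frame(chrom = integer(), start = integer(), end = integer(),
                      start_bp = numeric(), end_bp = numeric())
  out <- empty
  for (ch in unique(store$map$chrom)) {
    seg_ir <- function(a, b) {
      s <- pair_segments(store, a, b)
      s <- s[s$chrom == ch, , drop = FALSE]
      IRanges::IRanges(s$start, s$end - 1L)
    }
    p00 <- seg_ir(hap_index(i, 0L), hap_index(j, 0L))
    p11 <- seg_ir(hap_index(i, 1L), hap_index(j, 1L))
    p01 <- seg_ir(hap_index(i, 0L), hap_index(j, 1L))
    p10 <- seg_ir(hap_index(i, 1L), hap_index(j, 0L))
    both <- IRanges::reduce(c(IRanges::intersect(p00, p11),
                              IRanges::intersect(p01, p10)))
    if (length(both) == 0) next
    st <- IRanges::start(both); en <- IRanges::end(both)
    out <- rbind(out, data.frame(chrom = ch, start = st, end = en + 1L,
                                 start_bp = store$map$bp[st],
                                 end_bp = store$map$bp[en]))
  }
  out
}

#' Write / read an IBD segment store as tab-separated text
#'
#' Columns: sample and slot of both haplotypes, chromosome, half-open
#' marker interval, bp span, mean posterior.
#'
#' @param store an [segment_store()].
#' @param path output path.
#' @return `write_segments()`: invisibly, `path`. `read_segments()`: the
#'   segment table.
#' @export
write_segments <- function(store, path) {
  s <- store$segments
  out <- data.frame(
    hapA_sample = store$samples[hap_sample(s$hap_a)],
    hapA_slot = hap_slot(s$hap_a),
    hapB_sample = store$samples[hap_sample(s$hap_b)],
    hapB_slot = hap_slot(s$hap_b),
    chrom = s$chrom, start_marker = s$start, end_marker = s$end,
    start_bp = s$start_bp, end_bp = s$end_bp,
    mean_posterior = s$mean_posterior)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) read.table(path, header = TRUE, sep = "\t")
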