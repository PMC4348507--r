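#' Two-thirds majority vote over alleles
#'
#' Returns the allele carried by at least `frac` (default 2/3) of the
#' votes, or `NA` when no such majority exists (including the empty vote
#' set). A count of exactly two-thirds passes.
#'
#' @param votes integer vector of alleles (0/1), possibly empty.
#' @param frac required majority fraction.
#' @return The winning allele, or `NA_integer_`.
#' @export
majority_allele <- function(votes, frac = 2 / 3) {
  votes <- votes[!is.na(votes)]
  if (!length(votes)) return(NA_integer_)
  n1 <- sum(votes == 1L)
  n0 <- length(votes) - n1
  tol <- 1e-9
  if (n1 / length(votes) >= frac - tol) return(1L)
  if (n0 / length(votes) >= frac - tol) return(0L)
  NA_integer_
}

# nearest indexed framework marker (by bp, ties to the left) for each
# variant position on the same chromosome
anchor_markers <- function(D, chrom, bp) {
  vapply(seq_along(bp), function(i) {
    mk <- D$markers[D$map$chrom[D$markers] == chrom[i]]
    if (!length(mk)) return(NA_integer_)
    d <- abs(D$map$bp[mk] - bp[i])
    mk[which.min(d)]  # which.min takes the first (left) on ties
  }, 1L)
}

#' Impute one variant through the IBD cliques
#'
#' The queue algorithm: homozygous sequenced genotypes are phased and both
#' haplotypes enqueued with their allele (samples in ascending order);
#' popping a haplotype, the alleles of already-assigned sequenced
#' haplotypes in its clique are put to a two-thirds majority vote and the
#' winning allele is assigned to every haplotype of the clique; any
#' heterozygous sequenced sample with one haplotype newly resolved has the
#' other haplotype phased by complement and enqueued. A clique with no
#' majority (or with an assignment conflicting an existing allele) is
#' marked conflicted and all alleles it voted in are withdrawn; alleles
#' propagated onward by complement are kept.
#'
#' @param geno integer vector of the variant's genotypes over the
#'   sequenced samples (names = sample ids).
#' @param membership integer clique membership over all haplotypes at the
#'   variant's anchor marker.
#' @param seq_idx sample positions (into the cohort) of the sequenced
#'   samples.
#' @param frac majority fraction (default 2/3).
#' @return List with `alleles` (per-haplotype 0/1/NA) and `source`
#'   (`"sequenced"`, `"complement"`, `"pedigree"` or `"none"`).
#' @export
impute_variant <- function(geno, membership, seq_idx, frac = 2 / 3) {
  n_hap <- length(membership)
  alleles <- rep(NA_integer_, n_hap)
  source <- rep("none", n_hap)
  voted_by <- rep(NA_integer_, n_hap)   # clique id whose vote assigned it
  conflicted <- integer(0)
  is_seq_hap <- rep(FALSE, n_hap)
  hap0 <- hap_index(seq_idx, 0L); hap1 <- hap_index(seq_idx, 1L)
  is_seq_hap[c(hap0, hap1)] <- TRUE

  queue <- integer(0); q_allele <- integer(0)
  ord <- order(seq_idx)
  for (s in ord) {
    g <- geno[s]
    if (is.na(g) || g == 1L) next
    a <- as.integer(g / 2L)
    for (h in c(hap0[s], hap1[s])) {
      alleles[h] <- a
      source[h] <- "sequenced"
      queue <- c(queue, h); q_allele <- c(q_allele, a)
    }
  }

  head_ <- 1L
  while (head_ <= length(queue)) {
    h <- queue[head_]
    head_ <- head_ + 1L
    cl <- membership[h]
    if (cl %in% conflicted) next
    members <- which(membership == cl)
    votes <- alleles[members[is_seq_hap[members] & !is.na(alleles[members])]]
    win <- majority_allele(votes, frac)
    clash <- !is.na(win) &&
      any(!is.na(alleles[members]) & alleles[members] != win)
    if (is.na(win) || clash) {
      conflicted <- c(conflicted, cl)
      withdrawn <- members[!is.na(voted_by[members]) & voted_by[members] == cl]
      alleles[withdrawn] <- NA_integer_
      source[withdrawn] <- "none"
      next
    }
    newly <- members[is.na(alleles[members])]
    alleles[newly] <- win
    source[newly] <- "pedigree"
    voted_by[newly] <- cl
    # phase heterozygous sequenced samples with one haplotype resolved
    for (s in seq_along(seq_idx)) {
      if (is.na(geno[s]) || geno[s] != 1L) next
      ha <- hap0[s]; hb <- hap1[s]
      for (pair in list(c(ha, hb), c(hb, ha))) {
        if (!is.na(alleles[pair[1]]) && is.na(alleles[pair[2]])) {
          comp <- geno[s] - alleles[pair[1]]
          alleles[pair[2]] <- comp
          source[pair[2]] <- "complement"
          queue <- c(queue, pair[2]); q_allele <- c(q_allele, comp)
        }
      }
    }
  }
  list(alleles = alleles, source = source)
}

#' Impute all sequence variants through the clique dictionary
#'
#' Each variant is imputed independently ([impute_variant()]) at the
#' clique partition of its nearest framework marker, so variant order is
#' irrelevant and results are deterministic.
#'
#' @param variants `data.frame` with at least `chrom` and `bp`.
#' @param D a [build_dictionary()] whose markers cover the variants'
#'   chromosomes.
#' @param seq_geno matrix of sequenced-sample genotypes
#'   (sequenced x variants, rownames = sample ids).
#' @param sequenced sequenced sample ids.
#' @param frac majority fraction.
#' @return An `ImputedPanel`: `alleles` (2n x variants), `source`
#'   (same shape), `variants`, `samples`, `sequenced` and summary `rates`
#'   (see [panel_rates()]).
#' @export
impute_all <- function(variants, D, seq_geno, sequenced, frac = 2 / 3) {
  samples <- D$samples
  seq_idx <- match(sequenced, samples)
  if (anyNA(seq_idx)) stop("sequenced samples absent from dictionary")
  anchors <- anchor_markers(D, variants$chrom, variants$bp)
  nv <- nrow(variants)
  n_hap <- nrow(D$membership)
  alleles <- matrix(NA_integer_, n_hap, nv)
  source <- matrix("none", n_hap, nv)
  for (v in seq_len(nv)) {
    if (is.na(anchors[v])) next
    mem <- D$membership[, match(anchors[v], D$markers)]
    res <- impute_variant(seq_geno[, v], mem, seq_idx, frac)
    alleles[, v] <- res$alleles
    source[, v] <- res$source
  }
  panel <- structure(list(alleles = alleles, source = source,
                          variants = variants, samples = samples,
                          sequenced = sequenced, anchors = anchors),
                     class = "ImputedPanel")
  panel$genotypes <- panel_genotypes(panel)
  panel$geno_source <- matrix(ifelse(is.na(panel$genotypes), "none", "pedigree"),
                              nrow(panel$genotypes), nv)
  panel$rates <- panel_rates(panel, seq_geno)
  panel
}

#' @export
print.ImputedPanel <- function(x, ...) {
  cat(sprintf("ImputedPanel: %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  if (!is.null(x$rates)) print(x$rates)
  invisible(x)
}

#' Imputation panel summary rates
#'
#' Phasing rate: fraction of sequenced heterozygous genotypes whose two
#' haplotypes both received alleles. Allele call rate: fraction of target
#' (non-sequenced) haplotype alleles called. Genotype call rate: fraction
#' of target genotypes with both alleles called.
#'
#' @param panel an `ImputedPanel`.
#' @param seq_geno the sequenced genotype matrix used for imputation.
#' @return One-row `data.frame` with `phasing_rate`, `allele_call_rate`,
#'   `genotype_call_rate`.
#' @export
panel_rates <- function(panel, seq_geno) {
  seq_idx <- match(panel$sequenced, panel$samples)
  tgt_idx <- setdiff(seq_along(panel$samples), seq_idx)
  a0 <- panel$alleles[hap_index(seq_idx, 0L), , drop = FALSE]
  a1 <- panel$alleles[hap_index(seq_idx, 1L), , drop = FALSE]
  het <- !is.na(seq_geno) & seq_geno == 1L
  phasing <- if (any(het)) mean(!is.na(a0[het]) & !is.na(a1[het])) else NA_real_
  t0 <- panel$alleles[hap_index(tgt_idx, 0L), , drop = FALSE]
  t1 <- panel$alleles[hap_index(tgt_idx, 1L), , drop = FALSE]
  allele_rate <- mean(c(!is.na(t0), !is.na(t1)))
  geno_rate <- mean(!is.na(t0) & !is.na(t1))
  data.frame(phasing_rate = phasing, allele_call_rate = allele_rate,
             genotype_call_rate = geno_rate)
}

#' Called genotypes of an imputed panel
#'
#' @param panel an `ImputedPanel`.
#' @return Integer matrix samples x variants; `NA` where either allele is
#'   uncalled.
#' @export
panel_genotypes <- function(panel) {
  n <- length(panel$samples)
  g <- panel$alleles[hap_index(seq_len(n), 0L), , drop = FALSE] +
    panel$alleles[hap_index(seq_len(n), 1L), , drop = FALSE]
  rownames(g) <- panel$samples
  g
}

#' Leave-out cross-validation on framework markers
#'
#' Every `k`-th framework marker is re-imputed from the sequenced subset
#' with all other samples' genotypes masked, and the imputed calls are
#' compared with the observed (masked) genotypes. Heterozygote concordance
#' is computed over genotypes called by both sources and heterozygous in
#' at least one.
#'
#' @param G the framework [genotype_matrix()].
#' @param D a [build_dictionary()] indexing the selected markers.
#' @param sequenced sample ids whose genotypes remain visible.
#' @param k thinning step (default 5).
#' @param maf_bins breaks for the by-MAF summary.
#' @param frac majority fraction.
#' @return List with `overall` (concordance, het concordance, call rate,
#'   markers used) and `by_maf`.
#' @export
cross_validate <- function(G, D, sequenced, k = 5L,
                           maf_bins = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                           frac = 2 / 3) {
  markers <- seq(1L, nrow(G$map), by = k)
  markers <- markers[markers %in% D$markers]
  seq_idx <- match(sequenced, G$samples)
  tgt_idx <- setdiff(seq_along(G$samples), seq_idx)
  n_conc <- n_tot <- 0
  het_conc <- het_tot <- 0
  af <- colMeans(G$calls, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  bin_of <- cut(maf, maf_bins, include.lowest = TRUE)
  bin_conc <- bin_tot <- setNames(numeric(nlevels(bin_of)), levels(bin_of))
  for (s in markers) {
    mem <- D$membership[, match(s, D$markers)]
    res <- impute_variant(G$calls[seq_idx, s], mem, seq_idx, frac)
    g_imp <- res$alleles[hap_index(tgt_idx, 0L)] +
      res$alleles[hap_index(tgt_idx, 1L)]
    g_obs <- G$calls[tgt_idx, s]
    both <- !is.na(g_imp) & !is.na(g_obs)
    n_conc <- n_conc + sum(g_imp[both] == g_obs[both])
    n_tot <- n_tot + sum(both)
    bn <- as.character(bin_of[s])
    if (!is.na(bn)) {
      bin_conc[bn] <- bin_conc[bn] + sum(g_imp[both] == g_obs[both])
      bin_tot[bn] <- bin_tot[bn] + sum(both)
    }
    h <- both & (g_imp == 1L | g_obs == 1L)
    het_conc <- het_conc + sum(g_imp[h] == g_obs[h])
    het_tot <- het_tot + sum(h)
  }
  list(overall = data.frame(
         concordance = n_conc / n_tot,
         het_concordance = if (het_tot) het_conc / het_tot else NA_real_,
         call_rate = n_tot / (length(markers) * length(tgt_idx)),
         n_markers = length(markers)),
       by_maf = data.frame(bin = names(bin_conc),
                           concordance = bin_conc / pmax(bin_tot, 1),
                           n = bin_tot))
}

#' Merge LD-based genotype probabilities into a pedigree-imputed panel
#'
#' LD probabilities are hard-called only when the maximum genotype
#' probability exceeds `prob_cut`. Per variant, the heterozygote
#' concordance between pedigree calls and LD hard calls (over genotypes
#' called by both and heterozygous in at least one) must reach
#' `het_conc_min`, and the variant's MAF must reach `maf_min`; otherwise
#' the variant's LD calls are dropped. Kept LD calls only fill genotypes
#' the pedigree left missing — pedigree calls are never overwritten.
#'
#' @param panel an `ImputedPanel`.
#' @param ld_probs samples x variants list-like array: a 3-column
#'   probability matrix per genotype is supplied as an
#'   `n_samples x n_variants x 3` array (rows sum to 1).
#' @param maf per-variant minor allele frequencies.
#' @param prob_cut hard-call threshold (default 0.99, strict `>`).
#' @param het_conc_min per-variant heterozygote concordance floor
#'   (default 0.99).
#' @param maf_min MAF floor for keeping LD calls (default 0.01).
#' @return The merged `ImputedPanel`; filled genotypes carry source
#'   `"LD"`, and a `ld_report` data.frame is attached.
#' @export
merge_ld_calls <- function(panel, ld_probs, maf, prob_cut = 0.99,
                           het_conc_min = 0.99, maf_min = 0.01) {
  stopifnot(length(dim(ld_probs)) == 3, dim(ld_probs)[3] == 3)
  sums <- apply(ld_probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) stop("LD probability rows must sum to 1")
  n <- length(panel$samples)
  nv <- nrow(panel$variants)
  ped_g <- panel_genotypes(panel)
  pmaxv <- pmax(ld_probs[, , 1], ld_probs[, , 2], ld_probs[, , 3])
  hard <- max.col(matrix(ld_probs, ncol = 3), ties.method = "first") - 1L
  hard <- matrix(hard, n, nv)
  hard[pmaxv <= prob_cut] <- NA_integer_
  report <- data.frame(variant = seq_len(nv), het_concordance = NA_real_,
                       kept = FALSE)
  for (v in seq_len(nv)) {
    both <- !is.na(ped_g[, v]) & !is.na(hard[, v])
    het <- both & (ped_g[, v] == 1L | hard[, v] == 1L)
    hc <- if (any(het)) mean(ped_g[het, v] == hard[het, v]) else NA_real_
    report$het_concordance[v] <- hc
    keep <- (!any(het) || hc >= het_conc_min) && maf[v] >= maf_min
    report$kept[v] <- keep
    if (!keep) next
    fill <- is.na(ped_g[, v]) & !is.na(hard[, v])
    for (i in which(fill)) {
      h0 <- hap_index(i, 0L); h1 <- hap_index(i, 1L)
      g <- hard[i, v]
      panel$genotypes[i, v] <- g
      panel$geno_source[i, v] <- "LD"
      if (g != 1L) {
        # homozygotes also resolve the haplotypes; an LD heterozygote is a
        # genotype call without phase
        panel$alleles[h0, v] <- as.integer(g / 2L)
        panel$alleles[h1, v] <- as.integer(g / 2L)
        panel$source[h0, v] <- "LD"
        panel$source[h1, v] <- "LD"
      }
    }
  }
  panel$ld_genotypes <- hard
  panel$ld_report <- report
  panel
}

#' Export paternal/maternal haploid pseudo-sample panels
#'
#' Doubles the cohort: each haplotype becomes a homozygous diploid
#' pseudo-sample (paternal set from slot 0 after parental-origin
#' orientation, maternal from slot 1); unphased sites are exported as
#' missing. Written in HAPS-like text (one marker per row, two allele
#' columns per pseudo-sample, `?` for missing).
#'
#' @param H a [haplotype_matrix()] with `po` flags applied.
#' @param prefix output prefix; writes `<prefix>_paternal.haps` and
#'   `<prefix>_maternal.haps`.
#' @return Invisibly, the two paths.
#' @export
export_haploid_po_panels <- function(H, prefix) {
  n <- length(H$samples)
  po <- ifelse(is.na(H$po), 0L, H$po)
  pat_rows <- hap_index(seq_len(n), po)
  mat_rows <- hap_index(seq_len(n), 1L - po)
  write_one <- function(rows, path) {
    A <- H$alleles[rows, , drop = FALSE]
    X <- ifelse(is.na(A), "?", as.character(A))
    tab <- cbind(H$map$chrom, H$map$id, H$map$bp,
                 t(X)[, rep(seq_len(n), each = 2)])
    write.table(tab, path, quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
  }
  p1 <- write_one(pat_rows, paste0(prefix, "_paternal.haps"))
  p2 <- write_one(mat_rows, paste0(prefix, "_maternal.haps"))
  invisible(c(p1, p2))
}

#' Read a haploid pseudo-sample panel written by
#' [export_haploid_po_panels()]
#'
#' @param path one of the written files.
#' @return Integer matrix samples x markers of the haploid alleles.
#' @export
read_haploid_panel <- function(path) {
  tab <- read.table(path, colClasses = "character")
  X <- as.matrix(tab[, -(1:3), drop = FALSE])
  X[X == "?"] <- NA
  A <- t(matrix(as.integer(X), nrow(X)))
  A[seq(1, nrow(A), by = 2), , drop = FALSE]
}
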