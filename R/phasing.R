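#' Phase homozygous genotypes
#'
#' Every homozygous genotype is trivially phased: both haplotype slots get
#' the same allele.
#'
#' @param H a [haplotype_matrix()].
#' @param G the matching [genotype_matrix()].
#' @return Updated `HaplotypeMatrix`.
#' @export
phase_homozygotes <- function(H, G) {
  n <- length(H$samples)
  for (i in seq_len(n)) {
    g <- G$calls[i, ]
    hom <- !is.na(g) & g != 1L
    h0 <- hap_index(i, 0L); h1 <- hap_index(i, 1L)
    fill0 <- hom & is.na(H$alleles[h0, ])
    fill1 <- hom & is.na(H$alleles[h1, ])
    H$alleles[h0, fill0] <- as.integer(g[fill0] / 2L)
    H$alleles[h1, fill1] <- as.integer(g[fill1] / 2L)
  }
  H
}

#' Mendelian trio phasing within a nuclear family
#'
#' Phases every child site where transmission is logically forced: a
#' homozygous child is phased outright, and a heterozygous child is phased
#' when either genotyped parent is homozygous. When the father is
#' genotyped, the father-derived allele always goes to slot 0 (and the
#' mother-derived allele to slot 1), so non-quasi-founder haplotypes carry
#' parental origin by construction. Mendelian-inconsistent sites are left
#' unphased. No assignment ever contradicts an observed genotype.
#'
#' @param family a `NuclearFamily` from [nuclear_families()].
#' @param G a [genotype_matrix()].
#' @param H a [haplotype_matrix()] to update.
#' @return Updated `HaplotypeMatrix`.
#' @export
phase_by_mendel <- function(family, G, H) {
  fi <- match(family$father, G$samples)
  mi <- match(family$mother, G$samples)
  f <- if (!is.na(fi)) G$calls[fi, ] else rep(NA_integer_, ncol(G$calls))
  m <- if (!is.na(mi)) G$calls[mi, ] else rep(NA_integer_, ncol(G$calls))
  for (child in family$children) {
    ci <- match(child, G$samples)
    if (is.na(ci)) next
    if (is.na(fi) && is.na(mi)) next  # need at least 2 of 3 roles genotyped
    g <- G$calls[ci, ]
    consistent <- trio_consistent(f, m, g)
    h0 <- hap_index(ci, 0L); h1 <- hap_index(ci, 1L)
    unset <- is.na(H$alleles[h0, ]) | is.na(H$alleles[h1, ])
    # homozygous child
    hom <- !is.na(g) & g != 1L & consistent & unset
    H$alleles[h0, hom] <- as.integer(g[hom] / 2L)
    H$alleles[h1, hom] <- as.integer(g[hom] / 2L)
    # heterozygous child, homozygous parent forces the transmission
    het <- !is.na(g) & g == 1L & consistent & unset
    ffo <- het & !is.na(f) & f != 1L
    H$alleles[h0, ffo] <- as.integer(f[ffo] / 2L)
    H$alleles[h1, ffo] <- 1L - as.integer(f[ffo] / 2L)
    mfo <- het & !is.na(m) & m != 1L & !ffo
    H$alleles[h1, mfo] <- as.integer(m[mfo] / 2L)
    H$alleles[h0, mfo] <- 1L - as.integer(m[mfo] / 2L)
    if (!is.na(fi) && !is.na(mi)) H$po[ci] <- 0L  # slot 0 paternal
  }
  H
}

# Viterbi assignment of k sibling tracks to two parental haplotypes.
# `obs_eq` is a pairs x markers matrix: 1 when the pair looks identical
# (same transmitted allele / observed IBD), 0 when it looks different, NA
# when unobserved; pairs are ordered as combn(k, 2). Emission cost counts
# pairs whose observed state disagrees with the assignment; transitions
# pay `switch_cost` per track that changes haplotype. Track 1 is pinned to
# haplotype 0 (labels are arbitrary up to complement). Returns the k x M
# assignment path.
side_viterbi <- function(obs_eq, k, switch_cost = max(3, k - 1)) {
  M <- ncol(obs_eq)
  if (k == 1) return(matrix(0L, 1, M))
  if (k > 11) stop("haplotype side assignment supports at most 11 tracks")
  states <- as.matrix(expand.grid(rep(list(0:1), k)))
  states <- states[states[, 1] == 0, , drop = FALSE]
  S <- nrow(states)
  pr <- utils::combn(k, 2)
  A <- (states[, pr[1, ], drop = FALSE] == states[, pr[2, ], drop = FALSE]) * 1
  Smat <- obs_eq == 1; Smat[is.na(Smat)] <- FALSE
  Dmat <- obs_eq == 0; Dmat[is.na(Dmat)] <- FALSE
  E <- A %*% Dmat + (1 - A) %*% Smat  # S x M mismatch counts
  trans <- switch_cost * as.matrix(stats::dist(states, method = "manhattan"))
  cost <- E[, 1]
  back <- matrix(NA_integer_, S, M)
  for (t in seq_len(M)[-1]) {
    step <- cost + trans
    j <- max.col(-t(step), ties.method = "first")
    cost <- step[cbind(j, seq_len(S))] + E[, t]
    back[, t] <- j
  }
  path_states <- integer(M)
  path_states[M] <- which.min(cost)
  for (t in M:2) path_states[t - 1L] <- back[path_states[t], t]
  t(states[path_states, , drop = FALSE])
}

# Reconstruct one genotyped parent's haplotypes from the alleles they
# transmitted to their children, minimizing recombinations (side_viterbi
# over the children's transmitted-allele agreement), and use the
# reconstruction to resolve child sites that single-trio rules cannot
# (e.g. triple-heterozygous sites). `slot` is the child slot fed by this
# parent (0 = father, 1 = mother). Runs per chromosome.
phase_parent_from_children <- function(parent, slot, family, G, H) {
  pi_ <- match(parent, G$samples)
  if (is.na(pi_)) return(H)
  kids <- match(family$children, G$samples)
  kids <- kids[!is.na(kids)]
  if (length(kids) == 0) return(H)
  gP <- G$calls[pi_, ]
  cr <- chrom_ranges(G$map)
  ph0 <- hap_index(pi_, 0L); ph1 <- hap_index(pi_, 1L)

  for (r in seq_len(nrow(cr))) {
    cols <- cr$start[r]:(cr$end[r] - 1L)
    V <- H$alleles[hap_index(kids, slot), cols, drop = FALSE]
    J <- which(!is.na(gP[cols]) & gP[cols] == 1L & colSums(!is.na(V)) > 0)
    if (length(J) < 2) next
    Vj <- V[, J, drop = FALSE]
    k <- nrow(Vj)
    if (k > 1) {
      pr <- utils::combn(k, 2)
      obs_eq <- (Vj[pr[1, ], , drop = FALSE] == Vj[pr[2, ], , drop = FALSE]) * 1
      z <- side_viterbi(obs_eq, k)
    } else {
      z <- matrix(0L, 1, length(J))
    }
    # content of parent haplotype "A" by per-marker majority over children
    implied <- ifelse(z == 0L, Vj, 1L - Vj)
    votes1 <- colSums(implied == 1L, na.rm = TRUE)
    votes0 <- colSums(implied == 0L, na.rm = TRUE)
    h <- as.integer(votes1 >= votes0)
    # align hap A to the parent's existing slots (majority over phased hets)
    e0 <- H$alleles[ph0, cols][J]
    agree0 <- sum(e0 == h, na.rm = TRUE)
    agree1 <- sum(e0 == 1L - h, na.rm = TRUE)
    sA <- if (agree1 > agree0) 1L else 0L
    hA <- if (sA == 0L) h else 1L - h  # allele of parent's slot 0 at J
    fill <- is.na(H$alleles[ph0, cols][J])
    H$alleles[ph0, cols[J[fill]]] <- hA[fill]
    H$alleles[ph1, cols[J[fill]]] <- 1L - hA[fill]

    # fill children's unresolved sites from their assigned parental track
    for (ci in seq_along(kids)) {
      ch <- hap_index(kids[ci], slot)
      can <- which(is.na(H$alleles[ch, cols][J]))
      if (!length(can)) next
      allele <- ifelse(z[ci, can] == 0L, h[can], 1L - h[can])
      sites <- cols[J[can]]
      H$alleles[ch, sites] <- allele
      other <- hap_index(kids[ci], 1L - slot)
      gg <- G$calls[kids[ci], sites]
      ok <- !is.na(gg) & (gg - allele) %in% c(0L, 1L) &
        is.na(H$alleles[other, sites])
      H$alleles[other, sites[ok]] <- gg[ok] - allele[ok]
    }
  }
  H
}

# alt allele frequency per marker from genotype calls, clipped away from
# 0/1 for emission stability; preferred over haplotype-based estimates,
# which collapse to 0/1 at homozygote-only sites in small cohorts
genotype_allele_freq <- function(G, clip = 0.01) {
  f <- colMeans(G$calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0.5
  pmin(pmax(f, clip), 1 - clip)
}

# internal: run the segment scan over explicit haplotype pairs with
# explicit per-pair priors
scan_segments <- function(H, pairs, phi, eps = 0.005, threshold = 0.5,
                          min_markers = 10L, freq = NULL) {
  if (is.null(freq)) freq <- hap_allele_freq(H)
  freq <- rep_len(freq, ncol(H$alleles))
  phi <- pmin(pmax(rep_len(phi, nrow(pairs)), 0), 0.4999)
  lambda <- lambda_from_kinship(phi)
  cr <- chrom_ranges(H$map)
  res <- .ibd_scan(H$alleles, pairs, phi, lambda, as.numeric(H$map$cM),
                   as.numeric(freq), eps, threshold, as.integer(min_markers),
                   as.integer(cr$start), as.integer(cr$end))
  data.frame(hap_a = res$hap_a, hap_b = res$hap_b,
             chrom = cr$chrom[res$chrom_index], start = res$start,
             end = res$end, mean_posterior = res$mean_posterior)
}

# Phase a proband's unphased heterozygous sites by copying alleles from
# candidate haplotypes across detected IBD segments. Votes are converted
# to slot-0 alleles; at each site the vote with the highest segment
# posterior wins.
phase_from_candidates <- function(H, G, proband_idx, segs) {
  if (nrow(segs) == 0) return(H)
  m <- ncol(H$alleles)
  h0 <- hap_index(proband_idx, 0L); h1 <- hap_index(proband_idx, 1L)
  g <- G$calls[proband_idx, ]
  best_w <- rep(-1, m)
  best_a0 <- rep(NA_integer_, m)
  segs <- segs[order(-segs$mean_posterior), , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    prob_hap <- if (hap_sample(segs$hap_a[k]) == proband_idx) segs$hap_a[k] else segs$hap_b[k]
    src_hap <- if (prob_hap == segs$hap_a[k]) segs$hap_b[k] else segs$hap_a[k]
    slot <- hap_slot(prob_hap)
    rng <- segs$start[k]:(segs$end[k] - 1L)
    src <- H$alleles[src_hap, rng]
    cand <- !is.na(src) & !is.na(g[rng]) & g[rng] == 1L &
      is.na(H$alleles[h0, rng]) & segs$mean_posterior[k] > best_w[rng]
    if (!any(cand)) next
    sites <- rng[cand]
    a0 <- if (slot == 0L) src[cand] else 1L - src[cand]
    best_w[sites] <- segs$mean_posterior[k]
    best_a0[sites] <- a0
  }
  sites <- which(!is.na(best_a0))
  H$alleles[h0, sites] <- best_a0[sites]
  H$alleles[h1, sites] <- 1L - best_a0[sites]
  H
}

#' Phase siblings against a phased proband template
#'
#' Infers IBD sharing between each sibling's haplotypes and the proband's
#' two haplotypes with the pairwise HMM, then phases heterozygous sibling
#' sites inside shared segments by copying the proband allele onto the
#' shared slot (the complementary allele goes to the other slot). Conflicts
#' among overlapping segments are resolved by the higher posterior.
#'
#' @param family a `NuclearFamily`.
#' @param H a [haplotype_matrix()]; the proband should be substantially
#'   phased.
#' @param G the matching [genotype_matrix()].
#' @param proband id of the template child; defaults to the most completely
#'   phased child.
#' @param eps,threshold,min_markers HMM and segment parameters.
#' @param freq per-marker alt allele frequencies; estimated from the
#'   genotypes when omitted.
#' @return Updated `HaplotypeMatrix`.
#' @export
phase_siblings_by_template <- function(family, H, G, proband = NULL,
                                       eps = 0.005, threshold = 0.5,
                                       min_markers = 10L, freq = NULL) {
  if (is.null(freq)) freq <- genotype_allele_freq(G)
  kids <- match(family$children, G$samples)
  kids <- kids[!is.na(kids)]
  if (length(kids) < 2) return(H)
  phased_frac <- vapply(kids, function(i)
    mean(!is.na(H$alleles[hap_index(i, 0L), ])), 0.0)
  pidx <- if (is.null(proband)) kids[which.max(phased_frac)] else
    match(proband, G$samples)
  for (sib in setdiff(kids, pidx)) {
    pairs <- as.matrix(expand.grid(hap_index(sib, 0:1), hap_index(pidx, 0:1)))
    segs <- scan_segments(H, pairs, phi = 0.25, eps = eps,
                          threshold = threshold, min_markers = min_markers,
                          freq = freq)
    H <- phase_from_candidates(H, G, sib, segs)
  }
  H
}

#' Phase a proband through surrogate relatives
#'
#' For probands without genotyped parents (or with residual unphased
#' sites), IBD segments between each proband haplotype and the phased
#' haplotypes of non-descendant relatives are detected; an unphased
#' heterozygous site covered by a segment whose candidate allele is known
#' is phased by assigning that allele to the covered slot. Conflicting
#' overlapping segments are resolved by the highest posterior.
#'
#' @param proband sample id.
#' @param H a [haplotype_matrix()].
#' @param G the matching [genotype_matrix()].
#' @param ped the [pedigree()] (supplies kinship priors and the descendant
#'   exclusion).
#' @param eps,threshold,min_markers HMM and segment parameters.
#' @param min_kinship candidates with kinship below this contribute no
#'   usable IBD and are skipped (default 0.05).
#' @param freq per-marker alt allele frequencies; estimated from the
#'   genotypes when omitted.
#' @return Updated `HaplotypeMatrix`.
#' @export
phase_by_surrogate_parents <- function(proband, H, G, ped, eps = 0.005,
                                       threshold = 0.5, min_markers = 10L,
                                       min_kinship = 0.05, freq = NULL) {
  if (is.null(freq)) freq <- genotype_allele_freq(G)
  pidx <- match(proband, H$samples)
  K <- kinship_matrix(ped)
  excl <- c(proband, descendants(ped, proband))
  cand <- setdiff(H$samples, excl)
  phi_s <- K[match(cand, ped$id), match(proband, ped$id)]
  cand <- cand[phi_s >= min_kinship]
  phi_s <- phi_s[phi_s >= min_kinship]
  if (!length(cand)) return(H)
  cidx <- match(cand, H$samples)
  cand_haps <- as.vector(rbind(hap_index(cidx, 0L), hap_index(cidx, 1L)))
  pairs <- cbind(rep(hap_index(pidx, 0:1), each = length(cand_haps)),
                 rep(cand_haps, 2))
  phi <- rep(rep(phi_s, each = 2), 2)
  segs <- scan_segments(H, pairs, phi, eps = eps, threshold = threshold,
                        min_markers = min_markers, freq = freq)
  phase_from_candidates(H, G, pidx, segs)
}

#' Phase a whole cohort through the pedigree
#'
#' Pipeline order: homozygote phasing, Mendelian trio phasing with
#' family-wide parent reconstruction (families processed founders-first),
#' sibling-template phasing, then surrogate-relative phasing for samples
#' with remaining unphased heterozygous sites. No stage ever contradicts a
#' genotype, and the set of phased sites only grows.
#'
#' @param ped a [pedigree()].
#' @param G a quality-controlled [genotype_matrix()].
#' @param eps per-allele error rate for the HMM stages.
#' @param truth optional 2n-by-m matrix of true haplotype alleles for
#'   concordance reporting (see [phase_stats()]).
#' @param surrogate run the surrogate-relative stage (default `TRUE`).
#' @return List with `haplotypes` (a [haplotype_matrix()]) and `stats`
#'   (a `PhaseStats` row, see [phase_stats()]).
#' @export
phase_cohort <- function(ped, G, eps = 0.005, truth = NULL, surrogate = TRUE) {
  H <- empty_haplotypes(G)
  H <- phase_homozygotes(H, G)
  fams <- nuclear_families(ped)
  fams <- Filter(function(f) any(f$children %in% G$samples), fams)
  for (f in fams) {
    H <- phase_by_mendel(f, G, H)
  }
  for (f in fams) {
    if (f$father %in% G$samples)
      H <- phase_parent_from_children(f$father, 0L, f, G, H)
    if (f$mother %in% G$samples)
      H <- phase_parent_from_children(f$mother, 1L, f, G, H)
  }
  check_haplotypes(H, G)
  freq <- genotype_allele_freq(G)
  for (f in fams) {
    H <- phase_siblings_by_template(f, H, G, eps = eps, freq = freq)
  }
  check_haplotypes(H, G)
  if (surrogate) {
    unphased <- vapply(seq_along(H$samples), function(i) {
      g <- G$calls[i, ]
      sum(!is.na(g) & g == 1L & is.na(H$alleles[hap_index(i, 0L), ]))
    }, 0L)
    for (i in order(-unphased)) {
      if (unphased[i] == 0) next
      H <- phase_by_surrogate_parents(H$samples[i], H, G, ped, eps = eps,
                                      freq = freq)
    }
    check_haplotypes(H, G)
  }
  list(haplotypes = H, stats = phase_stats(H, G, truth))
}

#' Phasing quality statistics
#'
#' Fractions are over non-missing framework genotypes. A genotype is
#' unphased when either haplotype allele is still missing. With truth
#' available, phased heterozygous genotypes are compared to the true
#' haplotypes under the better of the two slot orientations per sample and
#' chromosome (quasi-founder slot order is arbitrary until parental-origin
#' assignment); homozygous genotypes are trivially concordant. The three
#' fractions sum to 1 when truth is supplied.
#'
#' @param H a [haplotype_matrix()].
#' @param G the matching [genotype_matrix()].
#' @param truth optional 2n-by-m matrix of true haplotype alleles.
#' @return A one-row `data.frame` with `unphased`, `concordant`,
#'   `discordant` (the latter two `NA` without truth).
#' @export
phase_stats <- function(H, G, truth = NULL) {
  n <- length(H$samples)
  a0 <- H$alleles[hap_index(seq_len(n), 0L), , drop = FALSE]
  a1 <- H$alleles[hap_index(seq_len(n), 1L), , drop = FALSE]
  obs <- !is.na(G$calls)
  phased <- !is.na(a0) & !is.na(a1) & obs
  unphased_frac <- 1 - sum(phased) / sum(obs)
  conc <- disc <- NA_real_
  if (!is.null(truth)) {
    t0 <- truth[hap_index(seq_len(n), 0L), , drop = FALSE]
    t1 <- truth[hap_index(seq_len(n), 1L), , drop = FALSE]
    cr <- chrom_ranges(G$map)
    n_conc <- sum(phased & G$calls != 1L, na.rm = TRUE)  # homozygotes
    n_disc <- 0
    for (i in seq_len(n)) {
      for (r in seq_len(nrow(cr))) {
        cols <- cr$start[r]:(cr$end[r] - 1L)
        het <- phased[i, cols] & !is.na(G$calls[i, cols]) & G$calls[i, cols] == 1L
        if (!any(het)) next
        direct <- sum(a0[i, cols][het] == t0[i, cols][het])
        swapped <- sum(a0[i, cols][het] == t1[i, cols][het])
        good <- max(direct, swapped)
        n_conc <- n_conc + good
        n_disc <- n_disc + sum(het) - good
      }
    }
    conc <- n_conc / sum(obs)
    disc <- n_disc / sum(obs)
  }
  data.frame(unphased = unphased_frac, concordant = conc, discordant = disc)
}
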