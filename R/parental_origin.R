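#' Assign sibling haplotypes to four parental bins
#'
#' Within a nuclear family with at least two children, every child
#' haplotype region descends from one of the four parental haplotypes
#' ("bins"). Regions that are IBD among siblings must share a bin, and the
#' assignment is chosen to minimize the number of bin switches
#' (recombinations) by dynamic programming over the thinned marker grid.
#'
#' Each child has one haplotype from each parent, so the problem decomposes
#' into two sides: child slots are first oriented to a parental side (from
#' the stored parental-origin flag when the parents are genotyped,
#' otherwise by two-coloring the between-sibling IBD graph), and each side
#' is solved by a Viterbi pass over the `2^(k-1)` assignments of the k
#' side-haplotypes to that parent's two bins. Emission cost counts sibling
#' haplotype pairs whose observed IBD state disagrees with the assignment;
#' transitions pay `switch_cost` per haplotype that changes bin.
#'
#' @param family a `NuclearFamily` with >= 2 children.
#' @param H a [haplotype_matrix()].
#' @param store an [segment_store()] covering the children.
#' @param thin use every `thin`-th framework marker (default 5).
#' @param switch_cost recombination penalty per haplotype switch
#'   (default 2).
#' @return List with `markers` (thinned global indices), `bins` (2k x M
#'   matrix of bin labels 1-4; rows ordered child1 slot0, child1 slot1,
#'   child2 slot0, ...), `children`, and `switches` (total bin switches).
#' @export
assign_family_bins <- function(family, H, store, thin = 5L, switch_cost = 2) {
  kids <- match(family$children, H$samples)
  kids <- kids[!is.na(kids)]
  k <- length(kids)
  if (k < 2) stop("bin assignment needs at least 2 genotyped children")
  if (k > 10) stop("bin assignment supports at most 10 children")
  markers <- seq(1L, nrow(H$map), by = thin)
  M <- length(markers)
  haps <- as.vector(rbind(hap_index(kids, 0L), hap_index(kids, 1L)))

  # IBD indicator among the 2k child haplotypes at the thinned markers
  ibd <- array(FALSE, c(2L * k, 2L * k, M))
  cm_weight <- matrix(0, 2L * k, 2L * k)
  for (a in seq_len(2L * k - 1L)) for (b in (a + 1L):(2L * k)) {
    s <- pair_segments(store, haps[a], haps[b])
    if (!nrow(s)) next
    for (r in seq_len(nrow(s))) {
      hit <- markers >= s$start[r] & markers < s$end[r]
      ibd[a, b, hit] <- ibd[b, a, hit] <- TRUE
      cm_weight[a, b] <- cm_weight[b, a] <- cm_weight[a, b] +
        (H$map$cM[s$end[r] - 1L] - H$map$cM[s$start[r]])
    }
  }

  # orient child slots to parental sides
  side <- side_of_slots(H, kids, cm_weight)  # 2k vector in {1, 2}

  bins <- matrix(NA_integer_, 2L * k, M)
  total_switch <- 0L
  for (sd in 1:2) {
    rows <- which(side == sd)
    sub <- ibd[rows, rows, , drop = FALSE]
    v <- bins_viterbi(sub, switch_cost)
    bins[rows, ] <- (sd - 1L) * 2L + 1L + v$path
    total_switch <- total_switch + v$switches
  }
  rn <- paste0(rep(family$children, each = 2), c("_0", "_1"))
  rownames(bins) <- rn
  list(markers = markers, bins = bins, children = family$children,
       switches = total_switch)
}

# Assign each child haplotype to parental side 1 or 2. Slot orientation is
# known for children phased through genotyped parents (slot 0 paternal);
# otherwise IBD edges (same side) are applied strongest-first, skipping
# edges that would conflict.
side_of_slots <- function(H, kids, cm_weight) {
  k <- length(kids)
  side <- rep(NA_integer_, 2L * k)
  known <- !is.na(H$po[kids])
  side[2 * which(known) - 1L] <- 1L + H$po[kids[known]]
  side[2 * which(known)] <- 2L - H$po[kids[known]]
  if (all(known)) return(side)
  if (!any(known)) {
    side[1] <- 1L; side[2] <- 2L
  }
  edges <- which(upper.tri(cm_weight) & cm_weight > 0, arr.ind = TRUE)
  if (nrow(edges)) {
    o <- order(-cm_weight[edges])
    edges <- edges[o, , drop = FALSE]
    for (rep_pass in 1:2) for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      other <- function(x) x + ifelse(x %% 2L == 1L, 1L, -1L)
      if (!is.na(side[a]) && is.na(side[b])) {
        side[b] <- side[a]; side[other(b)] <- 3L - side[a]
      } else if (is.na(side[a]) && !is.na(side[b])) {
        side[a] <- side[b]; side[other(a)] <- 3L - side[b]
      }
    }
  }
  # anything still unknown: default slot order
  miss <- which(is.na(side))
  side[miss] <- ifelse(miss %% 2L == 1L, 1L, 2L)
  side
}

# Viterbi over binary bin assignments of the side-haplotypes (wrapper
# around side_viterbi on the pairwise IBD observations; absence of an
# observed segment is treated as evidence of different bins).
bins_viterbi <- function(ibd_sub, switch_cost) {
  kk <- dim(ibd_sub)[1]
  M <- dim(ibd_sub)[3]
  if (kk == 1) return(list(path = matrix(0L, 1, M), switches = 0L))
  pr <- utils::combn(kk, 2)
  obs_eq <- matrix(0, ncol(pr), M)
  for (p in seq_len(ncol(pr)))
    obs_eq[p, ] <- ibd_sub[pr[1, p], pr[2, p], ] * 1
  path <- side_viterbi(obs_eq, kk, switch_cost)
  list(path = path, switches = sum(abs(diff(t(path))) > 0))
}

#' Orient family bins to parents and measure separation
#'
#' There are three ways to pair the four parental bins into two parents.
#' For each pairing and child, `F1` is the fraction of the child's slot-0
#' track covered by parent A's bins plus the fraction of slot 1 covered by
#' B's bins, and `F2` the swapped sum; the child separation is
#' `max(F1, F2) / (F1 + F2)`. The pairing maximizing the minimum child
#' separation is chosen, and each child's slot order relative to parent A
#' is returned.
#'
#' @param bins result of [assign_family_bins()].
#' @return List with `pairing` (bins of parent A), `separation` (per
#'   child), and `slot0_parent` per child (`"A"` or `"B"`).
#' @export
family_po_orientation <- function(bins) {
  pairings <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  k <- length(bins$children)
  best <- NULL
  for (pA in pairings) {
    sep <- F1s <- F2s <- numeric(k)
    for (c in seq_len(k)) {
      b0 <- bins$bins[2 * c - 1L, ]
      b1 <- bins$bins[2 * c, ]
      F1 <- mean(b0 %in% pA) + mean(!(b1 %in% pA))
      F2 <- mean(!(b0 %in% pA)) + mean(b1 %in% pA)
      F1s[c] <- F1; F2s[c] <- F2
      sep[c] <- if (F1 + F2 == 0) 0.5 else max(F1, F2) / (F1 + F2)
    }
    cand <- list(pairing = pA, separation = sep,
                 slot0_parent = ifelse(F1s >= F2s, "A", "B"),
                 min_sep = min(sep))
    if (is.null(best) || cand$min_sep > best$min_sep) best <- cand
  }
  best[c("pairing", "separation", "slot0_parent")]
}

#' Clique kinship matrix for a quasi-founder at a marker
#'
#' For a quasi-founder C with pedigree-recorded (possibly ungenotyped)
#' parents A and B, `K[p, h]` is the median kinship between parent p and
#' the eligible members of the clique containing C's haplotype slot h:
#' quasi-founders only, excluding C and C's siblings (to minimize bias);
#' an entry with no eligible member is 0.
#'
#' @param C quasi-founder sample id.
#' @param marker marker index present in the dictionary.
#' @param D a [build_dictionary()].
#' @param ped the [pedigree()].
#' @return 2x2 numeric matrix, rows parents (A = father, B = mother),
#'   columns C's slots.
#' @export
po_kinship_matrix <- function(C, marker, D, ped) {
  ci <- match(C, ped$id)
  A <- ped$father[ci]; B <- ped$mother[ci]
  if (is.na(A)) stop("quasi-founder's parents must be present in the pedigree")
  sibs <- ped$id[!is.na(ped$father) & ped$father == A & ped$mother == B]
  qf <- quasi_founders(ped)
  eligible_pool <- setdiff(intersect(qf, D$samples), c(C, sibs))
  K <- kinship_matrix(ped)
  col <- match(marker, D$markers)
  if (is.na(col)) stop("marker not indexed in dictionary")
  mem <- D$membership[, col]
  out <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("slot0", "slot1")))
  cs <- match(C, D$samples)
  for (h in 0:1) {
    cl <- mem[hap_index(cs, h)]
    members <- unique(D$samples[hap_sample(which(mem == cl))])
    members <- intersect(members, eligible_pool)
    if (!length(members)) next
    for (p in 1:2) {
      par_id <- if (p == 1) A else B
      out[p, h + 1L] <- median(K[par_id, members])
    }
  }
  out
}

#' Parental separation measure from a clique kinship matrix
#'
#' `m = (d - o) / (d + o)` where `d` sums the diagonal (father-slot0 +
#' mother-slot1) and `o` the off-diagonal entries; `m` approaches 1 when
#' the diagonal dominates (slot 0 paternal), -1 when the off-diagonal
#' dominates (slots swapped), and is 0 when `d + o = 0`.
#'
#' @param K 2x2 non-negative matrix from [po_kinship_matrix()].
#' @return Value in \[-1, 1\].
#' @export
separation_m <- function(K) {
  d <- K[1, 1] + K[2, 2]
  o <- K[1, 2] + K[2, 1]
  if (d + o == 0) return(0)
  (d - o) / (d + o)
}

#' Assign parental origin from per-marker separation measures
#'
#' Markers with `|m| > informative_cut` are informative; with `n_plus` and
#' `n_minus` counting their signs, `M = max(n_plus, n_minus) / (n_plus +
#' n_minus)`. Orientation is assigned when `M > assign_cut`: a positive
#' majority keeps slot 0 paternal (orientation 0), a negative majority
#' swaps (orientation 1).
#'
#' @param m numeric vector of separation measures along a chromosome.
#' @param informative_cut threshold on `|m|` (default 0.25).
#' @param assign_cut threshold on `M` (default 0.75).
#' @return List with `orientation` (0, 1 or `NA`), `M`, `n_plus`,
#'   `n_minus`.
#' @export
assign_po <- function(m, informative_cut = 0.25, assign_cut = 0.75) {
  m <- m[!is.na(m)]
  inf <- abs(m) > informative_cut
  n_plus <- sum(m[inf] > 0)
  n_minus <- sum(m[inf] < 0)
  if (n_plus + n_minus == 0)
    return(list(orientation = NA_integer_, M = NA_real_, n_plus = 0L,
                n_minus = 0L))
  M <- max(n_plus, n_minus) / (n_plus + n_minus)
  orientation <- if (M > assign_cut) {
    if (n_plus >= n_minus) 0L else 1L
  } else NA_integer_
  list(orientation = orientation, M = M, n_plus = n_plus, n_minus = n_minus)
}

#' Cohort parental-origin assignment
#'
#' Non-quasi-founders inherit slot-0-paternal orientation from Mendelian
#' phasing. For each quasi-founder whose parents are recorded in the
#' pedigree, the separation measure `m` is computed at every indexed
#' marker ([po_kinship_matrix()] + [separation_m()]) and orientation is
#' assigned per chromosome with [assign_po()].
#'
#' @param ped the [pedigree()].
#' @param H a [haplotype_matrix()]; its `po` flags are updated with the
#'   per-sample majority orientation over assigned chromosomes.
#' @param D a [build_dictionary()] built at (typically thinned) framework
#'   markers.
#' @param informative_cut,assign_cut see [assign_po()].
#' @return List with `haplotypes` (updated `H`) and `table` (one row per
#'   quasi-founder chromosome: `sample`, `chrom`, `orientation`, `M`,
#'   `n_plus`, `n_minus`).
#' @export
assign_parental_origin <- function(ped, H, D, informative_cut = 0.25,
                                   assign_cut = 0.75) {
  qf <- intersect(quasi_founders(ped), H$samples)
  non_qf <- setdiff(intersect(ped$genotyped, H$samples), qf)
  H$po[match(non_qf, H$samples)] <- 0L
  rows <- list()
  for (C in qf) {
    ci <- match(C, ped$id)
    if (is.na(ped$father[ci])) next  # founders: no parents to separate
    for (ch in unique(D$map$chrom[D$markers])) {
      mk <- D$markers[D$map$chrom[D$markers] == ch]
      m <- vapply(mk, function(s)
        separation_m(po_kinship_matrix(C, s, D, ped)), 0.0)
      a <- assign_po(m, informative_cut, assign_cut)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = C, chrom = ch, orientation = a$orientation,
                   M = if (is.null(a$M)) NA_real_ else a$M,
                   n_plus = a$n_plus, n_minus = a$n_minus)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = integer(),
               orientation = integer(), M = numeric(), n_plus = integer(),
               n_minus = integer())
  for (C in unique(tab$sample)) {
    ori <- tab$orientation[tab$sample == C]
    ori <- ori[!is.na(ori)]
    if (length(ori))
      H$po[match(C, H$samples)] <-
        as.integer(mean(ori) >= 0.5)
  }
  list(haplotypes = H, table = tab)
}
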