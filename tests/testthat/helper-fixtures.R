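# Shared fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# small trio-based pedigree used across modules
trio_ped <- function() {
  pedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
           mother = c(NA, NA, "M"), sex = c(1, 2, 1),
           genotyped = c("F", "M", "C"))
}

# three-generation, all-genotyped study at a reduced scale; shared by the
# phasing / IBD / imputation property tests
small_study <- function() {
  memo("small_study", {
    cfg <- sim_config(n_founder_couples = 8, generations = 3,
                      n_markers = 800, n_chrom = 2, n_seq_variants = 150,
                      n_sequenced = 10, seed = 42)
    # the greedy kinship selection may legitimately fall short of the
    # target subset size on a small pedigree; that warning is expected
    suppressWarnings(simulate_study(cfg))
  })
}

# QC'd genotypes + phased haplotypes + segment store for small_study
small_pipeline <- function() {
  memo("small_pipeline", {
    study <- small_study()
    qc <- framework_qc(study$framework, study$ped)
    ph <- phase_cohort(study$ped, qc$genotypes)
    store <- suppressWarnings(pairwise_ibd(ph$haplotypes, study$ped))
    keep <- match(qc$genotypes$map$id, study$framework$map$id)
    list(study = study, G = qc$genotypes, H = ph$haplotypes,
         stats = ph$stats, store = store,
         truth_haps = study$truth_haps[, keep, drop = FALSE])
  })
}

# four-generation pedigree with an ungenotyped top; quasi-founders are the
# second generation, whose cousins make the clique-kinship separation
# informative. Shared by the parental-origin tests.
po_fixture <- function() {
  memo("po_fixture", {
    cfg <- sim_config(n_founder_couples = 8, generations = 4,
                      genotyped_generations = 2, n_markers = 800,
                      n_chrom = 1, n_seq_variants = 50, n_sequenced = 10,
                      seed = 5)
    ped <- simulate_pedigree(cfg)
    truth <- gene_drop(ped, cfg, seed = 6)
    study <- suppressWarnings(make_study(ped, truth, cfg, seed = 7))
    qc <- framework_qc(study$framework, ped)
    ph <- phase_cohort(ped, qc$genotypes)
    store <- pairwise_ibd(ph$haplotypes, ped)
    D <- build_dictionary(store, seq(1L, nrow(qc$genotypes$map), by = 5L))
    keep <- match(qc$genotypes$map$id, study$framework$map$id)
    list(study = study, ped = ped, G = qc$genotypes, H = ph$haplotypes,
         store = store, D = D,
         truth_haps = study$truth_haps[, keep, drop = FALSE])
  })
}

# true slot-0 orientation (0 paternal, 1 maternal) of a phased sample on a
# chromosome, from the better-matching truth haplotype at phased het sites
true_orientation <- function(px, sample_id, min_hets = 20) {
  i <- match(sample_id, px$H$samples)
  g <- px$G$calls[i, ]
  a0 <- px$H$alleles[hap_index(i, 0L), ]
  het <- !is.na(g) & g == 1L & !is.na(a0)
  if (sum(het) < min_hets) return(NA_integer_)
  d0 <- sum(a0[het] != px$truth_haps[hap_index(i, 0L), het])
  d1 <- sum(a0[het] != px$truth_haps[hap_index(i, 1L), het])
  if (d0 == d1) return(NA_integer_)
  as.integer(d1 < d0)
}

# full-scale study at the headline simulation conditions (~200 individuals,
# 3 generations, 2,000 framework markers, 500 sequence-only variants, 20
# sequenced, per-allele error 1e-3), run through the whole pipeline
acceptance_fixture <- function(seed = 1L) {
  key <- paste0("acceptance_", seed)
  memo(key, {
    cfg <- sim_config(seed = seed)
    study <- suppressWarnings(simulate_study(cfg))
    qc <- framework_qc(study$framework, study$ped)
    ph <- phase_cohort(study$ped, qc$genotypes)
    store <- pairwise_ibd(ph$haplotypes, study$ped)
    G <- qc$genotypes
    anchors <- unique(pedimpute:::anchor_markers(
      list(markers = seq_len(nrow(G$map)), map = G$map),
      study$variants$chrom, study$variants$bp))
    D <- build_dictionary(store, anchors)
    panel <- impute_all(study$variants, D, study$seq_geno, study$sequenced)
    gm <- panel_genotypes(panel)
    tgt <- setdiff(study$samples, study$sequenced)
    called <- !is.na(gm[tgt, , drop = FALSE])
    conc <- mean(gm[tgt, , drop = FALSE][called] ==
                   study$truth_geno[tgt, , drop = FALSE][called])
    list(study = study, G = G, H = ph$haplotypes, store = store, D = D,
         panel = panel, concordance = conc, n_called = sum(called),
         call_rate = mean(called))
  })
}

# Called IBD segment lengths for the one relationship whose true tract
# lengths are exactly exponential under Haldane's model: parent-child
# haplotype pairs, where segments are the inter-crossover spacings of a
# single meiosis (a Poisson process on the genetic map). Scanned on
# gene-dropped truth haplotypes over one long chromosome so censoring at
# the ends is negligible. Returns interior segment lengths in cM.
parent_child_segment_lengths <- function(seed = 71L) {
  memo(paste0("pc_lengths_", seed), {
    cfg <- sim_config(n_founder_couples = 16L, generations = 2L,
                      mean_children = 4, n_markers = 8000L, n_chrom = 1L,
                      chrom_length_cM = 2000, n_seq_variants = 10L,
                      n_sequenced = 5L, seed = seed)
    ped <- simulate_pedigree(cfg)
    truth <- gene_drop(ped, cfg)
    fw <- truth$map$is_framework
    map <- truth$map[fw, setdiff(names(truth$map), "is_framework")]
    rownames(map) <- NULL
    class(map) <- c("MarkerMap", "data.frame")
    H <- haplotype_matrix(truth$hap_alleles[, fw, drop = FALSE], ped$id, map)
    kids <- which(!is.na(match(ped$father, ped$id)))
    fi <- match(ped$father, ped$id)
    pairs <- rbind(cbind(hap_index(kids, 0L), hap_index(fi[kids], 0L)),
                   cbind(hap_index(kids, 0L), hap_index(fi[kids], 1L)))
    segs <- pedimpute:::scan_segments(H, pairs, phi = 0.25, eps = 0.001,
                                      freq = truth$freq[fw])
    interior <- segs$start > 1L & segs$end <= nrow(map)
    segs <- segs[interior, , drop = FALSE]
    map$cM[segs$end - 1L] - map$cM[segs$start]
  })
}

# deterministic handmade map on one chromosome
toy_map <- function(m, spacing_cM = 0.1) {
  suppressMessages(marker_map(chrom = 1, bp = seq_len(m) * spacing_cM * 1e6))
}

# brute-force forward-backward by explicit summation over all state paths;
# independent oracle for the HMM (usable up to ~12 markers)
enumerate_posterior <- function(hapA, hapB, cM, freq, phi, lambda, eps) {
  m <- length(hapA)
  pi <- min(max(phi, 1e-4), 1 - 1e-4)
  emis <- function(a, b, p, state) {
    if (is.na(a) || is.na(b)) return(1)
    q <- 1 - p
    if (state == 1) {
      if (a == b) (1 - eps)^2 + eps^2 else 2 * eps * (1 - eps)
    } else {
      if (a == b) p^2 + q^2 else 2 * p * q
    }
  }
  trans <- function(s1, s2, d) {
    ex <- exp(-lambda * d)
    p_ibd <- if (s1 == 1) pi + (1 - pi) * ex else pi * (1 - ex)
    if (s2 == 1) p_ibd else 1 - p_ibd
  }
  paths <- as.matrix(expand.grid(rep(list(0:1), m)))
  pp <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- if (s[1] == 1) pi else 1 - pi
    p <- p * emis(hapA[1], hapB[1], freq[1], s[1])
    if (m > 1) for (t in 2:m) {
      p <- p * trans(s[t - 1], s[t], cM[t] - cM[t - 1]) *
        emis(hapA[t], hapB[t], freq[t], s[t])
    }
    pp[r] <- p
  }
  vapply(seq_len(m), function(t) sum(pp[paths[, t] == 1]) / sum(pp), 0.0)
}

# exhaustive minimum-edit clique-union partition of a small graph
# (cluster-editing oracle over all set partitions, enumerated as
# restricted-growth strings with branch-and-bound on the partial cost)
brute_force_clique_union <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    adj[cbind(edges$u, edges$v)] <- TRUE
    adj[cbind(edges$v, edges$u)] <- TRUE
  }
  if (n == 1) return(list(membership = 1L, cost = 0L))
  best <- NULL; best_cost <- Inf
  rgs <- integer(n); rgs[1] <- 1L
  recurse <- function(i, mx, cost) {
    if (cost >= best_cost) return(invisible())
    if (i > n) {
      best_cost <<- cost; best <<- rgs
      return(invisible())
    }
    prev <- seq_len(i - 1L)
    for (v in seq_len(mx + 1L)) {
      rgs[i] <<- v
      dc <- sum((rgs[prev] == v) != adj[i, prev])
      recurse(i + 1L, max(mx, v), cost + dc)
    }
  }
  recurse(2L, 1L, 0L)
  list(membership = best, cost = best_cost)
}

# adjusted-for-chance-free Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# IBD2 interval table trimmed by `trim` markers on each side — the
# high-confidence interior used by the discordance estimator checks
trimmed_ibd2 <- function(store, samples, map, trim = 10L, pairs = NULL) {
  tab <- ibd2_table(store, samples, pairs = pairs)
  if (!nrow(tab) || trim == 0) return(tab)
  keep <- logical(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    mks <- which(map$chrom == tab$chrom[r] & map$bp >= tab$start_bp[r] &
                   map$bp <= tab$end_bp[r])
    if (length(mks) <= 2 * trim) next
    keep[r] <- TRUE
    tab$start_bp[r] <- map$bp[mks[trim + 1L]]
    tab$end_bp[r] <- map$bp[mks[length(mks) - trim]]
  }
  tab[keep, , drop = FALSE]
}
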