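#' Simulation configuration
#'
#' Settings for the gene-dropping study generator. Defaults emulate a
#' small multi-generation founder cohort: founder couples at the top,
#' within-generation marriages avoiding close kin, large sibships, dense
#' common framework markers, a set of rarer sequence-only variants, and a
#' small sequenced subset chosen by the greedy kinship rule.
#'
#' @param n_founder_couples founder couples in the first generation.
#' @param generations total pedigree depth.
#' @param genotyped_generations how many of the most recent generations are
#'   genotyped (earlier generations stay in the pedigree ungenotyped, which
#'   is what makes their children quasi-founders).
#' @param mean_children mean children per couple (sibship size is
#'   `2 + Poisson(mean_children - 2)`; founder-population sibships are
#'   large, and at least two children are needed to reconstruct parental
#'   haplotypes).
#' @param mate_kinship_max couples are only formed between individuals with
#'   kinship below this (default 1/16: no sibs, half-sibs, avuncular pairs
#'   or first cousins).
#' @param n_markers framework markers in total, split evenly over
#'   chromosomes.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_cM genetic length per chromosome (bp = cM x 1e6).
#' @param maf_min framework alt frequencies are uniform on
#'   `[maf_min, 1 - maf_min]` (the MAF >= 5% framework panel).
#' @param seq_af_shape1,seq_af_shape2 Beta parameters of sequence-variant
#'   alt frequencies (defaults skew rare, Beta(0.5, 5)).
#' @param n_seq_variants sequence-only variants, placed uniformly between
#'   framework markers.
#' @param error_rate per-allele genotyping error probability.
#' @param missing_rate per-genotype missingness probability.
#' @param n_sequenced size of the sequenced subset.
#' @param kinship_max pairwise kinship ceiling within the sequenced subset
#'   (the greedy selection constraint).
#' @param seed integer seed threaded through every stochastic step.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_founder_couples = 18L, generations = 3L,
                       genotyped_generations = generations,
                       mean_children = 4, mate_kinship_max = 1 / 16,
                       n_markers = 2000L, n_chrom = 2L,
                       chrom_length_cM = 100, maf_min = 0.05,
                       seq_af_shape1 = 0.5, seq_af_shape2 = 5,
                       n_seq_variants = 500L, error_rate = 0.001,
                       missing_rate = 0.002, n_sequenced = 20L,
                       kinship_max = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$generations >= 1, cfg$genotyped_generations >= 1,
            cfg$genotyped_generations <= cfg$generations,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$n_markers >= cfg$n_chrom, cfg$mean_children >= 2)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a multi-generation founder pedigree
#'
#' Founder couples produce children; each later generation pairs its
#' members (male with female, at random) subject to the kinship ceiling,
#' and each couple has `2 + Poisson(mean_children - 2)` children. The most
#' recent `genotyped_generations` are marked genotyped. Reproducible by
#' seed.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return A [pedigree()].
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    id <- character(0); father <- character(0); mother <- character(0)
    sex <- integer(0); gen <- integer(0)
    new_id <- local({
      counter <- 0L
      function() {
        counter <<- counter + 1L
        sprintf("I%04d", counter)
      }
    })
    couples <- list()
    for (k in seq_len(cfg$n_founder_couples)) {
      f <- new_id(); m <- new_id()
      id <- c(id, f, m); father <- c(father, NA, NA); mother <- c(mother, NA, NA)
      sex <- c(sex, 1L, 2L); gen <- c(gen, 1L, 1L)
      couples[[k]] <- c(f, m)
    }
    for (g in seq_len(cfg$generations - 1L) + 1L) {
      kids_id <- character(0); kids_sex <- integer(0)
      for (cp in couples) {
        nk <- 2L + rpois(1L, cfg$mean_children - 2)
        for (j in seq_len(nk)) {
          cid <- new_id()
          id <- c(id, cid); father <- c(father, cp[1]); mother <- c(mother, cp[2])
          s <- rbinom(1L, 1L, 0.5) + 1L
          sex <- c(sex, s); gen <- c(gen, g)
          kids_id <- c(kids_id, cid); kids_sex <- c(kids_sex, s)
        }
      }
      if (g == cfg$generations) break
      ped_now <- pedigree(id, father, mother, sex)
      K <- kinship_matrix(ped_now)
      males <- sample(kids_id[kids_sex == 1L])
      females <- sample(kids_id[kids_sex == 2L])
      couples <- list()
      taken <- character(0)
      for (ml in males) {
        ok <- females[!(females %in% taken) &
                        K[ml, females] < cfg$mate_kinship_max]
        if (!length(ok)) next
        fe <- ok[1]
        taken <- c(taken, fe)
        couples <- c(couples, list(c(ml, fe)))
      }
      if (!length(couples)) break
    }
    genotyped <- id[gen > cfg$generations - cfg$genotyped_generations]
    pedigree(id, father, mother, sex, genotyped = genotyped)
  })
}

# marker map for the simulated genome: framework positions plus
# sequence-only variants placed uniformly between them
sim_marker_map <- function(cfg) {
  per_chrom <- diff(round(seq(0, cfg$n_markers, length.out = cfg$n_chrom + 1)))
  seq_per_chrom <- diff(round(seq(0, cfg$n_seq_variants,
                                  length.out = cfg$n_chrom + 1)))
  chrom <- bp <- fw <- NULL
  for (c in seq_len(cfg$n_chrom)) {
    L <- cfg$chrom_length_cM * 1e6
    fw_bp <- sort(sample.int(L - 2, per_chrom[c])) + 1
    lo <- min(fw_bp); hi <- max(fw_bp)
    sq_bp <- numeric(0)
    while (length(sq_bp) < seq_per_chrom[c]) {
      need <- seq_per_chrom[c] - length(sq_bp)
      draw <- round(runif(need, lo + 1, hi - 1))
      sq_bp <- unique(c(sq_bp, setdiff(draw, fw_bp)))
    }
    pos <- c(fw_bp, sq_bp)
    flag <- c(rep(TRUE, length(fw_bp)), rep(FALSE, length(sq_bp)))
    o <- order(pos)
    chrom <- c(chrom, rep(c, length(pos)))
    bp <- c(bp, pos[o]); fw <- c(fw, flag[o])
  }
  map <- suppressMessages(marker_map(chrom, bp))
  map$is_framework <- fw
  map
}

#' Gene dropping: simulate inheritance through a pedigree
#'
#' Founder haplotype alleles are drawn independently per marker from the
#' configured allele-frequency distributions (linkage equilibrium). Each
#' meiosis draws a Poisson number of crossovers with mean equal to the map
#' length in Morgans, at positions uniform on the genetic map (Haldane, no
#' interference), and the child haplotype copies the parental segments;
#' slot 0 of every non-founder is the paternal haplotype. Founder-allele
#' labels are recorded per haplotype per marker, so true IBD is label
#' equality — an equivalence relation by construction.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return An object of class `SimTruth`: `map` (with `is_framework`),
#'   `labels` and `hap_alleles` (2n-by-m matrices over all pedigree
#'   members), `freq` (true alt frequencies), `n_meioses`,
#'   `n_crossovers`.
#' @export
gene_drop <- function(ped, cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed, {
    map <- sim_marker_map(cfg)
    m <- nrow(map)
    n <- length(ped$id)
    freq <- numeric(m)
    freq[map$is_framework] <- runif(sum(map$is_framework), cfg$maf_min,
                                    1 - cfg$maf_min)
    freq[!map$is_framework] <- rbeta(sum(!map$is_framework),
                                     cfg$seq_af_shape1, cfg$seq_af_shape2)
    labels <- matrix(NA_integer_, 2L * n, m)
    alleles <- matrix(NA_integer_, 2L * n, m)
    fi <- match(ped$father, ped$id)
    mi <- match(ped$mother, ped$id)
    n_meioses <- 0L; n_crossovers <- 0L
    cr <- chrom_ranges(map)
    for (i in ped$order) {
      if (is.na(fi[i])) {
        for (s in 0:1) {
          h <- hap_index(i, s)
          labels[h, ] <- h
          alleles[h, ] <- rbinom(m, 1L, freq)
        }
      } else {
        for (s in 0:1) {
          p <- if (s == 0L) fi[i] else mi[i]
          child_h <- hap_index(i, s)
          for (r in seq_len(nrow(cr))) {
            cols <- cr$start[r]:(cr$end[r] - 1L)
            cm <- map$cM[cols]
            L <- max(cm) - min(cm)
            nx <- rpois(1L, L / 100)
            n_meioses <- n_meioses + 1L
            n_crossovers <- n_crossovers + nx
            bks <- sort(runif(nx, min(cm), max(cm)))
            src_slot <- (rbinom(1L, 1L, 0.5) +
                           findInterval(cm, bks)) %% 2L
            pick <- cbind(hap_index(p, src_slot), cols)
            labels[child_h, cols] <- labels[pick]
            alleles[child_h, cols] <- alleles[pick]
          }
        }
      }
    }
    structure(list(map = map, labels = labels, hap_alleles = alleles,
                   freq = freq, n_meioses = n_meioses,
                   n_crossovers = n_crossovers, ids = ped$id),
              class = "SimTruth")
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d haplotypes x %d markers (%d framework), %d crossovers in %d meioses\n",
              nrow(x$labels), nrow(x$map), sum(x$map$is_framework),
              x$n_crossovers, x$n_meioses))
  invisible(x)
}

#' Greedy selection of a sequencing subset
#'
#' Iteratively adds the genotyped individual maximizing mean kinship to the
#' still-unselected individuals, subject to pairwise kinship below
#' `kinship_max` with everyone already selected; stops early (with a
#' warning) when no candidate remains.
#'
#' @param ped a [pedigree()].
#' @param n_sequenced target subset size.
#' @param kinship_max pairwise ceiling within the subset.
#' @return Character vector of selected ids.
#' @export
select_sequenced <- function(ped, n_sequenced, kinship_max = 0.1) {
  K <- kinship_matrix(ped)
  pool <- ped$genotyped
  chosen <- character(0)
  while (length(chosen) < n_sequenced) {
    cand <- setdiff(pool, chosen)
    if (length(chosen))
      cand <- cand[apply(K[cand, chosen, drop = FALSE] < kinship_max, 1, all)]
    if (!length(cand)) {
      warning("kinship constraint infeasible; selected ",
              length(chosen), " of ", n_sequenced)
      break
    }
    rest <- function(x) mean(K[x, setdiff(pool, c(chosen, x))])
    score <- vapply(cand, rest, 0.0)
    chosen <- c(chosen, cand[which.max(score)])
  }
  chosen
}

#' Assemble a simulated study
#'
#' Produces the observed data the pipeline consumes: a framework genotype
#' matrix over the genotyped samples (haplotype sums with per-allele
#' symmetric errors and missingness), the sequenced subset chosen by
#' [select_sequenced()], and sequence-variant genotypes restricted to that
#' subset. Sequence variants are given plausible ref/alt strings (80% SNVs,
#' 10% insertions, 10% deletions) and dbSNP-known flags for the QC module.
#'
#' @param ped a [pedigree()].
#' @param truth a [gene_drop()] result.
#' @param cfg the [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return A list of class `SimStudy`: `framework` (GenotypeMatrix),
#'   `variants` (a `data.frame` of sequence variants), `seq_geno`
#'   (sequenced samples x variants), `sequenced`, `truth_geno` (true
#'   sequence-variant genotypes of all genotyped samples),
#'   `truth_haps` (true framework haplotypes of the genotyped samples),
#'   `samples`, `ped`, `truth`, `cfg`.
#' @export
make_study <- function(ped, truth, cfg = sim_config(), seed = cfg$seed) {
  with_seed(seed + 1L, {
    samples <- ped$genotyped
    sidx <- match(samples, ped$id)
    rows <- as.vector(rbind(hap_index(sidx, 0L), hap_index(sidx, 1L)))
    fw <- truth$map$is_framework
    fw_map <- truth$map[fw, setdiff(names(truth$map), "is_framework")]
    rownames(fw_map) <- NULL
    class(fw_map) <- c("MarkerMap", "data.frame")

    observe <- function(hapA, hapB) {
      e <- cfg$error_rate
      if (e > 0) {
        flipA <- matrix(rbinom(length(hapA), 1L, e), nrow(hapA))
        flipB <- matrix(rbinom(length(hapB), 1L, e), nrow(hapB))
        hapA <- abs(hapA - flipA); hapB <- abs(hapB - flipB)
      }
      g <- hapA + hapB
      if (cfg$missing_rate > 0)
        g[matrix(rbinom(length(g), 1L, cfg$missing_rate), nrow(g)) == 1L] <-
          NA_integer_
      g
    }

    hA <- truth$hap_alleles[rows[c(TRUE, FALSE)], fw, drop = FALSE]
    hB <- truth$hap_alleles[rows[c(FALSE, TRUE)], fw, drop = FALSE]
    G <- genotype_matrix(observe(hA, hB), samples, fw_map)

    sequenced <- select_sequenced(ped, cfg$n_sequenced, cfg$kinship_max)
    sq <- !fw
    sq_map <- truth$map[sq, , drop = FALSE]
    qidx <- match(sequenced, ped$id)
    sA <- truth$hap_alleles[hap_index(qidx, 0L), sq, drop = FALSE]
    sB <- truth$hap_alleles[hap_index(qidx, 1L), sq, drop = FALSE]
    seq_geno <- observe(sA, sB)
    dimnames(seq_geno) <- list(sequenced, NULL)

    nv <- sum(sq)
    type <- sample(c("SNV", "insertion", "deletion"), nv, replace = TRUE,
                   prob = c(0.8, 0.1, 0.1))
    ref <- ifelse(type == "deletion", "AT", "A")
    alt <- ifelse(type == "insertion", "AT", ifelse(type == "deletion", "A", "G"))
    variants <- data.frame(
      chrom = sq_map$chrom, bp = sq_map$bp, ref = ref, alt = alt, type = type,
      rs_known = runif(nv) < 0.7,
      call_rate = colMeans(!is.na(seq_geno)),
      singleton = colSums(seq_geno, na.rm = TRUE) == 1L)

    truth_geno <- truth$hap_alleles[hap_index(sidx, 0L), sq, drop = FALSE] +
      truth$hap_alleles[hap_index(sidx, 1L), sq, drop = FALSE]
    dimnames(truth_geno) <- list(samples, NULL)

    structure(list(framework = G, variants = variants, seq_geno = seq_geno,
                   sequenced = sequenced,
                   truth_geno = truth_geno,
                   truth_haps = truth$hap_alleles[rows, fw, drop = FALSE],
                   samples = samples, ped = ped, truth = truth, cfg = cfg),
              class = "SimStudy")
  })
}

#' @rdname make_study
#' @export
simulate_study <- function(cfg = sim_config(), seed = cfg$seed) {
  ped <- simulate_pedigree(cfg, seed)
  truth <- gene_drop(ped, cfg, seed + 101L)
  make_study(ped, truth, cfg, seed + 202L)
}
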