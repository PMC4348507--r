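test_that("majority vote needs two thirds of the votes", {
  expect_equal(majority_allele(c(1L, 1L, 1L)), 1L)
  expect_equal(majority_allele(c(1L, 0L)), NA_integer_)
  expect_equal(majority_allele(c(1L, 1L, 0L)), 1L)   # exactly 2/3 passes
  expect_equal(majority_allele(integer(0)), NA_integer_)
  expect_equal(majority_allele(c(0L, 0L, 0L, 1L)), 0L)
  expect_equal(majority_allele(c(1L, 1L, 0L, 0L)), NA_integer_)
})

test_that("a hand-traced queue run propagates alleles through cliques", {
  # 5 samples; sequenced: s1 (hom alt) and s2 (het).
  # cliques at the anchor: {s1_0, s1_1, s2_0, s3_0, s3_1}, {s2_1, s4_0},
  # singletons {s4_1}, {s5_0}, {s5_1}.
  membership <- c(1L, 1L, 1L, 2L, 1L, 1L, 2L, 3L, 4L, 5L)
  geno <- c(s1 = 2L, s2 = 1L)
  res <- impute_variant(geno, membership, seq_idx = c(1L, 2L))
  # trace: s1 homozygous -> haps 1,2 queued with allele 1; clique 1 gets 1
  # everywhere; s2 het has slot 0 resolved to 1 -> slot 1 complemented to 0
  # and queued; clique 2 = {s2_1, s4_0} gets allele 0.
  expect_equal(res$alleles, c(1L, 1L, 1L, 0L, 1L, 1L, 0L, NA, NA, NA))
  expect_equal(res$source[5:7], c("pedigree", "pedigree", "pedigree"))
  expect_equal(res$source[3], "pedigree")
  expect_equal(res$source[4], "complement")
  expect_equal(res$source[1:2], c("sequenced", "sequenced"))
})

test_that("one homozygous sequenced sample imputes its whole clique", {
  membership <- c(rep(1L, 5), 2L)
  geno <- c(s1 = 2L)
  res <- impute_variant(geno, membership, seq_idx = 1L)
  expect_equal(res$alleles[1:5], rep(1L, 5))
  expect_true(is.na(res$alleles[6]))
})

test_that("conflicting votes leave the clique fully uncalled", {
  # two sequenced homozygotes with opposite alleles share a clique
  membership <- c(1L, 1L, 1L, 1L, 1L, 1L)
  geno <- c(s1 = 2L, s2 = 0L)
  res <- impute_variant(geno, membership, seq_idx = c(1L, 2L))
  # votes {1,1,0,0}: no two-thirds majority; nothing beyond the observed
  # sequenced alleles is imputed
  expect_equal(res$alleles[5:6], c(NA_integer_, NA_integer_))
  expect_equal(res$source[5:6], c("none", "none"))
})

test_that("whole-panel imputation is order-independent and respects inputs", {
  px <- small_pipeline()
  study <- px$study
  G <- px$G
  anchors <- unique(pedimpute:::anchor_markers(
    list(markers = seq_len(nrow(G$map)), map = G$map),
    study$variants$chrom, study$variants$bp))
  D <- build_dictionary(px$store, anchors)
  panel <- impute_all(study$variants, D, study$seq_geno, study$sequenced)

  # shuffled variant order gives identical per-variant results
  set.seed(12)
  ord <- sample(nrow(study$variants))
  panel2 <- impute_all(study$variants[ord, ], D,
                       study$seq_geno[, ord, drop = FALSE], study$sequenced)
  expect_equal(panel2$alleles, panel$alleles[, ord])

  # sequenced samples are never overwritten
  gm <- panel_genotypes(panel)
  for (s in study$sequenced) {
    obs <- study$seq_geno[s, ]
    got <- gm[s, ]
    both <- !is.na(obs) & !is.na(got) & obs != 1L
    expect_true(all(got[both] == obs[both]))
  }

  # an all-missing variant yields no calls
  v_missing <- study$variants[1, ]
  sg <- matrix(NA_integer_, length(study$sequenced), 1,
               dimnames = list(study$sequenced, NULL))
  p0 <- impute_all(v_missing, D, sg, study$sequenced)
  expect_true(all(is.na(p0$alleles)))

  # call-rate chain: genotype <= allele <= max call rate at the anchor
  rates <- panel$rates
  expect_lte(rates$genotype_call_rate, rates$allele_call_rate + 1e-12)
  mcr <- vapply(seq_len(nrow(study$variants)), function(v)
    max_call_rate(D, study$sequenced, panel$anchors[v]), 0.0)
  per_var_allele <- colMeans(!is.na(panel$alleles))
  expect_true(all(per_var_allele <= mcr + 1e-12))
})

test_that("imputed genotypes agree with simulation truth on called calls", {
  px <- small_pipeline()
  study <- px$study
  anchors <- unique(pedimpute:::anchor_markers(
    list(markers = seq_len(nrow(px$G$map)), map = px$G$map),
    study$variants$chrom, study$variants$bp))
  D <- build_dictionary(px$store, anchors)
  panel <- impute_all(study$variants, D, study$seq_geno, study$sequenced)
  gm <- panel_genotypes(panel)
  tgt <- setdiff(study$samples, study$sequenced)
  called <- !is.na(gm[tgt, ])
  expect_gte(sum(called), 500)
  conc <- mean(gm[tgt, ][called] == study$truth_geno[tgt, ][called])
  expect_gte(conc, 0.99)
})

test_that("cross-validation reports overall and heterozygote concordance", {
  px <- small_pipeline()
  study <- px$study
  thinned <- seq(1L, nrow(px$G$map), by = 5L)
  D <- build_dictionary(px$store, thinned)
  cv <- cross_validate(px$G, D, study$sequenced, k = 5L)
  expect_gte(cv$overall$concordance, 0.99)
  expect_equal(cv$overall$n_markers, length(thinned))
  expect_true(all(cv$by_maf$concordance >= 0 & cv$by_maf$concordance <= 1))

  # a single-marker run reports on one marker
  D1 <- build_dictionary(px$store, 1L)
  cv1 <- cross_validate(px$G, D1, study$sequenced, k = nrow(px$G$map) + 1L)
  expect_equal(cv1$overall$n_markers, 1L)
})

test_that("het concordance denominator is both-called, het-in-either", {
  # toy table: 4 genotype pairs -> only 3 enter the het denominator
  ped_g <- c(1L, 1L, 0L, 2L)
  ld_g <- c(1L, 0L, 1L, 2L)
  both <- !is.na(ped_g) & !is.na(ld_g)
  het <- both & (ped_g == 1L | ld_g == 1L)
  expect_equal(sum(het), 3L)
  expect_equal(mean(ped_g[het] == ld_g[het]), 1 / 3)
})

test_that("LD merging applies hard-call, concordance and MAF rules", {
  map <- toy_map(3)
  variants <- data.frame(chrom = 1L, bp = map$bp[1:3])
  # panel over 3 samples, sample 3 unsequenced and uncalled everywhere
  alleles <- matrix(NA_integer_, 6, 3)
  alleles[1:2, ] <- 1L   # s1 hom alt everywhere (pedigree)
  alleles[3:4, 1] <- 0L  # s2 called hom ref at v1
  panel <- structure(list(alleles = alleles,
                          source = matrix("none", 6, 3),
                          variants = variants, samples = c("a", "b", "c"),
                          sequenced = "a", anchors = c(1L, 2L, 3L)),
                     class = "ImputedPanel")
  panel$genotypes <- panel_genotypes(panel)
  panel$geno_source <- matrix(ifelse(is.na(panel$genotypes), "none",
                                     "pedigree"), 3, 3)
  probs <- array(0, c(3, 3, 3))
  probs[, , 1] <- 0.005; probs[, , 2] <- 0.005; probs[, , 3] <- 0.99
  probs[3, 1, ] <- c(0.001, 0.0035, 0.9955)    # confident call for c at v1
  probs[3, 2, ] <- c(0.5, 0.3, 0.2)            # below the 0.99 cutoff
  probs[3, 3, ] <- c(0.001, 0.0035, 0.9955)
  maf <- c(0.3, 0.3, 0.005)
  merged <- merge_ld_calls(panel, probs, maf)
  # v1: kept, fills only the missing sample-c genotype
  expect_equal(unname(merged$genotypes[3, 1]), 2L)
  expect_equal(merged$geno_source[3, 1], "LD")
  expect_equal(unname(merged$genotypes[2, 1]), 0L)          # pedigree call untouched
  expect_equal(merged$geno_source[2, 1], "pedigree")
  # v2: no hard call for sample c
  expect_true(is.na(merged$genotypes[3, 2]))
  # v3: MAF below 1% drops all its LD calls
  expect_true(is.na(merged$genotypes[3, 3]))
  expect_false(merged$ld_report$kept[3])
  # malformed probabilities are rejected
  bad <- probs; bad[1, 1, ] <- c(0.5, 0.1, 0.1)
  expect_error(merge_ld_calls(panel, bad, maf), "sum to 1")
})

test_that("per-variant het discordance below 99% drops a variant's LD calls", {
  map <- toy_map(1)
  n <- 100
  samples <- sprintf("s%d", 1:n)
  alleles <- matrix(0L, 2 * n, 1)
  alleles[hap_index(3:52, 0L), 1] <- 1L  # 50 pedigree hets
  panel <- structure(list(alleles = alleles, source = matrix("ped", 2 * n, 1),
                          variants = data.frame(chrom = 1L, bp = map$bp[1]),
                          samples = samples, sequenced = "s1", anchors = 1L),
                     class = "ImputedPanel")
  panel$genotypes <- panel_genotypes(panel)
  panel$geno_source <- matrix("pedigree", n, 1)
  probs <- array(0, c(n, 1, 3))
  ld_geno <- panel$genotypes[, 1]
  ld_geno[3:4] <- 0L                      # two het discordances
  for (i in seq_len(n)) probs[i, 1, ld_geno[i] + 1L] <- 1
  merged <- merge_ld_calls(panel, probs, maf = 0.3)
  expect_false(merged$ld_report$kept[1])
  expect_equal(merged$ld_report$het_concordance[1], 48 / 50)
})

test_that("haploid parental panels export and recombine into genotypes", {
  map <- toy_map(4)
  A <- rbind(c(0L, 1L, NA, 1L), c(1L, 0L, NA, 1L))
  H <- haplotype_matrix(A, "s", map, po = 0L)
  prefix <- withr::local_tempfile()
  paths <- export_haploid_po_panels(H, prefix)
  pat <- read_haploid_panel(paths[1])
  mat <- read_haploid_panel(paths[2])
  expect_equal(unname(pat[1, ]), c(0L, 1L, NA, 1L))
  expect_equal(unname(mat[1, ]), c(1L, 0L, NA, 1L))
  # merging the two pseudo-samples reconstructs the genotype
  expect_equal(unname(pat[1, ] + mat[1, ]), c(1L, 1L, NA, 2L))
  # maternal-first orientation swaps the panels
  H2 <- haplotype_matrix(A, "s", map, po = 1L)
  paths2 <- export_haploid_po_panels(H2, paste0(prefix, "b"))
  expect_equal(unname(read_haploid_panel(paths2[1])[1, ]), c(1L, 0L, NA, 1L))
})
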