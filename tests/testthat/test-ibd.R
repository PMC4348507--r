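test_that("single-marker posterior equals the one-site Bayes update", {
  map <- toy_map(1)
  p <- hmm_params(phi = 0.1, eps = 0.01, freq = 0.3)
  for (pair in list(c(1L, 1L), c(0L, 0L), c(0L, 1L), c(NA, 1L))) {
    post <- hmm_posterior(pair[1], pair[2], map, p)
    pi <- 0.1
    e1 <- if (is.na(pair[1]) || is.na(pair[2])) 1 else
      if (pair[1] == pair[2]) (1 - 0.01)^2 + 0.01^2 else 2 * 0.01 * 0.99
    e0 <- if (is.na(pair[1]) || is.na(pair[2])) 1 else
      if (pair[1] == pair[2]) 0.3^2 + 0.7^2 else 2 * 0.3 * 0.7
    expect_equal(post, pi * e1 / (pi * e1 + (1 - pi) * e0), tolerance = 1e-12)
  }
})

test_that("a huge transition rate decouples markers into independent updates", {
  m <- 20
  map <- toy_map(m)
  set.seed(4)
  hapA <- rbinom(m, 1, 0.5)
  hapB <- hapA
  hapB[c(3, 11)] <- 1 - hapB[c(3, 11)]
  freq <- runif(m, 0.2, 0.8)
  p <- hmm_params(phi = 0.2, lambda = 1e6, eps = 0.01, freq = freq)
  post <- hmm_posterior(hapA, hapB, map, p)
  single <- vapply(seq_len(m), function(t)
    hmm_posterior(hapA[t], hapB[t], map[t, ], hmm_params(
      phi = 0.2, lambda = 1e6, eps = 0.01, freq = freq[t])), 0.0)
  expect_equal(post, single, tolerance = 1e-8)
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:6) {
    m <- sample(3:9, 1)
    map <- toy_map(m, spacing_cM = runif(1, 0.05, 2))
    hapA <- rbinom(m, 1, 0.5)
    hapB <- rbinom(m, 1, 0.5)
    if (rep %% 2 == 0) hapA[sample(m, 1)] <- NA
    freq <- runif(m, 0.1, 0.9)
    phi <- runif(1, 0.01, 0.4)
    lambda <- runif(1, 0.005, 0.5)
    eps <- runif(1, 0.001, 0.05)
    post <- hmm_posterior(hapA, hapB, map,
                          hmm_params(phi, lambda, eps, freq))
    oracle <- enumerate_posterior(hapA, hapB, map$cM, freq, phi, lambda, eps)
    expect_equal(post, oracle, tolerance = 1e-10)
  }
})

test_that("identical long haplotypes give near-certain interior posterior", {
  m <- 500
  map <- toy_map(m)
  set.seed(2)
  hap <- rbinom(m, 1, 0.5)
  p <- hmm_params(phi = 0.05, eps = 0.001, freq = 0.5)
  post <- hmm_posterior(hap, hap, map, p)
  expect_gte(min(post[50:450]), 0.99)
})

test_that("posterior is invariant under haplotype relabeling and never underflows", {
  m <- 1e5
  map <- toy_map(m, spacing_cM = 0.01)
  set.seed(3)
  hapA <- rbinom(m, 1, 0.5)
  hapB <- ifelse(runif(m) < 0.3, hapA, rbinom(m, 1, 0.5))
  p <- hmm_params(phi = 0.1, eps = 0.005, freq = 0.5)
  postAB <- hmm_posterior(hapA, hapB, map, p)
  postBA <- hmm_posterior(hapB, hapA, map, p)
  expect_equal(postAB, postBA)
  expect_true(all(is.finite(postAB)))
  expect_true(all(postAB >= 0 & postAB <= 1))
})

test_that("segment extraction finds maximal runs with half-open bounds", {
  map <- toy_map(100)
  expect_equal(nrow(extract_segments(rep(0.1, 100), map)), 0L)
  s <- extract_segments(rep(0.99, 100), map)
  expect_equal(s$start, 1L)
  expect_equal(s$end, 101L)
  post <- c(rep(0.2, 30), rep(0.9, 20), rep(0.2, 50))
  s2 <- extract_segments(post, map)
  expect_equal(s2$start, 31L)
  expect_equal(s2$end, 51L)
  expect_equal(s2$mean_posterior, 0.9)
  # runs below the minimum length are discarded
  post[60:64] <- 0.95
  expect_equal(nrow(extract_segments(post, map, min_markers = 10L)), 1L)
})

test_that("haplotype pair enumeration counts all C(2n, 2) pairs", {
  expect_equal(n_haplotype_pairs(2), 6)
  expect_equal(n_haplotype_pairs(1415), 4003035)
  prs <- pedimpute:::haplotype_pairs(2)
  expect_equal(nrow(prs), 6L)
  expect_true(all(prs[, 1] < prs[, 2]))
  expect_equal(nrow(pedimpute:::haplotype_pairs(3, include_self = FALSE)),
               choose(6, 2) - 3)
})

test_that("pairwise IBD recovers most true tracts of 2 cM or more", {
  px <- acceptance_fixture()
  study <- px$study
  store <- px$store
  keep <- match(px$G$map$id, study$framework$map$id)
  sidx <- match(study$samples, study$truth$ids)
  labels <- study$truth$labels[
    as.vector(rbind(hap_index(sidx, 0L), hap_index(sidx, 1L))),
    study$truth$map$is_framework][, keep, drop = FALSE]
  cr <- pedimpute:::chrom_ranges(px$G$map)
  set.seed(8)
  hp <- pedimpute:::haplotype_pairs(length(study$samples))
  hp <- hp[sample(nrow(hp), 2000), , drop = FALSE]
  found <- total <- 0
  for (r in seq_len(nrow(hp))) {
    a <- hp[r, 1]; b <- hp[r, 2]
    eq <- labels[a, ] == labels[b, ]
    segs <- pedimpute:::pair_segments(store, a, b)
    for (cc in seq_len(nrow(cr))) {
      cols <- cr$start[cc]:(cr$end[cc] - 1L)
      rl <- rle(eq[cols])
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        g0 <- cols[starts[k]]; g1 <- cols[ends[k]]
        if (px$G$map$cM[g1] - px$G$map$cM[g0] < 2) next
        total <- total + 1
        hit <- any(segs$start <= g1 & segs$end > g0)
        found <- found + hit
      }
    }
  }
  expect_gte(total, 100)
  expect_gte(found / total, 0.9)
})

test_that("genome IBD fraction takes interval unions, not sums", {
  map <- toy_map(100)
  seg <- data.frame(hap_a = c(1L, 1L), hap_b = c(3L, 3L), chrom = 1L,
                    start = c(10L, 30L), end = c(50L, 70L),
                    start_bp = map$bp[c(10, 30)], end_bp = map$bp[c(49, 69)],
                    mean_posterior = 0.9)
  store <- segment_store(seg, c("a", "b"), map)
  # union [10, 70) spans cM[10]..cM[69]; oracle computed directly
  expect_equal(genome_ibd_fraction(store, c("a", "b")),
               (map$cM[69] - map$cM[10]) / (map$cM[100] - map$cM[1]))
  empty <- segment_store(seg[0, ], c("a", "b"), map)
  expect_equal(genome_ibd_fraction(empty, c("a", "b")), 0)
  whole <- segment_store(data.frame(hap_a = 1L, hap_b = 3L, chrom = 1L,
                                    start = 1L, end = 101L,
                                    start_bp = map$bp[1], end_bp = map$bp[100],
                                    mean_posterior = 0.9),
                         c("a", "b"), map)
  expect_equal(genome_ibd_fraction(whole, c("a", "b")), 1)
})

test_that("IBD2 requires both disjoint pairings simultaneously", {
  map <- toy_map(100)
  mk_store <- function(seg) segment_store(seg, c("a", "b"), map)
  base <- data.frame(chrom = 1L, start_bp = 0, end_bp = 0, mean_posterior = 0.9)
  # one shared haplotype only: no IBD2
  one <- cbind(data.frame(hap_a = 1L, hap_b = 3L, start = 1L, end = 101L), base)
  expect_equal(nrow(ibd2_segments(mk_store(one), c("a", "b"))), 0L)
  # both pairings (0-0 and 1-1) over overlapping ranges
  two <- rbind(cbind(data.frame(hap_a = 1L, hap_b = 3L, start = 1L, end = 60L), base),
               cbind(data.frame(hap_a = 2L, hap_b = 4L, start = 40L, end = 101L), base))
  got <- ibd2_segments(mk_store(two), c("a", "b"))
  expect_equal(got$start, 40L)
  expect_equal(got$end, 60L)
  # unrelated: empty store
  expect_equal(nrow(ibd2_segments(mk_store(one[0, ]), c("a", "b"))), 0L)
})

test_that("called IBD2 covers most of a true double-shared region", {
  px <- small_pipeline()
  study <- px$study
  ped <- study$ped
  # a sib pair with substantial true IBD2
  fams <- Filter(function(f) length(f$children) >= 2, nuclear_families(ped))
  best <- NULL; best_frac <- 0
  keep <- match(px$G$map$id, study$framework$map$id)
  sidx <- match(study$samples, study$truth$ids)
  lab <- study$truth$labels[, study$truth$map$is_framework][, keep]
  for (f in fams[seq_len(min(10, length(fams)))]) {
    ch <- match(intersect(f$children, study$samples), study$samples)
    for (i in seq_along(ch)[-1]) {
      a <- ch[1]; b <- ch[i]
      ia <- sidx[a]; ib <- sidx[b]
      ibd2_true <- (lab[hap_index(ia, 0L), ] == lab[hap_index(ib, 0L), ] &
                      lab[hap_index(ia, 1L), ] == lab[hap_index(ib, 1L), ]) |
        (lab[hap_index(ia, 0L), ] == lab[hap_index(ib, 1L), ] &
           lab[hap_index(ia, 1L), ] == lab[hap_index(ib, 0L), ])
      if (mean(ibd2_true) > best_frac) {
        best_frac <- mean(ibd2_true)
        best <- list(a = a, b = b, truth = ibd2_true)
      }
    }
  }
  expect_gte(best_frac, 0.05)
  got <- ibd2_segments(px$store, study$samples[c(best$a, best$b)])
  covered <- rep(FALSE, ncol(lab))
  for (r in seq_len(nrow(got))) covered[got$start[r]:(got$end[r] - 1L)] <- TRUE
  recall <- sum(covered & best$truth) / sum(best$truth)
  expect_gte(recall, 0.9)
})

test_that("segment stores canonicalize, deduplicate and round-trip as text", {
  map <- toy_map(50)
  seg <- data.frame(hap_a = c(4L, 2L, 2L), hap_b = c(2L, 4L, 4L), chrom = 1L,
                    start = c(1L, 1L, 10L), end = c(20L, 20L, 30L),
                    start_bp = 1, end_bp = 2, mean_posterior = 0.9)
  store <- segment_store(seg, c("a", "b"), map)
  expect_equal(nrow(store$segments), 2L)  # duplicate pair collapsed
  expect_true(all(store$segments$hap_a < store$segments$hap_b))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(store, path)
  tab <- read_segments(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$hapA_sample, c("a", "a"))
  expect_equal(tab$start_marker, c(1L, 10L))
})
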