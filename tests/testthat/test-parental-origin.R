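test_that("separation measure has the stated limits, range and zero case", {
  K <- matrix(0, 2, 2)
  K[1, 1] <- 0.2; K[2, 2] <- 0.2
  expect_equal(separation_m(K), 1)     # diagonal dominates
  K2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_equal(separation_m(K2), -1)   # off-diagonal dominates
  K3 <- matrix(0.1, 2, 2)
  expect_equal(separation_m(K3), 0)    # symmetric
  expect_equal(separation_m(matrix(0, 2, 2)), 0)
  set.seed(1)
  for (i in 1:20) {
    K4 <- matrix(runif(4), 2, 2)
    expect_gte(separation_m(K4), -1)
    expect_lte(separation_m(K4), 1)
  }
})

test_that("orientation assignment counts informative signs against M > 0.75", {
  a <- assign_po(c(0.5, 0.8, 0.9, 0.3, -0.1, 0.02))
  expect_equal(a$orientation, 0L)
  expect_equal(a$M, 1)
  expect_equal(a$n_plus, 4L)  # |m| > 0.25 only
  b <- assign_po(c(0.5, -0.5, 0.6, -0.6))
  expect_true(is.na(b$orientation))   # M = 0.5
  d <- assign_po(c(rep(0.4, 8), rep(-0.4, 2)))
  expect_equal(d$M, 0.8)
  expect_equal(d$orientation, 0L)
  e <- assign_po(rep(-0.6, 5))
  expect_equal(e$orientation, 1L)
  expect_true(is.na(assign_po(rep(0.1, 10))$orientation))  # none informative
})

test_that("clique kinship matrix applies the eligibility rules", {
  px <- po_fixture()
  ped <- px$ped
  qf <- intersect(quasi_founders(ped), px$H$samples)
  C <- qf[1]
  K <- po_kinship_matrix(C, px$D$markers[10], px$D, ped)
  expect_equal(dim(K), c(2L, 2L))
  expect_true(all(K >= 0 & K <= 0.5))
  # a founder (parents absent) is rejected
  top <- ped$id[is.na(ped$father)][1]
  expect_error(po_kinship_matrix(top, px$D$markers[10], px$D, ped),
               "parents")
})

test_that("median-of-kinships uses only eligible members", {
  # handcrafted dictionary: C's slot-0 clique = {C, one cousin, one sib};
  # the sib and C are excluded, leaving the single cousin's kinship
  ped <- pedigree(
    id = c("g1", "g2", "A", "U", "B", "W", "C", "S", "Z"),
    father = c(NA, NA, "g1", "g1", NA, NA, "A", "A", "U"),
    mother = c(NA, NA, "g2", "g2", NA, NA, "B", "B", "W"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 1, 1),
    genotyped = c("C", "S", "Z"))
  samples <- c("C", "S", "Z")
  map <- toy_map(5)
  mem <- matrix(seq_len(6), 6, 1)   # all singletons...
  mem[c(1, 3, 5), 1] <- 1L          # ...except slot0 of C, S and Z
  D <- structure(list(markers = 3L, membership = mem, samples = samples,
                      map = map), class = "CliqueDictionary")
  K <- po_kinship_matrix("C", 3L, D, ped)
  # eligible member of C's slot-0 clique: Z only (sib S excluded)
  expect_equal(K[1, 1], kinship(ped, "A", "Z"))  # uncle-nephew = 1/8
  expect_equal(K[1, 1], 0.125)
  expect_equal(K[2, 1], kinship(ped, "B", "Z"))  # unrelated = 0
  # slot-1 clique of C is a singleton -> zero column
  expect_equal(unname(K[, 2]), c(0, 0))
  # median over several members
  expect_equal(median(c(0.1, 0.2, 0.4)), 0.2)
})

test_that("slot swap negates m, preserves M and flips the orientation", {
  px <- po_fixture()
  ped <- px$ped
  H <- px$H
  qf <- intersect(quasi_founders(ped), H$samples)
  qf <- qf[!is.na(ped$father[match(qf, ped$id)])]
  C <- qf[3]
  ci <- match(C, H$samples)
  # swapped copy: exchange C's two haplotype rows, rebuild the store rows
  Hsw <- H
  r0 <- hap_index(ci, 0L); r1 <- hap_index(ci, 1L)
  Hsw$alleles[c(r0, r1), ] <- H$alleles[c(r1, r0), ]
  store_sw <- px$store
  sw <- function(h) ifelse(h == r0, r1, ifelse(h == r1, r0, h))
  store_sw$segments$hap_a <- sw(store_sw$segments$hap_a)
  store_sw$segments$hap_b <- sw(store_sw$segments$hap_b)
  store_sw <- segment_store(store_sw$segments, store_sw$samples, store_sw$map)
  D_sw <- build_dictionary(store_sw, px$D$markers)

  mk <- px$D$markers[seq(1, length(px$D$markers), by = 4)]
  m1 <- vapply(mk, function(s) separation_m(po_kinship_matrix(C, s, px$D, ped)), 0.0)
  m2 <- vapply(mk, function(s) separation_m(po_kinship_matrix(C, s, D_sw, ped)), 0.0)
  expect_equal(m1, -m2, tolerance = 1e-12)
  a1 <- assign_po(m1); a2 <- assign_po(m2)
  expect_equal(a1$M, a2$M)
  expect_equal(a1$n_plus, a2$n_minus)
  if (!is.na(a1$orientation)) expect_equal(a2$orientation, 1L - a1$orientation)
})

test_that("assigned quasi-founder orientations agree with simulated truth", {
  px <- po_fixture()
  res <- assign_parental_origin(px$ped, px$H, px$D)
  tab <- res$table
  assigned <- tab[!is.na(tab$orientation), ]
  expect_gte(nrow(assigned), 10)
  agree <- total <- 0
  for (r in seq_len(nrow(assigned))) {
    truth_ori <- true_orientation(px, assigned$sample[r])
    if (is.na(truth_ori)) next
    total <- total + 1
    agree <- agree + (assigned$orientation[r] == truth_ori)
  }
  expect_gte(agree / total, 0.95)
  # non-quasi-founders all oriented slot-0-paternal
  non_qf <- setdiff(px$ped$genotyped, quasi_founders(px$ped))
  expect_true(all(res$haplotypes$po[match(non_qf, px$H$samples)] == 0L))
})

test_that("family bins co-assign shared haplotypes and recover recombinations", {
  px <- small_pipeline()
  study <- px$study
  fams <- Filter(function(f) length(f$children) >= 3,
                 nuclear_families(study$ped))
  fam <- fams[[1]]
  bins <- assign_family_bins(fam, px$H, px$store, thin = 10L)
  k <- length(fam$children)
  expect_equal(dim(bins$bins), c(2L * k, length(bins$markers)))
  expect_true(all(bins$bins %in% 1:4))
  # slot-0 rows stay on the paternal side (bins 1-2), slot-1 on maternal
  expect_true(all(bins$bins[seq(1, 2 * k, by = 2), ] %in% 1:2))
  expect_true(all(bins$bins[seq(2, 2 * k, by = 2), ] %in% 3:4))
  # bins reflect true founder-haplotype sharing: siblings sharing the
  # true paternal segment share a bin at most thinned markers
  keep <- match(px$G$map$id, study$framework$map$id)
  sidx <- match(study$samples, study$truth$ids)
  lab <- study$truth$labels[, study$truth$map$is_framework][, keep]
  kids <- match(fam$children, study$samples)
  ok <- tot <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    same_true <- lab[hap_index(sidx[kids[i]], 0L), bins$markers] ==
      lab[hap_index(sidx[kids[j]], 0L), bins$markers]
    same_bin <- bins$bins[2 * i - 1L, ] == bins$bins[2 * j - 1L, ]
    ok <- ok + sum(same_true == same_bin)
    tot <- tot + length(same_true)
  }
  expect_gte(ok / tot, 0.9)
  expect_error(assign_family_bins(list(children = fam$children[1]), px$H,
                                  px$store), "at least 2")
})

test_that("bin switch counts from the DP never exceed a greedy assignment", {
  set.seed(17)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    M <- 40
    # simulate a true binary side assignment with occasional switches
    z <- matrix(0L, k, M)
    for (c in seq_len(k)) {
      cur <- rbinom(1, 1, 0.5)
      for (t in seq_len(M)) {
        if (runif(1) < 0.05) cur <- 1L - cur
        z[c, t] <- cur
      }
    }
    pr <- utils::combn(k, 2)
    obs <- (z[pr[1, ], , drop = FALSE] == z[pr[2, ], , drop = FALSE]) * 1
    # add observation noise
    flip <- matrix(runif(length(obs)) < 0.05, nrow(obs))
    obs[flip] <- 1 - obs[flip]
    rho <- max(3, k - 1)
    total_cost <- function(a) {
      emis <- sum(vapply(seq_len(M), function(t)
        sum((a[pr[1, ], t] == a[pr[2, ], t]) != (obs[, t] == 1)), 0L))
      emis + rho * sum(abs(diff(t(a))) > 0)
    }
    path <- pedimpute:::side_viterbi(obs, k, switch_cost = rho)
    # greedy baseline: left-to-right, keep previous assignment unless the
    # current marker's observations improve by switching one track (track 1
    # stays pinned, as in the DP's state space)
    greedy <- matrix(0L, k, M)
    for (t in 2:M) {
      greedy[, t] <- greedy[, t - 1]
      cost <- function(a) sum((a[pr[1, ]] == a[pr[2, ]]) != (obs[, t] == 1))
      for (c in seq_len(k)[-1]) {
        alt <- greedy[, t]; alt[c] <- 1L - alt[c]
        if (cost(alt) < cost(greedy[, t])) greedy[, t] <- alt
      }
    }
    expect_lte(total_cost(path), total_cost(greedy))
  }
})

test_that("bin pairing orientation maximizes the minimum child separation", {
  # perfect two-child family, no recombination
  bins <- list(children = c("c1", "c2"),
               markers = 1:10,
               bins = rbind(rep(1L, 10), rep(3L, 10),
                            rep(2L, 10), rep(4L, 10)))
  rownames(bins$bins) <- c("c1_0", "c1_1", "c2_0", "c2_1")
  got <- family_po_orientation(bins)
  expect_equal(got$separation, c(1, 1))    # F1 = 2, F2 = 0
  expect_equal(got$slot0_parent, c("A", "A"))
  expect_equal(sort(got$pairing), c(1L, 2L))
  # uninformative: child covered half by each pairing
  bins2 <- list(children = "c1", markers = 1:10,
                bins = rbind(c(rep(1L, 5), rep(3L, 5)),
                             c(rep(3L, 5), rep(1L, 5))))
  got2 <- family_po_orientation(bins2)
  expect_equal(got2$separation, 0.5)
})
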