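test_that("conserved-core intersection follows interval algebra", {
  # single strain: core equals its own reference intervals
  m1 <- make_cmap(data.frame(ref_start = c(0, 200), ref_end = c(100, 300),
                             query_start = c(0, 200), query_end = c(100, 300),
                             anchors = c(1, 1)), 400, 400, L = 10)
  s1 <- intersect_conserved(list(a = m1))
  expect_equal(s1$core, data.frame(start = c(0, 200), end = c(100, 300)))

  # idempotence under duplication
  s2 <- intersect_conserved(list(a = m1, b = m1))
  expect_equal(s2$core, s1$core)

  # the worked two-strain example
  m2 <- make_cmap(data.frame(ref_start = 50, ref_end = 250,
                             query_start = 50, query_end = 250, anchors = 1),
                  400, 400, L = 10)
  s3 <- intersect_conserved(list(a = m1, b = m2))
  expect_equal(s3$core, data.frame(start = c(50, 200), end = c(100, 250)))
  expect_equal(s3$slots$start, c(0, 100, 250))
  expect_equal(s3$slots$end, c(50, 200, 400))
  expect_equal(s3$p, 3)

  # brute-force per-base oracle
  cov <- coverage_vector(s3$core, 400)
  oracle <- coverage_vector(data.frame(start = c(0, 200), end = c(100, 300)), 400) &
            coverage_vector(data.frame(start = 50, end = 250), 400)
  expect_equal(cov, oracle)
  expect_error(intersect_conserved(list(
    a = m1, b = make_cmap(m2, 400, 400, ref_id = "otherref"))), "reference id")
})

test_that("core fragments shorter than L are absorbed into slots", {
  m1 <- make_cmap(data.frame(ref_start = c(0, 500), ref_end = c(400, 1000),
                             query_start = c(0, 500), query_end = c(400, 1000),
                             anchors = c(1, 1)), 1000, 1000, L = 32)
  m2 <- make_cmap(data.frame(ref_start = 380, ref_end = 1000,
                             query_start = 380, query_end = 1000, anchors = 1),
                  1000, 1000, L = 32)
  s <- intersect_conserved(list(a = m1, b = m2))
  # raw intersection gives [380,400) of width 20 < 32: absorbed
  expect_false(any(s$core$start == 380))
  expect_equal(s$core, data.frame(start = 500, end = 1000))
})

test_that("strain-side slot lengths track planted events", {
  set.seed(61)
  sim <- simulate_strain_set(seed = 3, n_strains = 2, ref_length = 60000,
                             n_insertions = 1, n_deletions = 1, snp_rate = 0,
                             n_runs = 0)
  idx <- build_index(sim$reference)
  maps <- lapply(sim$strains, function(s)
    chain_segments(find_common_lgrams(idx, s)))
  slots <- intersect_conserved(maps)

  # a strain identical to the reference measures every slot at its reference length
  self_map <- chain_segments(find_common_lgrams(idx, sim$reference))
  len_self <- strain_slot_length(slots, self_map)
  expect_equal(as.numeric(len_self), slots$slots$end - slots$slots$start)

  for (s in names(sim$strains)) {
    tr <- sim$truth$plants[sim$truth$plants$strain_id == s, ]
    lens <- strain_slot_length(slots, maps[[s]])
    for (k in seq_len(nrow(tr))) {
      slot_hit <- which(slots$slots$start < tr$ref_end[k] + 64 &
                        slots$slots$end > tr$ref_start[k] - 64)
      expect_length(slot_hit, 1)
      ref_len <- slots$slots$end[slot_hit] - slots$slots$start[slot_hit]
      if (tr$kind[k] == "insertion")
        expect_lt(abs(lens[slot_hit] - (ref_len + tr$length[k])), 128)
      else  # the slot is mostly the deleted interval: near-empty in the strain
        expect_lt(lens[slot_hit], ref_len - tr$length[k] + 128)
    }
  }
})

test_that("binary profiles respond to the threshold monotonically", {
  set.seed(62)
  sim <- simulate_strain_set(seed = 5, n_strains = 3, ref_length = 60000,
                             n_insertions = 1, n_deletions = 1)
  idx <- build_index(sim$reference)
  maps <- lapply(sim$strains, function(s)
    chain_segments(find_common_lgrams(idx, s)))
  slots <- intersect_conserved(maps)
  p0 <- binary_profiles(slots, maps, d = 0)
  expect_true(all(p0 == 1))
  prev <- p0
  for (d in c(300, 1000, 4000, 10000, 1e7)) {
    p <- binary_profiles(slots, maps, d = d)
    expect_true(all(p <= prev))  # raising d can only clear bits
    prev <- p
  }
  expect_true(all(prev == 0))
  # slot count is shared across strains by construction
  expect_equal(ncol(p0), slots$p)
})

test_that("identical strains give identical profiles and zero distances", {
  set.seed(63)
  ref <- chromosome_seq(rand_seq(20000), "ref", "chr")
  idx <- build_index(ref)
  strains <- list(a = chromosome_seq(plant_n_run(ref$seq, 5000, 1000), "a", "chr"),
                  b = chromosome_seq(plant_n_run(ref$seq, 5000, 1000), "b", "chr"))
  maps <- lapply(strains, function(s) chain_segments(find_common_lgrams(idx, s)))
  slots <- intersect_conserved(maps)
  prof <- binary_profiles(slots, maps, d = 300)
  expect_equal(unname(prof["a", ]), unname(prof["b", ]))
  D <- hamming_matrix(prof)
  expect_true(all(D == 0))
})

test_that("Hamming distances equal a per-bit recount", {
  expect_equal(hamming_matrix(rbind(a = c(0, 0, 0), b = c(1, 1, 1)))["a", "b"], 3)
  set.seed(64)
  prof <- matrix(rbinom(10 * 50, 1, 0.4), nrow = 10,
                 dimnames = list(paste0("s", 1:10), NULL))
  D <- hamming_matrix(prof)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  for (a in 1:10) for (b in 1:10)
    expect_equal(D[a, b], sum(prof[a, ] != prof[b, ]))
  expect_error(hamming_matrix(list(c(0, 1), c(0, 1, 1))), "length")
})

test_that("UPGMA reproduces hand-executed merges and is ultrametric", {
  # two leaves at distance 6: each branch is 3
  D2 <- matrix(c(0, 6, 6, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_tree(D2)
  expect_equal(sort(t2$edge.length), c(3, 3))

  # four leaves, hand-run UPGMA: merge (A,B) at 2 -> heights 1;
  # d(AB,C) = 4 so merge at 4 -> height 2; d(ABC,D) = 6 -> root height 3.
  # cophenetic distances: AB 2, {A,B}C 4, all-D 6
  D4 <- matrix(c(0, 2, 4, 6,
                 2, 0, 4, 6,
                 4, 4, 0, 6,
                 6, 6, 6, 0), 4, byrow = TRUE,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- upgma_tree(D4)
  coph <- ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(coph, D4)

  # a case where unweighted (size-weighted) averaging matters:
  # d(A,B)=2; d(C,A)=5, d(C,B)=9 -> d(AB,C) = 7; d(D,*)=10.
  # merges: (A,B)@2, (AB,C)@7, root@10 (= (10*2+10)/3, size-weighted)
  D4b <- matrix(c(0, 2, 5, 10,
                  2, 0, 9, 10,
                  5, 9, 0, 10,
                  10, 10, 10, 0), 4, byrow = TRUE,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4b <- upgma_tree(D4b)
  coph_b <- ape::cophenetic.phylo(t4b)[LETTERS[1:4], LETTERS[1:4]]
  expected <- matrix(c(0, 2, 7, 10,
                       2, 0, 7, 10,
                       7, 7, 0, 10,
                       10, 10, 10, 0), 4, byrow = TRUE,
                     dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_equal(coph_b, expected)

  # ultrametricity: every root-to-leaf path has the same length
  expect_true(ape::is.ultrametric(t4b))

  # leaf-order permutation does not change the tree
  perm <- c("C", "A", "D", "B")
  tp <- upgma_tree(D4b[perm, perm])
  expect_equal(ape::cophenetic.phylo(tp)[LETTERS[1:4], LETTERS[1:4]], expected)

  expect_error(upgma_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("conservation scores split almost- from fully-non-conserved slots", {
  prof <- rbind(s1 = c(1, 1, 0, 1),
                s2 = c(1, 0, 0, 1),
                s3 = c(1, 1, 0, 1))
  colnames(prof) <- paste0("slot", 1:4)
  sc <- conservation_scores(prof)
  expect_equal(sc$score, c(3, 2, 0, 3))
  expect_equal(sc$class, c("almost_conserved", "fully_non_conserved",
                           "fully_non_conserved", "almost_conserved"))
  # random recount
  set.seed(65)
  pr <- matrix(rbinom(7 * 20, 1, 0.5), nrow = 7,
               dimnames = list(paste0("s", 1:7), paste0("slot", 1:20)))
  expect_equal(conservation_scores(pr)$score, unname(colSums(pr)))
})

test_that("sensitivity and specificity follow the contingency formulas", {
  # no false negatives: sensitivity is 100%
  ss <- sens_spec_counts(TP = 12, FP = 3, TN = 40, FN = 0)
  expect_equal(ss$Sn, 1)
  # no true positives
  expect_equal(sens_spec_counts(TP = 0, FP = 3, TN = 40, FN = 5)$Sn, 0)
  # the printed worked values, at one decimal in percent
  s2 <- sens_spec_counts(TP = 7, FP = 7, TN = 26, FN = 4)
  expect_equal(round(100 * s2$Sn, 1), 63.6)
  expect_equal(round(100 * s2$Sp, 1), 78.8)
  # brute-force agreement on random counts
  set.seed(66)
  for (rep in 1:50) {
    cnt <- sample(0:30, 4, replace = TRUE)
    s <- sens_spec_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(s$Sn, if (cnt[1] + cnt[4] > 0) cnt[1] / (cnt[1] + cnt[4])
                       else NA_real_)
    expect_equal(s$Sp, if (cnt[3] + cnt[2] > 0) cnt[3] / (cnt[3] + cnt[2])
                       else NA_real_)
  }
})

test_that("interval-overlap matching fills the contingency table", {
  truth <- data.frame(start = c(100, 1000, 5000), end = c(200, 1500, 5400))
  pred <- data.frame(start = c(150, 4000, 9000), end = c(300, 4100, 9100))
  ss <- sens_spec(pred, truth, universe = 10)
  expect_equal(ss$TP, 1)  # truth 1 is hit
  expect_equal(ss$FN, 2)  # truths 2 and 3 missed
  expect_equal(ss$FP, 2)  # predictions 2 and 3 hit nothing
  expect_equal(ss$TN, 10 - 1 - 2 - 2)
  expect_error(sens_spec(pred, truth, universe = 0), "positive")
})
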