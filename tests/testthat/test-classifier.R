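test_that("full coverage yields no events; sub-threshold gaps are discarded", {
  set.seed(51)
  ref <- chromosome_seq(rand_seq(5000), "ref", "chr")
  q <- chromosome_seq(ref$seq, "q", "chr")
  m2 <- make_cmap(data.frame(ref_start = 0, ref_end = 5000,
                             query_start = 0, query_end = 5000, anchors = 1),
                  5000, 5000)
  expect_equal(nrow(extract_gaps(m2, ref, q)), 0)

  # 150 b gap on both sides: below the 200 b significance floor
  m150 <- make_cmap(data.frame(ref_start = c(0, 2150), ref_end = c(2000, 5000),
                               query_start = c(0, 2150), query_end = c(2000, 5000),
                               anchors = c(1, 1)), 5000, 5000)
  expect_equal(nrow(extract_gaps(m150, ref, q)), 0)
})

test_that("gap lengths and unresolved fractions are measured on both sides", {
  set.seed(52)
  px <- pair_with_insertion(20000, 9000, 6000)
  ref <- chromosome_seq(px$ref, "ref", "chr")
  q <- chromosome_seq(px$query, "q", "chr")
  ap <- anchor_pair(ref, q)
  ev <- extract_gaps(ap$segments, ref, q)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$gB - 6000), 64)
  expect_lt(ev$gA, 200)
  expect_equal(ev$n_frac_query, 0)
})

test_that("the taxonomy assigns the canonical categories", {
  cfg <- classifier_config()
  ann <- data.frame(chrom_id = "chr",
                    start = c(1000, 20000), end = c(6900, 20300),
                    feature_class = c("Ty1", "Ty2ltr"),
                    name = c("ty", "ltr"), stringsAsFactors = FALSE)
  ev <- data.frame(
    ref_start   = c(1000, 10000, 19850, 30000, 40000, 50000, 60000),
    ref_end     = c(6900, 16000, 19880, 36000, 40020, 50030, 66000),
    query_start = c(100, 1000, 2000, 3000, 9000, 20000, 30000),
    query_end   = c(100, 7050, 2300, 3000, 14000, 25000, 36500),
    gA          = c(5900, 6000, 30, 6000, 20, 30, 6000),
    gB          = c(0, 6050, 300, 0, 5000, 5000, 6500),
    n_frac_query = c(0, 0.9, 0, 0, 1.0, 0, 0))
  out <- classify_events(ev, ann, cfg)
  expect_equal(out$category,
               c("pDEL_Ty",   # deletion overlapping an annotated Ty1
                 "pCONSu",    # same length both sides, mostly unresolved
                 "pINS",      # strain-side only, 300 b
                 "pDEL",      # deletion with no mobile annotation
                 "pINSu",     # unresolved insertion
                 "pINS",      # resolved insertion near the solo-LTR
                 "COMPLEX"))  # both sides significant, lengths differ
  expect_equal(out$size_class,
               c("Ty_c", "Ty_c", "ltr_c", "Ty_c", "Ty_c", "Ty_c", "Ty_c"))
  # events 1 and 3 touch/neighbour annotations within 200 b
  expect_true(out$prox_mobil[1])
  expect_true(out$prox_mobil[3])   # solo-LTR 120 b from the gap
  expect_false(out$prox_mobil[4])
})

test_that("worked examples: pDEL_Ty, unresolved Ty-compatible insertion, pCONSu", {
  cfg <- classifier_config()
  # deletion of 5900 b overlapping an annotated Ty1
  ann <- data.frame(chrom_id = "chr", start = 500, end = 6000,
                    feature_class = "Ty1", name = "ty", stringsAsFactors = FALSE)
  e1 <- classify_events(data.frame(ref_start = 400, ref_end = 6300,
                                   query_start = 50, query_end = 50,
                                   gA = 5900, gB = 0, n_frac_query = 0),
                        ann, cfg)
  expect_equal(e1$category, "pDEL_Ty")
  expect_equal(e1$size_class, "Ty_c")

  # all-N 5000 b insertion with the nearest solo-LTR 150 b away
  ann2 <- data.frame(chrom_id = "chr", start = 1180, end = 1480,
                     feature_class = "Ty3ltr", name = "ltr",
                     stringsAsFactors = FALSE)
  e2 <- classify_events(data.frame(ref_start = 1000, ref_end = 1030,
                                   query_start = 2000, query_end = 7000,
                                   gA = 30, gB = 5000, n_frac_query = 1),
                        ann2, cfg)
  expect_equal(e2$category, "pINSu")
  expect_equal(e2$size_class, "Ty_c")
  expect_true(e2$prox_mobil)

  # both sides ~6 kb, strain side 90% unresolved: conserved but unreadable
  e3 <- classify_events(data.frame(ref_start = 0, ref_end = 6000,
                                   query_start = 0, query_end = 6050,
                                   gA = 6000, gB = 6050, n_frac_query = 0.9),
                        NULL, cfg)
  expect_equal(e3$category, "pCONSu")
})

test_that("every extracted event gets exactly one category", {
  set.seed(53)
  sim <- simulate_strain_set(seed = 99, n_strains = 2, ref_length = 60000,
                             n_insertions = 2, n_deletions = 2)
  taxonomy <- c("CONS", "pCONSu", "pDEL", "pDEL_Ty", "pDEL_LTR", "pINS",
                "pINSu", "COMPLEX")
  for (s in names(sim$strains)) {
    res <- run_pairwise(sim$reference, sim$strains[[s]],
                        annotations = sim$annotations)
    expect_true(all(res$events$category %in% taxonomy))
    expect_false(any(is.na(res$events$category)))
    expect_equal(sum(table(res$events$category)), nrow(res$events))
  }
})

test_that("shrinking the proximity radius never adds prox_mobil events", {
  set.seed(54)
  sim <- simulate_strain_set(seed = 7, n_strains = 1, ref_length = 60000,
                             n_insertions = 2, n_deletions = 2)
  res <- anchor_pair(sim$reference, sim$strains[[1]])
  ev <- extract_gaps(res$segments, sim$reference, sim$strains[[1]])
  n_prox <- vapply(c(400, 200, 100, 0), function(p) {
    cfg <- classifier_config(prox = p)
    sum(classify_events(ev, sim$annotations, cfg)$prox_mobil)
  }, numeric(1))
  expect_true(all(diff(n_prox) <= 0))
})

test_that("summaries count categories and annotated deletions correctly", {
  empty <- classify_events(data.frame(ref_start = numeric(), ref_end = numeric(),
                                      query_start = numeric(), query_end = numeric(),
                                      gA = numeric(), gB = numeric(),
                                      n_frac_query = numeric()), NULL,
                           classifier_config())
  s0 <- summarize_events(empty)
  expect_equal(sum(s0$by_category$n), 0)

  ann <- data.frame(chrom_id = "chr", start = 100, end = 5100,
                    feature_class = "Ty2", name = "ty2", stringsAsFactors = FALSE)
  ev <- classify_events(data.frame(ref_start = 90, ref_end = 5200,
                                   query_start = 10, query_end = 10,
                                   gA = 5110, gB = 0, n_frac_query = 0),
                        ann, classifier_config())
  s1 <- summarize_events(ev, ann)
  expect_equal(s1$by_feature$deletions[s1$by_feature$feature_class == "Ty2"], 1)
  expect_equal(sum(s1$by_category$n), 1)
  expect_equal(s1$by_category$n[s1$by_category$category == "pDEL_Ty" &
                                s1$by_category$size_class == "Ty_c"], 1)
})

test_that("a synthetic strain's event table matches a hand count of its truth log", {
  sim <- simulate_strain_set(seed = 11, n_strains = 3, ref_length = 80000,
                             n_insertions = 2, n_deletions = 3)
  for (s in names(sim$strains)) {
    res <- run_pairwise(sim$reference, sim$strains[[s]],
                        annotations = sim$annotations)
    tr <- sim$truth$plants[sim$truth$plants$strain_id == s, ]
    n_del_expected <- sum(tr$kind == "deletion")
    n_ins_expected <- sum(tr$kind == "insertion")
    expect_equal(sum(startsWith(res$events$category, "pDEL")), n_del_expected)
    expect_equal(sum(startsWith(res$events$category, "pINS")), n_ins_expected)
    # deletions hit their own annotation: all are Ty-classified
    expect_equal(sum(res$events$category == "pDEL_Ty"), n_del_expected)
    # the two N-runs surface as unresolved-conservation events
    expect_equal(sum(res$events$category == "pCONSu"), 2)
  }
})
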