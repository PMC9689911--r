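test_that("contingency tables are laid out focal-vs-rest", {
  focal <- make_counts("P1", "rs1", 8L, 10L)
  rest <- make_counts("REST", "rs1", 10L, 40L)
  expect_equal(contingency_table(focal, rest, "rs1"),
               c(a = 8L, b = 2L, c = 10L, d = 30L))
  # degenerate all-absent column is still testable with p = 1
  t0 <- contingency_table(make_counts("P1", "rs1", 0L, 10L),
                          make_counts("REST", "rs1", 0L, 40L), "rs1")
  expect_equal(t0, c(a = 0L, b = 10L, c = 0L, d = 40L))
  expect_equal(fisher_exact_p(0, 10, 0, 40), 1)
  # zero focal total -> untestable
  expect_null(contingency_table(make_counts("P1", "rs1", 0L, 0L),
                                rest, "rs1"))
  expect_null(contingency_table(focal, rest, "rs_not_there"))
})

test_that("exact p matches enumeration and an independent implementation", {
  expect_equal(fisher_exact_p(5, 5, 50, 50), 1)  # modal table
  expect_equal(fisher_exact_p(8, 2, 10, 30), naive_fisher_p(8, 2, 10, 30),
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(0, 10, 40, 0), naive_fisher_p(0, 10, 40, 0),
               tolerance = 1e-12)
  # random tables against stats::fisher.test (a separate code base)
  withr::with_seed(42, {
    for (i in 1:200) {
      t <- sample(0:25, 4, replace = TRUE)
      if (t[1] + t[2] == 0 || t[3] + t[4] == 0) next
      ours <- fisher_exact_p(t[1], t[2], t[3], t[4])
      ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact_p(0, 0, 3, 4), "row margin")
})

test_that("signed score has the -log10 magnitude and frequency-driven sign", {
  p <- naive_fisher_p(8, 2, 10, 30)
  s <- signed_score(8, 2, 10, 30)          # focal 0.8 > rest 0.25: enriched
  expect_equal(as.numeric(s), -log10(p))
  expect_equal(attr(s, "p"), p, tolerance = 1e-12)
  # swapping effect/non-effect columns on both rows flips only the sign
  s_dep <- signed_score(2, 8, 30, 10)
  expect_equal(as.numeric(s_dep), -as.numeric(s))
  # equal proportions score exactly 0
  expect_equal(as.numeric(signed_score(5, 5, 50, 50)), 0)
  expect_equal(as.numeric(signed_score(3, 7, 30, 70)), 0)
})

test_that("the p-value floor caps scores at 300", {
  s <- signed_score(0, 2000, 2000, 0)  # total separation, huge counts
  expect_equal(as.numeric(s), -300)
  expect_lte(abs(as.numeric(signed_score(2000, 0, 0, 2000))), 300)
})

test_that("p decreases monotonically toward separation at fixed margins", {
  ps <- vapply(10:0, function(a) fisher_exact_p(a, 20 - a, 20 - a, a),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the matrix composes per-cell scores and marks untestable cells", {
  model <- make_model(c(1.1, 1.2), rsid = c("rs1", "rs2"))
  ct <- dplyr::bind_rows(
    make_counts("P1", c("rs1", "rs2"), c(8L, 3L), c(10L, 10L)),
    make_counts("P2", c("rs1", "rs2"), c(5L, 5L), c(20L, 20L)),
    make_counts("P3", "rs1", 5L, 20L))      # rs2 missing in P3
  em <- build_enrichment_matrix(model, ct)
  expect_equal(dim(em$scores), c(2, 3))
  # cell equals the directly composed statistic (rest pools P2 + P3)
  expect_equal(em$scores["rs1", "P1"],
               as.numeric(signed_score(8, 2, 10, 30)))
  expect_equal(em$p["rs1", "P1"], naive_fisher_p(8, 2, 10, 30),
               tolerance = 1e-12)
  expect_true(is.na(em$scores["rs2", "P3"]))
  expect_true(all(abs(em$scores) >= 0 | is.na(em$scores)))
  # identical populations give an all-zero matrix
  same <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(p) {
    make_counts(p, c("rs1", "rs2"), c(4L, 6L), c(10L, 10L))
  }))
  em0 <- build_enrichment_matrix(model, same)
  expect_true(all(em0$scores == 0))
  expect_error(build_enrichment_matrix(model, make_counts("A", "rs1", 1L, 2L)),
               "at least 2 populations")
})

test_that("long format carries raw p plus a reference Bonferroni column", {
  model <- make_model(c(1, 1), rsid = c("rs1", "rs2"))
  ct <- dplyr::bind_rows(
    make_counts("P1", c("rs1", "rs2"), c(8L, 3L), c(10L, 10L)),
    make_counts("P2", c("rs1", "rs2"), c(5L, 5L), c(20L, 20L)))
  lg <- enrichment_long(build_enrichment_matrix(model, ct))
  expect_equal(nrow(lg), 4)
  expect_true(all(lg$p_bonferroni >= lg$p & lg$p_bonferroni <= 1))
})

test_that("divergence filter uses |a| + |b| with a strict cutoff", {
  scores <- matrix(c(40, 30, 2, -25, -30, 1), ncol = 2,
                   dimnames = list(c("rs1", "rs2", "rs3"), c("AFR", "EAS")))
  em <- make_em(scores)
  expect_equal(divergence_filter(em, "AFR", "EAS", 60), "rs1")  # 65 > 60
  # rs2 sums to exactly 60: strict inequality drops it
  expect_false("rs2" %in% divergence_filter(em, "AFR", "EAS", 60))
  expect_equal(divergence_filter(em, "AFR", "EAS", 0),
               c("rs1", "rs2", "rs3"))
  expect_error(divergence_filter(em, "AFR", "XXX", 60), "XXX")
})

test_that("cluster order puts identical rows adjacent and separates blocks", {
  m <- rbind(rs1 = c(5, -5, 0), rs2 = c(-4, 4, 1),
             rs3 = c(5, -5, 0), rs4 = c(-5, 5, 0))
  colnames(m) <- c("A", "B", "C")
  ord <- cluster_order(make_em(m))
  pos <- match(c(1, 3), ord$rows)  # identical rows rs1 and rs3
  expect_equal(abs(diff(pos)), 1)

  # two opposite-signed blocks stay contiguous at the top split
  blocks <- rbind(matrix(10 + rnorm(9, sd = .1), 3),
                  matrix(-10 + rnorm(9, sd = .1), 3))
  rownames(blocks) <- paste0("rs", 1:6)
  colnames(blocks) <- c("A", "B", "C")
  for (perm in list(1:6, c(4, 1, 5, 2, 6, 3))) {
    o <- cluster_order(make_em(blocks[perm, ]))$rows
    side <- perm[o] <= 3
    expect_true(all(side[1:3]) || all(!side[1:3]))
  }

  one <- make_em(matrix(1, 1, 1, dimnames = list("rs1", "A")))
  expect_equal(cluster_order(one), list(rows = 1L, cols = 1L))
})
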