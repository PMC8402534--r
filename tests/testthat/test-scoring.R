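test_that("competition ranking handles direction and ties", {
  expect_equal(rank_parameter(c(0.5, 0.3, 0.1), "higher_better"), c(1L, 2L, 3L))
  expect_equal(rank_parameter(c(0.5, 0.5, 0.2), "higher_better"), c(1L, 1L, 3L))
  expect_equal(rank_parameter(c(30, 900, 5000), "lower_better"), c(1L, 2L, 3L))
  expect_error(rank_parameter(c(1, NaN), "lower_better", ids = c("a", "b")),
               "b")
})

test_that("the non-binder penalty is all-or-nothing at the threshold", {
  expect_equal(penalty_k(1500, 300), 300L)
  expect_equal(penalty_k(1000, 300), 0L)    # boundary: strictly greater
  expect_equal(penalty_k(1000.01, 300), 300L)
  expect_equal(penalty_k(50, 7), 0L)
  expect_equal(penalty_k(c(2000, 10), 5), c(5L, 0L))
})

test_that("a sole candidate attains the minimum weighted rank sum of 3", {
  r <- venus_score(data.frame(peptide_id = "only", tumor_mf = 0.3,
                              corr_tpm = 2, wf = 1, best_ic50_nm = 400))
  expect_equal(r$rsum, 3)
  expect_equal(r$final_position, 1L)
  # the same candidate with wf = 5 scores 15 but still ranks first alone
  r5 <- venus_score(data.frame(peptide_id = "only", tumor_mf = 0.3,
                               corr_tpm = 2, wf = 5, best_ic50_nm = 400))
  expect_equal(r5$rsum, 15)
})

test_that("the weighted rank sum composes ranks, penalty and WF exactly", {
  # three candidates whose ranks are hand-computable
  tab <- data.frame(peptide_id = c("a", "b", "c"),
                    tumor_mf = c(0.6, 0.4, 0.2),      # ranks 1 2 3
                    corr_tpm = c(1, 9, 4),            # ranks 3 1 2
                    wf = c(1L, 1L, 2L),
                    best_ic50_nm = c(800, 1200, 90))  # ranks 2 3 1
  r <- venus_score(tab)
  r <- r[order(r$peptide_id), ]
  expect_equal(r$rsum[r$peptide_id == "a"], (1 + 3 + (0 + 2)) * 1)   # 6
  expect_equal(r$rsum[r$peptide_id == "b"], (2 + 1 + (3 + 3)) * 1)   # 9
  expect_equal(r$rsum[r$peptide_id == "c"], (3 + 2 + (0 + 1)) * 2)   # 12
  expect_equal(r$final_position[order(r$rsum)], 1:3)
  expect_true(all(r$rsum == (r$r_freq + r$r_expr + (r$k + r$r_ic50)) * r$wf))
})

test_that("scoring matches the exhaustive oracle on random tables", {
  set.seed(41)
  for (rep in 1:300) {
    tab <- random_candidate_table(sample(1:6, 1))
    got <- as.data.frame(venus_score(tab))
    want <- rsum_oracle(tab)
    expect_equal(got[, names(want)], want)
  }
})

test_that("final positions are invariant under input permutation", {
  set.seed(42)
  tab <- random_candidate_table(40)
  a <- as.data.frame(venus_score(tab))
  b <- as.data.frame(venus_score(tab[sample(40), ]))
  expect_equal(a$peptide_id, b$peptide_id)
  expect_equal(a$final_position, b$final_position)
})

test_that("improving one parameter never worsens a candidate's rsum", {
  set.seed(43)
  for (rep in 1:25) {
    tab <- random_candidate_table(15)
    base <- as.data.frame(venus_score(tab))
    i <- sample(15, 1)
    for (col in c("tumor_mf", "corr_tpm", "best_ic50_nm")) {
      tab2 <- tab
      delta <- runif(1, 0, 2)
      tab2[[col]][i] <- if (col == "best_ic50_nm")
        max(0.01, tab[[col]][i] - delta * 500) else tab[[col]][i] + delta
      new <- as.data.frame(venus_score(tab2))
      id <- tab$peptide_id[i]
      expect_lte(new$rsum[new$peptide_id == id],
                 base$rsum[base$peptide_id == id])
    }
  }
})

test_that("rsum structure invariants hold on random tables", {
  set.seed(44)
  tab <- random_candidate_table(120)
  r <- venus_score(tab)
  expect_true(all(r$k %in% c(0L, 120L)))
  expect_true(all(r$wf %in% 1:5))
  expect_true(all(r$rsum >= 3))
  expect_equal(sort(r$final_position), 1:120)
})

test_that("alternative strategies rank by their single parameter", {
  tab <- data.frame(peptide_id = c("a", "b", "c"),
                    tumor_mf = c(0.5, 0.3, 0.9),
                    corr_tpm = c(4, 9, 1),
                    tpm = c(4, 9, 1),
                    wf = 1L,
                    best_ic50_nm = c(600, 90, 450))
  expect_equal(rank_alternative(tab, "mf_only")$peptide_id, c("c", "a", "b"))
  expect_equal(rank_alternative(tab, "expr_only")$peptide_id,
               c("b", "a", "c"))
  expect_equal(rank_alternative(tab, "ic50_only")$peptide_id,
               c("b", "c", "a"))
  # venus delegates to the weighted rank sum
  expect_equal(rank_alternative(tab, "venus"), venus_score(tab))
  expect_error(rank_alternative(tab, "best_guess"))
})

test_that("funnel filtering drops threshold failures regardless of the other axis", {
  tab <- data.frame(peptide_id = c("strong_lowexpr", "weak_expr", "ok"),
                    tumor_mf = 0.5, corr_tpm = c(0.1, 9, 4),
                    tpm = c(0.1, 9, 4), wf = 1L,
                    best_ic50_nm = c(20, 600, 450))
  out <- rank_alternative(tab, "funnel_then_ic50")
  # IC50 600 > 500 excluded despite high expression; TPM 0.1 < 0.5 excluded
  # despite strong binding
  expect_equal(out$peptide_id, "ok")
  expect_equal(truth_positions(out, c("weak_expr", "ok"), "peptide_id"),
               c(weak_expr = Inf, ok = 1))
})
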