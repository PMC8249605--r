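# Sequential, undisputed and combined search strategies

test_that("static sequential search reproduces the worked example", {
  prob <- dvi_example(1)
  res <- sequential_search(prob, threshold = 5)
  expect_equal(nrow(res$solutions), 1)
  expect_equal(unname(res$solutions[1, ]), c("*", "M2", "M3"))
  # T > 5: no identifications at all
  expect_equal(unname(sequential_search(prob, 5.5)$solutions[1, ]),
               c("*", "*", "*"))
  expect_error(sequential_search(prob, 1), "> 1")
})

test_that("updating sequential search recovers the father in toy 1", {
  res <- sequential_search(dvi_example(1), threshold = 5, update = TRUE)
  expect_equal(nrow(res$solutions), 1)
  expect_equal(unname(res$solutions[1, ]), c("M1", "M2", "M3"))
  # the trail shows the conditional LR of 10 for the father
  lrs <- lapply(res$trail, function(tr) tr$LR)
  expect_true(all(vapply(lrs, function(x) any(abs(x - 10) < 1e-6),
                         logical(1))))
})

test_that("updating sequential search ties on toy 2 and is suboptimal", {
  res <- sequential_search(dvi_example(2), threshold = 10, update = TRUE)
  sols <- apply(res$solutions, 1, paste, collapse = ",")
  expect_setequal(sols, c("M2,*,M1", "M2,*,M3"))
  prob <- dvi_example(2)
  lrs <- apply(res$solutions, 1, function(a) lr_vs_null(prob, a))
  expect_equal(unname(lrs), c(200, 200), tolerance = 1e-9)
  # ... versus the joint optimum, ten times more likely
  best <- rank_assignments(prob)[1, ]
  expect_equal(best$LR / lrs[[1]], 10, tolerance = 1e-9)
  # the sequential solutions never contain the jointly optimal pairings
  expect_false(any(sols == "M3,M1,M2"))
  # with the threshold above all entries nothing is identified
  expect_equal(unname(sequential_search(dvi_example(2), 21)$solutions[1, ]),
               c("*", "*", "*"))
})

test_that("the undisputed criterion applies strictly and relaxed", {
  B2 <- pairwise_lr_matrix(dvi_example(2))
  # row V1 has competitors > 1 everywhere: nothing undisputed
  expect_equal(nrow(find_undisputed(B2, 10)), 0)
  # single nonzero entry above T
  B <- matrix(c(0, 0, 0, 50), 2, 2, dimnames = list(c("V1", "V2"),
                                                    c("M1", "M2")))
  u <- find_undisputed(B, 10)
  expect_equal(u$victim, "V2")
  expect_equal(u$mp, "M2")
  # competitor 2 in the same row: rejected strictly, relaxed iff 2 <= LR/T
  B["V2", "M1"] <- 2
  expect_equal(nrow(find_undisputed(B, 10)), 0)
  expect_equal(nrow(find_undisputed(B, 10, relaxed = TRUE)), 1)  # 2 <= 5
  B["V2", "M2"] <- 15                                            # 2 > 1.5
  expect_equal(nrow(find_undisputed(B, 10, relaxed = TRUE)), 0)
})

test_that("combined search ranks toy problems correctly", {
  j1 <- joint_search(dvi_example(1), threshold = 2)
  expect_equal(unname(unlist(j1[1, c("V1", "V2", "V3")])),
               c("M1", "M2", "M3"))
  expect_equal(j1$LR[1], 250, tolerance = 1e-9)
  # at T=2 every pairing resolves as undisputed, so the ranking is the
  # single fixed assignment with conditional posterior 1
  expect_setequal(names(attr(j1, "undisputed")), c("V1", "V2", "V3"))

  j2 <- joint_search(dvi_example(2), threshold = 10)
  expect_equal(unname(unlist(j2[1, c("V1", "V2", "V3")])),
               c("M3", "M1", "M2"))
  expect_equal(j2$LR[1], 2000, tolerance = 1e-9)
  expect_equal(round(j2$posterior[1], 2), 0.69)
  expect_equal(length(attr(j2, "undisputed")), 0)
  expect_equal(j2$LR[1] / j2$LR[2], 10, tolerance = 1e-9)
  # zero-LR pairings are dropped before the joint step: 27 of 34 remain
  # (joint exclusions invisible to the pairwise matrix may still rank
  # with LR 0, e.g. V2 = M3 once V1 = M2 pins down M2's genotype)
  expect_equal(nrow(j2), 27)
  expect_false(is.unsorted(rev(j2$loglik)))
  expect_equal(sum(j2$posterior), 1, tolerance = 1e-9)
})

test_that("a problem with no informative pairings returns the null row", {
  prob <- dvi_example(1)
  # cut all victims loose: no shared alleles with any reference family
  prob$victim_gt$L1[] <- c("9/9", "9/10", "9/10")
  B <- pairwise_lr_matrix(prob)
  rk <- joint_search(prob, threshold = 1e4)
  expect_equal(rk$LR[1], 1, tolerance = 1e-9)
  expect_equal(unname(unlist(rk[1, c("V1", "V2", "V3")])), c("*", "*", "*"))
})

test_that("the joint step cap rejects oversized enumerations", {
  expect_error(rank_assignments(dvi_example(1), cap = 5), "cap")
  expect_error(joint_search(dvi_example(2), threshold = 1e6, cap = 10),
               "threshold")
})

test_that("combined search equals the enumeration argmax on random problems", {
  set.seed(314)
  for (case in 1:8) {
    prob <- rand_problem(sample(2:4, 1), sample(2:4, 1))
    full <- rank_assignments(prob)
    for (T in c(2, 10, 1e4)) {
      jk <- joint_search(prob, threshold = T)
      expect_equal(jk$loglik[1], full$loglik[1], tolerance = 1e-9)
      # the reported optimum must be among the tied-top rows of the
      # exhaustive ranking
      tied <- full[full$loglik >= full$loglik[1] - 1e-9, , drop = FALSE]
      keys <- apply(tied[, prob$victims$id, drop = FALSE], 1,
                    paste, collapse = ",")
      expect_true(paste(jk[1, prob$victims$id], collapse = ",") %in% keys)
    }
  }
})
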