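# Assignment likelihoods, pairwise LR matrices, conditioning

test_that("toy problem 1 reproduces the hand-computable golden table", {
  prob <- dvi_example(1)
  expect_equal(assignment_loglik(prob, c("*", "*", "*")), log(4e-10),
               tolerance = 1e-9)
  expect_equal(lr_vs_null(prob, c("*", "*", "*")), 1, tolerance = 1e-9)
  expect_equal(lr_vs_null(prob, c("M1", "M2", "M3")), 250, tolerance = 1e-9)
  expect_equal(assignment_loglik(prob, c("M2", "M1", "M3")), -Inf)

  rk <- rank_assignments(prob)
  expect_equal(nrow(rk), 14)
  # ranked loglik/LR/posterior columns, top to bottom
  expect_equal(round(rk$loglik, 2),
               c(-16.12, -17.73, -18.42, rep(-20.03, 4), rep(-21.64, 3),
                 rep(-Inf, 4)))
  expect_equal(rk$LR, c(250, 50, 25, 5, 5, 5, 5, 1, 1, 1, 0, 0, 0, 0),
               tolerance = 1e-9)
  expect_equal(round(rk$posterior, 2),
               c(0.72, 0.14, 0.07, rep(0.01, 4), rep(0, 7)))
  expect_equal(unname(unlist(rk[1, c("V1", "V2", "V3")])),
               c("M1", "M2", "M3"))
  # non-increasing in loglik
  expect_false(is.unsorted(rev(rk$loglik)))
  # rejection of malformed assignments
  expect_error(assignment_loglik(prob, c("M1", "M1", "*")), "two victims")
  expect_error(assignment_loglik(prob, c("M3", "*", "*")), "sex-inconsistent")
})

test_that("pairwise LR matrices match the worked single-marker values", {
  B1 <- pairwise_lr_matrix(dvi_example(1))
  expect_equal(B1, rbind(V1 = c(1, 0, 0), V2 = c(1, 5, 0), V3 = c(0, 0, 5)),
               ignore_attr = TRUE, tolerance = 1e-9)
  B2 <- pairwise_lr_matrix(dvi_example(2))
  # grandfather column uninformative (all 1); V1=M2 is the top entry
  expect_equal(B2, rbind(V1 = c(1, 20, 10.5),
                         V2 = c(1, 0, 0.5),
                         V3 = c(1, 10, 5.5)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(max(B2), B2["V1", "M2"])
})

test_that("toy problem 2 reproduces its golden ranking", {
  prob <- dvi_example(2)
  rk <- rank_assignments(prob)
  expect_equal(nrow(rk), 34)
  top <- rk[1:6, ]
  expect_equal(unname(unlist(top[1, c("V1", "V2", "V3")])),
               c("M3", "M1", "M2"))
  expect_equal(top$LR, c(2000, 200, 200, 200, 100, 100), tolerance = 1e-9)
  expect_equal(round(top$loglik, 2),
               c(-15.67, -17.97, -17.97, -17.97, -18.67, -18.67))
  expect_equal(round(top$posterior[1], 2), 0.69)
  expect_equal(lr_vs_null(prob, c("M3", "M1", "M2")), 2000, tolerance = 1e-9)
})

test_that("full-data LR equals the reduced-problem LR", {
  expect_true(full_vs_reduced_lr_check(dvi_example(1)))
  expect_true(full_vs_reduced_lr_check(dvi_example(2)))
  set.seed(77)
  for (case in 1:8) {
    prob <- rand_problem(2, sample(2:3, 1))
    expect_true(full_vs_reduced_lr_check(prob))
  }
})

test_that("conditioning reproduces the worked updated matrices", {
  # toy 1: after fixing V2=M2 and V3=M3, the father becomes identifiable
  C1 <- conditioned_lr_matrix(dvi_example(1), c(V2 = "M2", V3 = "M3"))
  expect_equal(C1, rbind(V1 = 10), ignore_attr = TRUE, tolerance = 1e-9)
  expect_gt(C1["V1", "M1"], 1)
  # toy 2: fixing V1=M2 (genotype 1/1) blocks V2 (2/2) completely
  C2 <- conditioned_lr_matrix(dvi_example(2), c(V1 = "M2"))
  expect_equal(C2["V2", ], c(M1 = 0, M3 = 0))
  expect_equal(C2["V3", ], c(M1 = 10, M3 = 10), tolerance = 1e-9)
  # empty conditioning is the identity operation
  expect_equal(conditioned_lr_matrix(dvi_example(2), NULL),
               pairwise_lr_matrix(dvi_example(2)))
  expect_error(condition_problem(dvi_example(1), c(V1 = "M1", V2 = "M1")),
               "inconsistent")
})

test_that("conditional logliks telescope", {
  set.seed(42)
  for (case in 1:6) {
    prob <- rand_problem(3, 3)
    A <- enumerate_assignments(prob)
    full <- A[nrow(A), ]                    # a maximally-paired assignment
    fixed <- full[full != "*"]
    if (!length(fixed)) next
    f1 <- fixed[1]
    cond <- condition_problem(prob, f1)
    rest <- full[setdiff(names(full), names(f1))]
    lhs <- assignment_loglik(prob, full)
    base <- stats::setNames(rep("*", nrow(prob$victims)), prob$victims$id)
    base[names(f1)] <- f1
    rhs <- assignment_loglik(prob, base) +
      (assignment_loglik(cond, rest) -
         assignment_loglik(cond, rep("*", nrow(cond$victims))))
    if (is.infinite(lhs)) expect_true(is.infinite(rhs))
    else expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})
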