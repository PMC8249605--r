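# Assignment counting and enumeration

test_that("closed-form counts match known values", {
  expect_equal(count_assignments_nosex(0, 5), 1)
  expect_equal(count_assignments_nosex(1, 1), 2)
  expect_equal(count_assignments_nosex(5, 8), 19081)
  expect_equal(count_assignments(1, 2, 1, 2), 14)
  expect_equal(count_assignments(3, 2, 6, 6), 9847)
  expect_equal(count_assignments(0, 0, 4, 7), 1)
  expect_error(count_assignments_nosex(-1, 2), "non-negative")
  expect_error(count_assignments(1, 1, -2, 1), "non-negative")
})

test_that("the 5-victim/8-MP count grid is symmetric in the sex split", {
  grid <- outer(0:5, 0:8, Vectorize(function(sf, mf)
    count_assignments(sf, 5 - sf, mf, 8 - mf)))
  expect_equal(grid, grid[6:1, 9:1])           # swap the sex labels
  expect_equal(grid[1, 1], 19081)              # all same sex
  expect_true(all(grid[, 2:8] < 19081))        # mixed sexes always smaller
})

test_that("enumeration order is deterministic with '*' first", {
  prob <- dvi_example(1)
  A <- enumerate_assignments(prob)
  expect_equal(nrow(A), 14)
  expect_equal(unname(A[1, ]), c("*", "*", "*"))
  expect_equal(colnames(A), c("V1", "V2", "V3"))
  # V1 (male) may only take M1/M2; V3 (female) only M3
  expect_true(all(A[, "V1"] %in% c("*", "M1", "M2")))
  expect_true(all(A[, "V3"] %in% c("*", "M3")))
  expect_identical(A, enumerate_assignments(prob))
})

test_that("enumeration count matches the formula on random problems", {
  set.seed(301)
  for (case in 1:12) {
    s <- sample(0:4, 1); m <- sample(1:5, 1)
    prob <- rand_problem(max(s, 1), m)
    if (s == 0) prob <- local({
      p <- prob; p$victims <- p$victims[0, , drop = FALSE]
      p$victim_gt <- lapply(p$victim_gt, function(g) g[0]); p
    })
    A <- enumerate_assignments(prob)
    sf <- sum(prob$victims$sex == 2); sm <- sum(prob$victims$sex == 1)
    mp <- subset(as.data.frame(do.call(rbind, lapply(prob$families, function(f)
      cbind(f$missing, f$ped$sex[match(f$missing, f$ped$id)])))), TRUE)
    mf <- sum(mp[[2]] == "2"); mm <- sum(mp[[2]] == "1")
    expect_equal(nrow(A), count_assignments(sf, sm, mf, mm))
    # no duplicates; injectivity; sex consistency per row
    expect_false(anyDuplicated(apply(A, 1, paste, collapse = "\r")) > 0)
    for (r in seq_len(nrow(A)))
      expect_silent(dvimatch:::check_assignment(prob, A[r, ]))
    # ignore-sex mode reproduces the unknown-sex count
    expect_equal(nrow(enumerate_assignments(prob, ignore_sex = TRUE)),
                 count_assignments_nosex(nrow(prob$victims), nrow(mp)))
  }
})

test_that("forbidden pairs filter monotonically and exactly", {
  prob <- dvi_example(1)
  B <- pairwise_lr_matrix(prob)
  zero <- which(B == 0, arr.ind = TRUE)
  forb <- data.frame(victim = rownames(B)[zero[, 1]],
                     mp = colnames(B)[zero[, 2]])
  A_all <- enumerate_assignments(prob)
  A_flt <- enumerate_assignments(prob, forbidden = forb)
  expect_equal(nrow(A_flt), 10)  # the finite-likelihood assignments
  expect_lte(nrow(A_flt), nrow(A_all))
  # adding pairs never increases the count
  forb2 <- rbind(forb, data.frame(victim = "V1", mp = "M1"))
  expect_lt(nrow(enumerate_assignments(prob, forbidden = forb2)), nrow(A_flt))
  expect_error(enumerate_assignments(prob,
                                     forbidden = data.frame(victim = "V9",
                                                            mp = "M1")),
               "unknown victim")
})

test_that("degenerate problems enumerate to the single empty assignment", {
  prob <- dvi_example(1)
  prob$victims <- prob$victims[0, , drop = FALSE]
  prob$victim_gt <- lapply(prob$victim_gt, function(g) g[0])
  A <- enumerate_assignments(prob)
  expect_equal(nrow(A), 1)
  expect_equal(ncol(A), 0)
})

test_that("problem validation catches inconsistent declarations", {
  prob <- dvi_example(1)
  fams <- prob$families
  # same MP in two families
  fams[[2]]$missing <- c("M3", "M1")
  expect_error(dvi_problem(prob$victims, prob$victim_gt, fams, prob$db),
               "two families")
  # missing person genotyped
  fams <- prob$families
  fams[[1]]$gt$L1 <- c(fams[[1]]$gt$L1, c(M2 = "1/1"))
  expect_error(dvi_problem(prob$victims, prob$victim_gt, fams, prob$db),
               "genotyped")
  # no reference
  fams <- prob$families
  fams[[1]]$gt <- list()
  expect_error(dvi_problem(prob$victims, prob$victim_gt, fams, prob$db),
               "no genotyped reference")
  # victim/MP id overlap
  vict <- prob$victims; vict$id[1] <- "M1"
  expect_error(dvi_problem(vict, list(), prob$families, prob$db),
               "both a victim and a missing person")
})
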