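# Exact pedigree likelihoods: peeling vs brute force, closed forms,
# factorization, mutation handling

trio <- pedigree(c("FA", "MO", "CH"), c(NA, NA, "FA"), c(NA, NA, "MO"),
                 c(1, 2, 1))

test_that("closed-form cases: singletons, empty data, exclusions", {
  db <- equifreq_db(1, 10)
  single <- pedigree("A", NA, NA, 1)
  expect_equal(pedigree_loglik(single, list(L1 = c(A = "1/2")), db),
               log(0.02))
  expect_equal(pedigree_loglik_bruteforce(single, list(L1 = c(A = "1/2")), db),
               log(0.02))
  # untyped pedigree: empty product
  expect_equal(pedigree_loglik(trio, list(L1 = character(0)), db), 0)
  expect_equal(pedigree_loglik(trio, list(), db), 0)
  # Mendelian exclusion without mutation
  expect_equal(pedigree_loglik(trio, list(L1 = c(FA = "1/1", CH = "2/2")), db),
               -Inf)
  # parent-child: P(FA) * P(CH | FA) = p^2 * p for homozygous shares
  expect_equal(pedigree_loglik(trio, list(L1 = c(FA = "1/1", CH = "1/1")), db),
               log(0.01 * 0.1))
})

test_that("five unrelated singletons reproduce the toy null likelihood", {
  db <- equifreq_db(1, 10)
  ped <- pedigree(paste0("I", 1:5), rep(NA, 5), rep(NA, 5), c(1, 1, 2, 2, 2))
  data <- list(L1 = c(I1 = "1/1", I2 = "1/2", I3 = "3/4",
                      I4 = "2/2", I5 = "3/3"))
  expect_equal(pedigree_loglik(ped, data, db), log(4 * 0.1^10),
               tolerance = 1e-12)
  expect_equal(round(log(4 * 0.1^10), 2), -21.64)
})

test_that("peeling agrees with brute force on the toy families", {
  for (which in 1:2) {
    prob <- dvi_example(which)
    for (fam in prob$families) {
      data <- fam$gt
      expect_equal(pedigree_loglik(fam$ped, data, prob$db),
                   pedigree_loglik_bruteforce(fam$ped, data, prob$db),
                   tolerance = 1e-10)
      # also with victims inserted into missing slots
      a <- stats::setNames(fam$missing[1], prob$victims$id[1])
      data2 <- data
      g <- prob$victim_gt[[1]][prob$victims$id[1]]
      data2[[1]] <- c(data2[[1]], stats::setNames(g, fam$missing[1]))
      expect_equal(pedigree_loglik(fam$ped, data2, prob$db),
                   pedigree_loglik_bruteforce(fam$ped, data2, prob$db),
                   tolerance = 1e-10)
    }
  }
})

test_that("peeling equals brute force on random pedigrees and data", {
  set.seed(2024)
  for (case in 1:30) {
    cs <- rand_oracle_case()
    ped <- cs$ped; db <- cs$db; data <- cs$data
    ll1 <- pedigree_loglik(ped, data, db)
    ll2 <- pedigree_loglik_bruteforce(ped, data, db)
    if (is.infinite(ll1)) expect_identical(ll2, -Inf)
    else expect_equal(ll1, ll2, tolerance = 1e-10)
  }
})

test_that("peeling handles mutation models and matches brute force", {
  set.seed(99)
  db <- freq_db(list(X = c("1" = 0.5, "2" = 0.3, "3" = 0.2)))
  mod <- mutation_model(db, "proportional", 0.01)
  # exclusion becomes merely improbable under mutation
  data <- list(X = c(FA = "1/1", CH = "2/2"))
  ll <- pedigree_loglik(trio, data, db, mod)
  expect_gt(ll, -Inf)
  expect_equal(ll, pedigree_loglik_bruteforce(trio, data, db, mod),
               tolerance = 1e-10)
  for (case in 1:10) {
    ped <- rand_ped(sample(3:7, 1))
    data <- rand_data(ped, db, consistent = FALSE)
    expect_equal(pedigree_loglik(ped, data, db, mod),
                 pedigree_loglik_bruteforce(ped, data, db, mod),
                 tolerance = 1e-10)
  }
})

test_that("rate-0 proportional model reproduces the no-mutation likelihood", {
  set.seed(5)
  db <- equifreq_db(2, 4)
  mod0 <- mutation_model(db, "proportional", 0)
  for (case in 1:5) {
    ped <- rand_ped(6)
    data <- rand_data(ped, db, consistent = TRUE)
    expect_identical(pedigree_loglik(ped, data, db, mod0),
                     pedigree_loglik(ped, data, db))
  }
})

test_that("markers factorize and individual relabeling is neutral", {
  set.seed(12)
  db <- equifreq_db(2, 4)
  ped <- rand_ped(6)
  data <- rand_data(ped, db, consistent = TRUE)
  both <- pedigree_loglik(ped, data, db)
  m1 <- pedigree_loglik(ped, data["L1"], db)
  m2 <- pedigree_loglik(ped, data["L2"], db)
  expect_equal(both, m1 + m2, tolerance = 1e-12)

  relab <- stats::setNames(paste0("Z", seq_len(nrow(ped))), ped$id)
  ped2 <- pedigree(relab[ped$id],
                   ifelse(is.na(ped$fid), NA, relab[ped$fid]),
                   ifelse(is.na(ped$mid), NA, relab[ped$mid]),
                   ped$sex)
  data2 <- lapply(data, function(g) stats::setNames(g, relab[names(g)]))
  expect_equal(pedigree_loglik(ped2, data2, db), both, tolerance = 1e-12)
})

test_that("the brute-force guard rejects oversized instances", {
  db <- equifreq_db(1, 10)
  big <- rand_ped(12)
  expect_error(pedigree_loglik_bruteforce(big, list(L1 = character(0)), db,
                                          max_states = 1e4),
               "too large")
})
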