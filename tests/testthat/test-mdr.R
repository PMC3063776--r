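test_that("age quantile bins come from the training distribution", {
  b <- age_binning(1:100, k = 4)
  expect_identical(bin_age(b, 10), 1L)
  expect_identical(bin_age(b, 99), 4L)
  # clamping outside the training range
  expect_identical(bin_age(b, -5), 1L)
  expect_identical(bin_age(b, 150), 4L)

  # balanced occupancy within one individual for distinct ages
  set.seed(5)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    k <- sample(2:6, 1)
    ages <- sample(seq(40, 100, by = 0.01), n)
    b <- age_binning(ages, k)
    occ <- tabulate(bin_age(b, ages), nbins = k)
    expect_lte(diff(range(occ)), 1)
  }

  expect_error(age_binning(rep(70, 10), k = 4), "identical")
})

test_that("cells are labelled by the strict case:control ratio rule", {
  # training totals 349 cases / 216 controls (overall ratio 1.616); one
  # combination with 10 cases and 2 controls (ratio 5) and one with 1 case
  # and 1 control; the remainder sits in a third combination
  n_by_cell <- data.frame(
    CFH = c(1, 2, 0),
    n_case = c(10, 1, 338),
    n_control = c(2, 1, 213)
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(n_by_cell)), function(i) {
    data.frame(
      age = 60, smoking = 0, CFH = n_by_cell$CFH[i],
      ARMS2 = 0, CFB = 0, C3 = 0,
      status = rep(c(1, 0), c(n_by_cell$n_case[i], n_by_cell$n_control[i]))
    )
  }))
  m <- mdr_build(as_amd_cohort(rows), k = 1)
  expect_equal(m$overall_ratio, 349 / 216)
  label_of <- function(cfh) m$cells$label[m$cells$CFH == cfh]
  expect_identical(label_of(1), "high")  # 5 > 1.616
  expect_identical(label_of(2), "low")   # 1 < 1.616
})

test_that("a cell ratio exactly equal to the overall ratio is low-risk", {
  # overall ratio 1; a 1:1 cell does not exceed it
  d <- data.frame(
    age = rep(c(55, 56, 57, 58), 2),
    smoking = 0, CFH = rep(0:1, each = 4), ARMS2 = 0, CFB = 0, C3 = 0,
    status = rep(c(1, 0), 4)
  )
  d$age <- rep(60, 8)  # single combination per CFH level
  m <- mdr_build(as_amd_cohort(d), k = 1)
  expect_true(all(m$cells$label == "low"))
})

test_that("cells with a single class take the extreme labels", {
  d <- data.frame(
    age = 60, smoking = 0, CFH = c(0, 0, 1, 1), ARMS2 = 0, CFB = 0,
    C3 = c(0, 0, 1, 1), status = c(1, 1, 0, 0)
  )
  m <- mdr_build(as_amd_cohort(d), k = 1)
  expect_identical(m$cells$label[m$cells$CFH == 0], "high")  # cases only
  expect_identical(m$cells$label[m$cells$CFH == 1], "low")   # controls only
})

test_that("classification matches the model cells and flags unseen combinations", {
  train <- toy_cohort(120, seed = 8)
  m <- mdr_build(train, k = 3)
  test <- toy_cohort(80, seed = 9)
  calls <- mdr_classify(m, test)
  expect_true(all(calls %in% c("high", "low", "cnc")))
  expect_identical(calls, mdr_oracle(train, test, k = 3))

  # an impossible combination is could-not-classify
  unseen <- as_amd_cohort(data.frame(age = 60, smoking = 1, CFH = 2,
                                     ARMS2 = 2, CFB = 2, C3 = 2, status = 1))
  expect_identical(mdr_classify(m, unseen), "cnc")
})

test_that("the model is invariant to training row order", {
  train <- toy_cohort(150, seed = 10)
  test <- toy_cohort(60, seed = 11)
  m1 <- mdr_build(train, k = 4)
  set.seed(1)
  shuffled <- as_amd_cohort(train[sample(nrow(train)), ])
  m2 <- mdr_build(shuffled, k = 4)
  expect_equal(m1$cells, m2$cells)
  expect_identical(mdr_classify(m1, test), mdr_classify(m2, test))
})

test_that("with one age bin and constant smoking the model is a genotype lookup", {
  train <- toy_cohort(200, seed = 12)
  train$smoking <- 0L
  train <- as_amd_cohort(train)
  m <- mdr_build(train, k = 1)
  geno_key <- function(d) paste(d$CFH, d$ARMS2, d$CFB, d$C3)
  expect_identical(nrow(m$cells), length(unique(geno_key(train))))
  test <- toy_cohort(50, seed = 13)
  test$smoking <- 0L
  test <- as_amd_cohort(test)
  # lookup oracle on genotypes alone
  overall <- sum(train$status == 1) / sum(train$status == 0)
  expected <- vapply(geno_key(test), function(k_) {
    hit <- geno_key(train) == k_
    if (!any(hit)) return("cnc")
    nca <- sum(train$status[hit] == 1); nco <- sum(train$status[hit] == 0)
    if (nco == 0) "high" else if (nca / nco > overall) "high" else "low"
  }, character(1), USE.NAMES = FALSE)
  expect_identical(mdr_classify(m, test), expected)
})

test_that("could-not-classify rates at clinic-like sizes are moderate", {
  spec_tr <- cohort_preset("vm_training")
  spec_te <- cohort_preset("vm_testing")
  rates <- numeric(20)
  for (r in 1:20) {
    spec_tr$seed <- r
    spec_te$seed <- 10000 + r
    m <- mdr_build(generate_cohort(spec_tr))
    calls <- mdr_classify(m, generate_cohort(spec_te))
    rates[r] <- mean(calls == "cnc")
  }
  # synthetic cohorts are iid draws with no family structure or cohort
  # heterogeneity, so unclassifiable fractions run somewhat below the
  # ~20% seen in heterogeneous clinical samples
  expect_true(all(rates > 0.03 & rates < 0.35))
  expect_gt(mean(rates), 0.08)
})

test_that("an MDR model round-trips through its TSV serialization", {
  train <- toy_cohort(150, seed = 14)
  test <- toy_cohort(60, seed = 15)
  m <- mdr_build(train, k = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mdr(m, path)
  m2 <- read_mdr(path)
  expect_equal(m2$overall_ratio, m$overall_ratio, tolerance = 1e-10)
  expect_equal(m2$binning$edges, m$binning$edges, tolerance = 1e-10)
  expect_identical(mdr_classify(m2, test), mdr_classify(m, test))
})
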