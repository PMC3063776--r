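# build a genome from codon values (8 bits each, most significant bit first)
codon_genome <- function(codons) {
  bits <- unlist(lapply(codons, function(v) {
    as.integer(intToBits(v))[8:1]
  }))
  as.integer(bits)
}

# codons deriving the flat topology with chosen leaf weights/inputs and a
# zero bias, following the grammar by hand:
#   net choice, then per leaf {sign, digit, digit, input}, then bias choice
flat_codons <- function(weights, inputs, bias = NULL) {
  stopifnot(length(weights) == 6, length(inputs) == 6)
  input_idx <- match(inputs, factor_names()) - 1L
  codons <- c(0L)  # topology: flat
  for (i in 1:6) {
    w <- weights[i]
    codons <- c(codons,
                if (w < 0) 1L else 0L,            # sign
                abs(trunc(w)),                    # integer digit
                round((abs(w) - abs(trunc(w))) * 10),  # tenths digit
                input_idx[i])                     # input choice
  }
  if (is.null(bias)) {
    codons <- c(codons, 1L)                       # bias -> 0
  } else {
    codons <- c(codons, 0L,
                if (bias < 0) 1L else 0L,
                abs(trunc(bias)),
                round((abs(bias) - abs(trunc(bias))) * 10))
  }
  as.integer(codons)
}

test_that("genome mapping is deterministic and follows the grammar", {
  g0 <- codon_genome(rep(0L, 40))
  n1 <- map_genome(g0)
  n2 <- map_genome(g0)
  expect_identical(n1, n2)
  # all-zero codons always pick the first alternative: flat topology,
  # weight +0.0 on the first input everywhere
  expect_s3_class(n1, "genn_invalid")  # same input six times
  expect_identical(n1$reason, "constraint")

  # a hand-derived codon sequence builds each factor exactly once
  g <- codon_genome(flat_codons(c(1.5, -2.0, 9.9, 0.1, -0.7, 3.0),
                                factor_names()))
  net <- map_genome(g)
  expect_s3_class(net, "genn_network")
  expect_true(constraint_check(net))
  expect_equal(unname(net$coefficients),
               c(1.5, -2.0, 9.9, 0.1, -0.7, 3.0), tolerance = 1e-12)
  expect_identical(net$bias, 0)

  # too short a genome with no wrapping allowed is invalid, not an error
  short <- map_genome(codon_genome(c(0L, 0L, 0L, 0L)), max_wraps = 0L)
  expect_s3_class(short, "genn_invalid")
  expect_identical(short$reason, "incomplete")
})

test_that("forward pass matches hand arithmetic and the boundary rule", {
  ind <- as_amd_cohort(data.frame(age = 60, smoking = 1, CFH = 2, ARMS2 = 1,
                                  CFB = 0, C3 = 1, status = 1))
  binning <- age_binning(c(50, 60, 70, 80, 90, 100), k = 4)
  x <- c(age = bin_age(binning, 60), smoking = 1, CFH = 2, ARMS2 = 1,
         CFB = 0, C3 = 1)

  weight_sets <- list(
    c(0.5, -1.0, 2.0, 0.0, 3.0, -0.5),
    c(9.9, 9.9, 9.9, 9.9, 9.9, 9.9),
    c(-0.1, 0.2, -0.3, 0.4, -0.5, 0.6)
  )
  for (w in weight_sets) {
    net <- map_genome(codon_genome(flat_codons(w, factor_names())))
    expect_equal(genn_score(net, ind, binning),
                 plogis(sum(w * x)), tolerance = 1e-12)
  }

  # all weights zero: sigmoid(0) = 0.5, called high under the >= rule
  zero_net <- map_genome(codon_genome(flat_codons(rep(0, 6), factor_names())))
  expect_equal(genn_score(zero_net, ind, binning), 0.5)
  expect_identical(genn_classify(zero_net, ind, binning), "high")

  # negating every weight flips calls strictly off the boundary
  w <- weight_sets[[3]]
  net_pos <- map_genome(codon_genome(flat_codons(w, factor_names())))
  net_neg <- map_genome(codon_genome(flat_codons(-w, factor_names())))
  expect_false(genn_score(net_pos, ind, binning) == 0.5)
  expect_false(genn_classify(net_pos, ind, binning) ==
                 genn_classify(net_neg, ind, binning))
})

test_that("balanced accuracy matches a brute-force confusion computation", {
  coh <- toy_cohort(50, seed = 20)
  expect_equal(balanced_accuracy(rep("high", 50), coh$status), 0.5)
  expect_equal(balanced_accuracy(ifelse(coh$status == 1, "high", "low"),
                                 coh$status), 1.0)
  expect_error(balanced_accuracy(rep("high", 3), c(1, 1, 1)), "both cases")

  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    status <- c(0, 1, rbinom(n - 2, 1, 0.5))
    calls <- sample(c("high", "low"), n, replace = TRUE)
    tp <- sum(calls == "high" & status == 1)
    tn <- sum(calls == "low" & status == 0)
    expected <- (tp / sum(status == 1) + tn / sum(status == 0)) / 2
    expect_equal(balanced_accuracy(calls, status), expected)
  }
})

test_that("evolution is reproducible, elitist and constraint-satisfying", {
  coh <- single_factor_cohort(seed = 31, n = 200)
  cfg <- genn_config(pop_size = 120, generations = 8, seed = 5)
  fit1 <- genn_evolve(coh, cfg)
  fit2 <- genn_evolve(coh, cfg)
  expect_identical(fit1$network, fit2$network)
  expect_identical(fit1$fitness, fit2$fitness)

  expect_true(constraint_check(fit1$network))
  # best-so-far fitness never decreases under elitism
  expect_true(all(diff(fit1$history) >= 0))
  # the returned model is at least as fit as the best initial individual
  expect_gte(fit1$fitness, fit1$history[1])

  # serialization round trip preserves behaviour
  path <- withr::local_tempfile(fileext = ".txt")
  write_genn(fit1, path)
  back <- read_genn(path)
  expect_equal(back$network$coefficients, fit1$network$coefficients,
               tolerance = 1e-10)
  test <- single_factor_cohort(seed = 32, n = 100)
  expect_identical(genn_classify(back$network, test, back$binning),
                   genn_classify(fit1$network, test, fit1$binning))
})
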