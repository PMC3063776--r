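#' Grammar for evolvable weighted-addition risk networks
#'
#' Defines the production rules used to map a binary genome onto a neural
#' network over the six susceptibility factors.  The networks are built
#' from weighted-addition (PADD) nodes: either a single flat PADD combining
#' all six weighted inputs, or a two-hub topology in which two PADD hubs
#' (splitting the inputs 2+4, 3+3 or 4+2) feed a weighted output PADD - the
#' hub-and-spoke shape seen when these networks are trained on real AMD
#' cohorts, where genetic and environmental factors tend to separate into
#' hubs.  An optional bias term enters the output node, weights are signed
#' one-decimal constants built by digit concatenation (-9.9 to 9.9), and
#' the output passes through a sigmoid.  Input choices are free during
#' derivation; networks that do not contain each of the six factors exactly
#' once are invalid and receive zero fitness.
#'
#' Productions (alternatives chosen by successive codons, `codon mod
#' n_alternatives`; rules with a single alternative consume no codon):
#'
#' ```
#' <net>    ::= sig(PADD(<leaf> x6, <bias>))
#'            | sig(PADD(<w>*<hub2>, <w>*<hub4>, <bias>))
#'            | sig(PADD(<w>*<hub3>, <w>*<hub3>, <bias>))
#'            | sig(PADD(<w>*<hub4>, <w>*<hub2>, <bias>))
#' <hubN>   ::= PADD(<leaf> xN)
#' <leaf>   ::= <w> * <input>
#' <input>  ::= age | smoking | CFH | ARMS2 | CFB | C3
#' <bias>   ::= <w> | 0
#' <w>      ::= <sign><digit>.<digit>
#' <sign>   ::= + | -
#' <digit>  ::= 0 | 1 | ... | 9
#' ```
#'
#' @return An object of class `genn_grammar` holding the rule table.
#' @export
genn_grammar <- function() {
  structure(
    list(
      topologies = list(
        flat = c(6L),
        split_2_4 = c(2L, 4L),
        split_3_3 = c(3L, 3L),
        split_4_2 = c(4L, 2L)
      ),
      inputs = factor_names(),
      signs = c(1, -1),
      digits = 0:9
    ),
    class = "genn_grammar"
  )
}

#' Construct a random binary genome
#'
#' Genomes are bitstrings read as 8-bit codons; lengths are drawn uniformly
#' over whole codons within the allowed 25-1000 bit range.
#'
#' @param bits genome length in bits; when `NULL` a random multiple of 8 in
#'   `[32, 1000]` is drawn.
#' @return Integer vector of 0/1 bits.
#' @export
random_genome <- function(bits = NULL) {
  if (is.null(bits)) bits <- 8L * sample(4:125, 1L)
  stopifnot(bits >= 25L, bits <= 1000L)
  sample(c(0L, 1L), bits, replace = TRUE)
}

# stateful codon reader with genome wrapping
codon_reader <- function(bits, max_wraps) {
  n_codons <- length(bits) %/% 8L
  if (n_codons == 0L) {
    return(list(choose = function(n) NULL))
  }
  codons <- as.integer(
    crossprod(matrix(bits[seq_len(8L * n_codons)], nrow = 8L),
              2L^(7:0))
  )
  pos <- 0L
  wraps <- 0L
  list(choose = function(n) {
    if (n == 1L) return(1L)
    pos <<- pos + 1L
    if (pos > n_codons) {
      wraps <<- wraps + 1L
      if (wraps > max_wraps) return(NULL)
      pos <<- 1L
    }
    codons[pos] %% n + 1L
  })
}

#' Map a genome to a risk network via the grammar
#'
#' Standard grammatical-evolution mapping: codons are read left to right
#' and each selects a production alternative by `codon mod n_alternatives`;
#' when the genome is exhausted, reading wraps to the start up to
#' `max_wraps` times.  A derivation that remains incomplete after the wrap
#' cap, or a completed network that does not contain every one of the six
#' factors exactly once, is returned as invalid - invalidity is a value
#' (fitness zero during evolution), not an error.
#'
#' @param genome bit vector from [random_genome()].
#' @param grammar a [genn_grammar()].
#' @param max_wraps wrap cap (default 2).
#' @return A `genn_network` object, or an object of class `genn_invalid`
#'   whose `reason` is `"incomplete"` or `"constraint"`.
#' @export
map_genome <- function(genome, grammar = genn_grammar(), max_wraps = 2L) {
  stopifnot(inherits(grammar, "genn_grammar"))
  reader <- codon_reader(genome, max_wraps)
  invalid <- function(reason) structure(list(reason = reason),
                                        class = "genn_invalid")
  derive_weight <- function() {
    s <- reader$choose(2L); if (is.null(s)) return(NULL)
    d1 <- reader$choose(10L); if (is.null(d1)) return(NULL)
    d2 <- reader$choose(10L); if (is.null(d2)) return(NULL)
    grammar$signs[s] * (grammar$digits[d1] + grammar$digits[d2] / 10)
  }
  derive_leaf <- function() {
    w <- derive_weight(); if (is.null(w)) return(NULL)
    i <- reader$choose(length(grammar$inputs)); if (is.null(i)) return(NULL)
    list(weight = w, input = grammar$inputs[i])
  }

  topo_idx <- reader$choose(length(grammar$topologies))
  if (is.null(topo_idx)) return(invalid("incomplete"))
  topo_name <- names(grammar$topologies)[topo_idx]
  hub_sizes <- grammar$topologies[[topo_idx]]

  hub_weights <- numeric(0)
  leaf_inputs <- character(0)
  leaf_weights <- numeric(0)
  leaf_hub <- integer(0)
  for (h in seq_along(hub_sizes)) {
    hw <- 1
    if (length(hub_sizes) > 1L) {     # hubs enter the output PADD weighted
      hw <- derive_weight()
      if (is.null(hw)) return(invalid("incomplete"))
    }
    hub_weights <- c(hub_weights, hw)
    for (l in seq_len(hub_sizes[h])) {
      leaf <- derive_leaf()
      if (is.null(leaf)) return(invalid("incomplete"))
      leaf_inputs <- c(leaf_inputs, leaf$input)
      leaf_weights <- c(leaf_weights, leaf$weight)
      leaf_hub <- c(leaf_hub, h)
    }
  }
  bias_choice <- reader$choose(2L)
  if (is.null(bias_choice)) return(invalid("incomplete"))
  bias <- 0
  if (bias_choice == 1L) {
    bias <- derive_weight()
    if (is.null(bias)) return(invalid("incomplete"))
  }

  if (!constraint_check(leaf_inputs, grammar)) return(invalid("constraint"))

  # PADD nodes are linear, so the whole network collapses to an effective
  # linear score per input: leaf weight times the weight of its hub arc.
  coefs <- setNames(leaf_weights * hub_weights[leaf_hub], leaf_inputs)
  structure(
    list(topology = topo_name, hub_sizes = hub_sizes,
         hub_weights = hub_weights, leaf_inputs = leaf_inputs,
         leaf_weights = leaf_weights, leaf_hub = leaf_hub, bias = bias,
         coefficients = coefs[factor_names()]),
    class = "genn_network"
  )
}

#' Check the every-factor-exactly-once network constraint
#'
#' Only networks containing all six susceptibility factors exactly once are
#' propagated during evolution: the search optimizes weights and wiring but
#' is not allowed to perform variable selection.
#'
#' @param leaf_inputs character vector of the input factor at each leaf, or
#'   a `genn_network`.
#' @param grammar a [genn_grammar()].
#' @return `TRUE` or `FALSE`.
#' @export
constraint_check <- function(leaf_inputs, grammar = genn_grammar()) {
  if (inherits(leaf_inputs, "genn_network")) {
    leaf_inputs <- leaf_inputs$leaf_inputs
  }
  length(leaf_inputs) == length(grammar$inputs) &&
    setequal(leaf_inputs, grammar$inputs) &&
    !anyDuplicated(leaf_inputs)
}

#' @export
print.genn_network <- function(x, ...) {
  leaf_str <- function(idx) {
    paste(sprintf("%+.1f*%s", x$leaf_weights[idx], x$leaf_inputs[idx]),
          collapse = ", ")
  }
  if (x$topology == "flat") {
    body <- sprintf("PADD(%s)", leaf_str(seq_along(x$leaf_inputs)))
  } else {
    hubs <- vapply(seq_along(x$hub_sizes), function(h) {
      sprintf("%+.1f*PADD(%s)", x$hub_weights[h], leaf_str(which(x$leaf_hub == h)))
    }, character(1))
    body <- sprintf("PADD(%s)", paste(hubs, collapse = ", "))
  }
  cat(sprintf("GENN network [%s]: sig(%s %+.1f)\n", x$topology, body, x$bias))
  invisible(x)
}

# design matrix for network evaluation: age replaced by its quantile bin
genn_design <- function(cohort, binning) {
  X <- as.matrix(cohort[, factor_names(), drop = FALSE])
  X[, "age"] <- bin_age(binning, cohort$age)
  X
}

#' Network output scores for a cohort
#'
#' Forward pass: each hub computes its weighted sum of inputs, the output
#' PADD combines the weighted hubs and the bias, and the result passes
#' through a sigmoid.  Age is encoded as its training-derived quantile bin.
#'
#' @param network a valid `genn_network`.
#' @param cohort an `amd_cohort`.
#' @param binning the [age_binning()] learned on the training cohort.
#' @return Numeric vector of sigmoid outputs in (0, 1).
#' @export
genn_score <- function(network, cohort, binning) {
  if (inherits(network, "genn_invalid")) {
    stop("cannot evaluate an invalid network (", network$reason, ")",
         call. = FALSE)
  }
  stopifnot(inherits(network, "genn_network"))
  X <- genn_design(cohort, binning)
  plogis(network$bias + drop(X %*% network$coefficients))
}

#' Risk calls from a network
#'
#' Sigmoid outputs at or above 0.5 (equivalently, a non-negative weighted
#' sum) are called high-risk.
#'
#' @inheritParams genn_score
#' @return Character vector of `"high"` / `"low"` calls.
#' @export
genn_classify <- function(network, cohort, binning) {
  ifelse(genn_score(network, cohort, binning) >= 0.5, "high", "low")
}

#' Balanced accuracy of risk calls
#'
#' The fitness function of the evolutionary search:
#' `(sensitivity + specificity) / 2` of high/low calls against true status.
#' `"cnc"` calls count as misclassifications of their class.
#'
#' @param calls character vector of `"high"` / `"low"` (or `"cnc"`) calls.
#' @param status binary truth, 1 = case, 0 = control.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(calls, status) {
  stopifnot(length(calls) == length(status))
  status <- as.integer(status)
  if (length(unique(status)) < 2L) {
    stop("balanced accuracy requires both cases and controls", call. = FALSE)
  }
  sens <- mean(calls[status == 1L] == "high")
  spec <- mean(calls[status == 0L] == "low")
  (sens + spec) / 2
}

#' Configuration of the evolutionary search
#'
#' Defaults follow the published settings: population 5000, crossover
#' probability 0.9, per-bit mutation probability 0.01, genome sizes of
#' 25-1000 bits.  Generation count, tournament size and elitism are not
#' published settings and default to standard practice (50 generations,
#' binary tournament, one elite).
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations after initialization.
#' @param p_crossover probability of a crossover event per offspring.
#' @param p_mutation per-bit mutation probability.
#' @param tournament tournament size for parent selection.
#' @param elitism number of best genomes copied unchanged each generation.
#' @param max_wraps genome wrap cap during mapping.
#' @param seed integer seed for the whole run.
#' @return A list of class `genn_config`.
#' @export
genn_config <- function(pop_size = 5000L, generations = 50L,
                        p_crossover = 0.9, p_mutation = 0.01,
                        tournament = 2L, elitism = 1L, max_wraps = 2L,
                        seed = 1L) {
  stopifnot(pop_size >= 2L, generations >= 1L,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            tournament >= 1L, elitism >= 0L)
  structure(
    list(pop_size = as.integer(pop_size), generations = as.integer(generations),
         p_crossover = p_crossover, p_mutation = p_mutation,
         tournament = as.integer(tournament), elitism = as.integer(elitism),
         max_wraps = as.integer(max_wraps), seed = as.integer(seed)),
    class = "genn_config"
  )
}

#' Evolve a risk network on a training cohort
#'
#' Grammatical evolution: a random population of genomes is mapped to
#' networks, scored by balanced accuracy on the training cohort (invalid
#' networks - incomplete derivations or constraint failures - score zero),
#' and evolved by tournament selection, single-point crossover and per-bit
#' mutation with elitism.  The best constraint-satisfying network found at
#' any point is returned; under elitism its fitness is non-decreasing over
#' generations.  The run is fully reproducible from `config$seed`.
#'
#' @param cohort training `amd_cohort` with both classes present.
#' @param config a [genn_config()].
#' @param grammar a [genn_grammar()].
#' @param binning an [age_binning()]; defaults to quartiles of the training
#'   ages.
#' @return A list of class `genn_fit` with `network` (best `genn_network`),
#'   `fitness` (its training balanced accuracy), `genome`, `binning`, and
#'   `history` (best-so-far fitness per generation, starting at the initial
#'   population).
#' @export
genn_evolve <- function(cohort, config = genn_config(),
                        grammar = genn_grammar(), binning = NULL) {
  stopifnot(inherits(cohort, "amd_cohort"), inherits(config, "genn_config"))
  if (length(unique(cohort$status)) < 2L) {
    stop("training cohort must contain both cases and controls", call. = FALSE)
  }
  if (is.null(binning)) binning <- age_binning(cohort$age, 4L)
  set.seed(config$seed)
  X <- genn_design(cohort, binning)
  status <- as.integer(cohort$status)
  n1 <- sum(status == 1L)
  n0 <- sum(status == 0L)

  eval_genome <- function(genome) {
    net <- map_genome(genome, grammar, config$max_wraps)
    if (inherits(net, "genn_invalid")) {
      return(list(fitness = 0, network = NULL))
    }
    score <- net$bias + drop(X %*% net$coefficients)
    high <- score >= 0
    sens <- sum(high & status == 1L) / n1
    spec <- sum(!high & status == 0L) / n0
    list(fitness = (sens + spec) / 2, network = net)
  }

  pop <- lapply(seq_len(config$pop_size), function(i) random_genome())
  fitness <- numeric(config$pop_size)
  best <- list(fitness = -Inf, network = NULL, genome = NULL)
  history <- numeric(config$generations + 1L)

  evaluate_pop <- function() {
    for (i in seq_len(config$pop_size)) {
      ev <- eval_genome(pop[[i]])
      fitness[i] <<- ev$fitness
      if (!is.null(ev$network) && ev$fitness > best$fitness) {
        best <<- list(fitness = ev$fitness, network = ev$network,
                      genome = pop[[i]])
      }
    }
  }
  select_parent <- function() {
    cand <- sample.int(config$pop_size, config$tournament, replace = TRUE)
    cand[which.max(fitness[cand])]
  }

  evaluate_pop()
  history[1L] <- if (is.finite(best$fitness)) best$fitness else NA_real_
  for (gen in seq_len(config$generations)) {
    newpop <- vector("list", config$pop_size)
    n_elite <- min(config$elitism, config$pop_size)
    if (n_elite > 0L) {
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(n_elite)]
      newpop[seq_len(n_elite)] <- pop[elite_idx]
    }
    for (i in seq.int(n_elite + 1L, config$pop_size)) {
      p1 <- pop[[select_parent()]]
      child <- p1
      if (runif(1) < config$p_crossover) {
        p2 <- pop[[select_parent()]]
        cut <- sample.int(min(length(p1), length(p2)) - 1L, 1L)
        child <- c(p1[seq_len(cut)], p2[seq.int(cut + 1L, length(p2))])
      }
      flip <- runif(length(child)) < config$p_mutation
      child[flip] <- 1L - child[flip]
      newpop[[i]] <- child
    }
    pop <- newpop
    evaluate_pop()
    history[gen + 1L] <- if (is.finite(best$fitness)) best$fitness else NA_real_
  }
  if (is.null(best$network)) {
    stop("no constraint-satisfying network found in any generation",
         call. = FALSE)
  }
  structure(
    list(network = best$network, fitness = best$fitness, genome = best$genome,
         binning = binning, history = history, config = config),
    class = "genn_fit"
  )
}

#' @export
print.genn_fit <- function(x, ...) {
  cat(sprintf("GENN fit: training balanced accuracy %.3f after %d generations\n",
              x$fitness, x$config$generations))
  print(x$network)
  invisible(x)
}

#' Serialize a network and its age binning to plain text
#'
#' Writes an explicit node list: one line per node (output PADD, hub PADDs,
#' input leaves and bias) with arc weights, plus the age-bin edges needed to
#' evaluate new individuals.
#'
#' @param fit a `genn_fit` or a list with `network` and `binning`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genn <- function(fit, path) {
  net <- fit$network
  b <- fit$binning
  lines <- c(
    sprintf("topology\t%s", net$topology),
    sprintf("hub_sizes\t%s", paste(net$hub_sizes, collapse = ",")),
    sprintf("hub_weights\t%s", paste(net$hub_weights, collapse = ",")),
    sprintf("leaf_inputs\t%s", paste(net$leaf_inputs, collapse = ",")),
    sprintf("leaf_weights\t%s", paste(net$leaf_weights, collapse = ",")),
    sprintf("leaf_hub\t%s", paste(net$leaf_hub, collapse = ",")),
    sprintf("bias\t%s", net$bias),
    sprintf("age_k\t%d", b$k),
    sprintf("age_edges\t%s", paste(b$edges, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a network written by [write_genn()]
#'
#' @param path input path.
#' @return A list with `network` (`genn_network`) and `binning`
#'   ([age_binning()]).
#' @export
read_genn <- function(path) {
  kv <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  val <- function(k) kv$V2[kv$V1 == k]
  nums <- function(k) as.numeric(strsplit(val(k), ",")[[1L]])
  leaf_inputs <- strsplit(val("leaf_inputs"), ",")[[1L]]
  leaf_weights <- nums("leaf_weights")
  leaf_hub <- as.integer(nums("leaf_hub"))
  hub_weights <- nums("hub_weights")
  coefs <- setNames(leaf_weights * hub_weights[leaf_hub], leaf_inputs)
  network <- structure(
    list(topology = val("topology"),
         hub_sizes = as.integer(nums("hub_sizes")),
         hub_weights = hub_weights,
         leaf_inputs = leaf_inputs,
         leaf_weights = leaf_weights,
         leaf_hub = leaf_hub,
         bias = as.numeric(val("bias")),
         coefficients = coefs[factor_names()]),
    class = "genn_network"
  )
  binning <- structure(
    list(k = as.integer(val("age_k")), edges = nums("age_edges")),
    class = "age_binning"
  )
  list(network = network, binning = binning)
}
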