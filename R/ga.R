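## ga_optimizer: real-valued genetic algorithm over universal centroids.

GENOME_LENGTH <- 32L  # 6 centroids x 5 coordinates + C + P

#' Genetic-algorithm configuration
#'
#' Defaults follow the search that optimized the universal centroids: 400
#' random individuals initially, the best 200 kept as parents, 200 children
#' per generation built by exchanging 1-6 centroids (whole or partial) and
#' optionally the C/P weights, 2-4 genome entries mutated by a uniform
#' increment in [-1, 1], and a stop after 20 generations without improvement
#' of the best fitness. Random initialization samples centroid positions in
#' a 30 x 30 x 30 Angstrom box around the superposed-structure center.
#'
#' @param init_population initial population size (default 400).
#' @param survivors parents kept per generation (default 200; also the
#'   steady-state population size).
#' @param children children generated per generation (default 200).
#' @param crossover_range range of centroid counts exchanged (default 1-6).
#' @param crossover_mode `"whole"` (default) swaps complete centroids,
#'   `"partial"` swaps a random subset of each chosen centroid's 5
#'   coordinates.
#' @param mutation_count_range entries mutated per child (default 2-4).
#' @param mutation_increment uniform increment bounds (default c(-1, 1)).
#' @param stagnation generations without improvement before stopping
#'   (default 20).
#' @param max_generations hard cap on generations (default 500).
#' @param init_mode `"random"` (in the box) or `"tol"` (seeded from average
#'   tip-of-loop positions).
#' @param box_size edge of the random-initialization box in Angstrom
#'   (default 30).
#' @param seed RNG seed; the whole run is reproducible from it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(init_population = 400L, survivors = 200L,
                      children = 200L, crossover_range = c(1L, 6L),
                      crossover_mode = c("whole", "partial"),
                      mutation_count_range = c(2L, 4L),
                      mutation_increment = c(-1, 1), stagnation = 20L,
                      max_generations = 500L,
                      init_mode = c("random", "tol"), box_size = 30,
                      seed = 1L) {
  crossover_mode <- match.arg(crossover_mode)
  init_mode <- match.arg(init_mode)
  stopifnot(is_count(init_population), is_count(survivors),
            is_count(children), is_count(stagnation),
            is_count(max_generations),
            length(crossover_range) == 2L,
            crossover_range[1] >= 1, crossover_range[2] <= 6,
            crossover_range[1] <= crossover_range[2],
            length(mutation_count_range) == 2L,
            mutation_count_range[1] <= mutation_count_range[2],
            mutation_count_range[1] >= 0,
            length(mutation_increment) == 2L,
            mutation_increment[1] <= mutation_increment[2],
            box_size > 0)
  structure(list(init_population = as.integer(init_population),
                 survivors = as.integer(survivors),
                 children = as.integer(children),
                 crossover_range = as.integer(crossover_range),
                 crossover_mode = crossover_mode,
                 mutation_count_range = as.integer(mutation_count_range),
                 mutation_increment = as.numeric(mutation_increment),
                 stagnation = as.integer(stagnation),
                 max_generations = as.integer(max_generations),
                 init_mode = init_mode, box_size = as.numeric(box_size),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Build a GA training set from CDR sets
#'
#' Packs property-assigned CDR sets (structures already superposed into the
#' canonical frame) into the flat form the GA fitness functions consume: per
#' TCR, the pooled atom coordinates with *raw* charge and logP (the genome's
#' C and P re-weight them), the tip-of-loop CA positions, and the peptide
#' label.
#'
#' @param cdr_sets list of [assign_properties()] results.
#' @param labels peptide label per TCR (same order).
#' @return object of class `ga_set`.
#' @export
make_ga_set <- function(cdr_sets, labels) {
  stopifnot(length(cdr_sets) == length(labels), length(cdr_sets) >= 2L)
  entries <- lapply(cdr_sets, function(cdrs) {
    stopifnot(inherits(cdrs, "cdr_set"))
    if (is.null(cdrs$C)) stop("CDR sets must have assigned properties")
    atoms <- do.call(rbind, lapply(cdrs$loops, function(at) {
      as.matrix(at[, c("x", "y", "z", "charge", "logp")])
    }))
    tol <- place_centroids_tol(cdrs)
    ## store tip coordinates with raw (unweighted) charge/logP
    tips <- tol$coords
    tips[, 4] <- tips[, 4] / cdrs$C
    tips[, 5] <- tips[, 5] / cdrs$P
    list(id = cdrs$tcr_id, atoms = atoms, tips = tips)
  })
  structure(list(entries = entries, ids = vapply(entries, `[[`, "", "id"),
                 labels = as.character(labels)),
            class = "ga_set")
}

## 18-value fingerprint matrix of a ga_set under a genome
ga_fp_matrix <- function(genome, set, third_moment = "cbrt") {
  C <- genome[31L]
  P <- genome[32L]
  if (C <= 0 || P <= 0) stop("genome weights C and P must be positive")
  cen <- matrix(genome[1:30], 6L, 5L, byrow = TRUE)
  t(vapply(set$entries, function(e) {
    atoms <- e$atoms
    atoms[, 4] <- C * atoms[, 4]
    atoms[, 5] <- P * atoms[, 5]
    es5d_values(atoms, cen, third_moment)
  }, numeric(18L)))
}

#' MATCH fitness: mean peptide-identity score over training sets
#'
#' Fingerprints every TCR of every set under the genome's centroids and
#' weights, then scores each set by its rank-1, no-threshold peptide
#' identity and averages over sets.
#'
#' @param genome numeric genome of length 32.
#' @param sets list of [make_ga_set()] objects (each >= 2 TCRs).
#' @return mean peptide-identity score in percent.
#' @export
fitness_match <- function(genome, sets) {
  if (inherits(sets, "ga_set")) sets <- list(sets)
  scores <- vapply(sets, function(set) {
    n <- length(set$ids)
    if (n < 2L) stop("every GA set needs at least 2 TCRs")
    fp <- ga_fp_matrix(genome, set)
    rownames(fp) <- set$ids
    sim <- matrix(1, n, n, dimnames = list(set$ids, set$ids))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- 1 / (1 + mean(abs(fp[i, ] - fp[j, ])))
        sim[i, j] <- s
        sim[j, i] <- s
      }
    }
    correct <- vapply(seq_len(n), function(i) {
      cand <- set$ids[-i]
      nb <- cand[order(-sim[i, cand], cand)][1L]
      set$labels[match(nb, set$ids)] == set$labels[i]
    }, logical(1))
    100 * mean(correct)
  }, numeric(1))
  mean(scores)
}

#' MaxD fitness: mean fingerprint distance between unlike-specificity TCRs
#'
#' Averages the Manhattan distance between the fingerprints of every pair of
#' TCRs that do not bind the same peptide, under the genome's centroids and
#' weights. Maximizing it pushes differently-specific TCRs apart while
#' same-specificity TCRs may stay close.
#'
#' @param genome numeric genome of length 32.
#' @param set a [make_ga_set()] object with at least one differently-labeled
#'   pair.
#' @return mean inter-specificity Manhattan fingerprint distance.
#' @export
fitness_maxd <- function(genome, set) {
  stopifnot(inherits(set, "ga_set"))
  n <- length(set$ids)
  fp <- ga_fp_matrix(genome, set)
  tot <- 0
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (set$labels[i] != set$labels[j]) {
        tot <- tot + sum(abs(fp[i, ] - fp[j, ]))
        cnt <- cnt + 1L
      }
    }
  }
  if (cnt == 0L) stop("no differently-labeled pair in the set")
  tot / cnt
}

## averaged tip-of-loop genome of the training sets (TOL seeding)
tol_seed_genome <- function(sets, C = 25, P = 4) {
  if (inherits(sets, "ga_set")) sets <- list(sets)
  tips <- Reduce(`+`, unlist(lapply(sets, function(set) {
    lapply(set$entries, `[[`, "tips")
  }), recursive = FALSE))
  n <- sum(vapply(sets, function(set) length(set$entries), integer(1)))
  tips <- tips / n
  tips[, 4] <- C * tips[, 4]
  tips[, 5] <- P * tips[, 5]
  c(as.vector(t(tips)), C, P)
}

#' Initialize a GA population
#'
#' Random mode samples every centroid coordinate uniformly in the
#' `box_size`-edged box around `center` (weights C in (0, 50], P in (0, 8]);
#' TOL-seeded mode copies the training sets' average tip-of-loop genome and
#' diversifies all but the first individual with unit-uniform jitter.
#'
#' @param config a [ga_config()].
#' @param sets training sets (required for `init_mode = "tol"`).
#' @param center 3D center of the initialization box (default origin, the
#'   center of superposed structures).
#' @return matrix `init_population` x 32.
#' @export
initialize_population <- function(config, sets = NULL, center = c(0, 0, 0)) {
  stopifnot(inherits(config, "ga_config"))
  n <- config$init_population
  with_seed(config$seed, {
    if (config$init_mode == "random") {
      half <- config$box_size / 2
      pop <- t(vapply(seq_len(n), function(i) {
        cen <- cbind(
          matrix(stats::runif(18L, -half, half), 6L, 3L) +
            matrix(center, 6L, 3L, byrow = TRUE),
          matrix(stats::runif(12L, -half, half), 6L, 2L)
        )
        c(as.vector(t(cen)), stats::runif(1, 0.5, 50),
          stats::runif(1, 0.5, 8))
      }, numeric(GENOME_LENGTH)))
    } else {
      if (is.null(sets)) stop("TOL seeding requires training sets")
      g0 <- tol_seed_genome(sets)
      pop <- matrix(g0, n, GENOME_LENGTH, byrow = TRUE)
      if (n > 1L) {
        jit <- matrix(stats::runif((n - 1L) * GENOME_LENGTH, -1, 1),
                      n - 1L, GENOME_LENGTH)
        pop[-1L, ] <- pop[-1L, , drop = FALSE] + jit
        pop[, 31:32] <- pmax(abs(pop[, 31:32]), 1e-6)
      }
    }
    pop
  })
}

## one child from two parents: centroid crossover + entry mutation
ga_child <- function(p1, p2, config) {
  k <- if (config$crossover_range[1] == config$crossover_range[2]) {
    config$crossover_range[1]
  } else {
    sample(config$crossover_range[1]:config$crossover_range[2], 1L)
  }
  which_cen <- sample.int(6L, k)
  c1 <- p1
  c2 <- p2
  for (ci in which_cen) {
    cols <- (5L * (ci - 1L) + 1L):(5L * ci)
    if (config$crossover_mode == "partial") {
      cols <- cols[sample(c(TRUE, FALSE), 5L, replace = TRUE)]
      if (length(cols) == 0L) next
    }
    tmp <- c1[cols]
    c1[cols] <- c2[cols]
    c2[cols] <- tmp
  }
  for (wi in 31:32) {  # C and P exchanged individually at random
    if (stats::runif(1) < 0.5) {
      tmp <- c1[wi]
      c1[wi] <- c2[wi]
      c2[wi] <- tmp
    }
  }
  child <- if (stats::runif(1) < 0.5) c1 else c2
  m <- if (config$mutation_count_range[1] == config$mutation_count_range[2]) {
    config$mutation_count_range[1]
  } else {
    sample(config$mutation_count_range[1]:config$mutation_count_range[2], 1L)
  }
  if (m > 0L) {
    idx <- sample.int(GENOME_LENGTH, m)
    child[idx] <- child[idx] +
      stats::runif(m, config$mutation_increment[1],
                   config$mutation_increment[2])
  }
  ## positivity repair for the weights: reflect at 0
  child[31:32] <- pmax(abs(child[31:32]), 1e-6)
  child
}

#' Run the genetic algorithm
#'
#' Generational loop: evaluate, keep the `survivors` best, build `children`
#' children by crossover and mutation, merge, re-rank and truncate back to
#' `survivors`. Truncation is elitist, so the best-so-far fitness trace is
#' non-decreasing. Stops when the best fitness has not improved for
#' `stagnation` generations (or at `max_generations`). Fully reproducible
#' from `config$seed`.
#'
#' @param config a [ga_config()].
#' @param fitness function(genome) -> numeric score to maximize, e.g.
#'   `function(g) fitness_match(g, sets)`.
#' @param sets optional training sets (used for TOL seeding).
#' @param center initialization box center.
#' @return list with `best_genome`, `best_fitness`, `trace` (best-so-far
#'   fitness per generation), `generations`, `population` (final matrix) and
#'   `population_sizes` (after every generation).
#' @export
evolve <- function(config, fitness, sets = NULL, center = c(0, 0, 0)) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness))
  pop <- initialize_population(config, sets, center)
  eval_pop <- function(p, gen) {
    vapply(seq_len(nrow(p)), function(i) {
      f <- tryCatch(fitness(p[i, ]), error = function(e) {
        stop("fitness failure at generation ", gen, ": ",
             conditionMessage(e))
      })
      as.numeric(f)
    }, numeric(1))
  }
  with_seed(derive_seed(config$seed, 1L), {
    fit <- eval_pop(pop, 0L)
    ord <- order(-fit)
    pop <- pop[ord, , drop = FALSE]
    fit <- fit[ord]
    best <- fit[1L]
    trace <- numeric(0)
    sizes <- integer(0)
    stag <- 0L
    gen <- 0L
    while (gen < config$max_generations && stag < config$stagnation) {
      gen <- gen + 1L
      parents <- pop[seq_len(min(config$survivors, nrow(pop))), ,
                     drop = FALSE]
      pfit <- fit[seq_len(nrow(parents))]
      kids <- t(vapply(seq_len(config$children), function(j) {
        pi <- sample.int(nrow(parents), 2L)
        ga_child(parents[pi[1L], ], parents[pi[2L], ], config)
      }, numeric(GENOME_LENGTH)))
      kfit <- eval_pop(kids, gen)
      allp <- rbind(parents, kids)
      allf <- c(pfit, kfit)
      ord <- order(-allf)
      keep <- ord[seq_len(config$survivors)]
      pop <- allp[keep, , drop = FALSE]
      fit <- allf[keep]
      sizes <- c(sizes, nrow(pop))
      if (fit[1L] > best + 1e-12) {
        best <- fit[1L]
        stag <- 0L
      } else {
        stag <- stag + 1L
      }
      trace <- c(trace, best)
    }
    list(best_genome = pop[1L, ], best_fitness = best, trace = trace,
         generations = gen, population = pop, population_sizes = sizes)
  })
}
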