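#' Genetic-algorithm configuration for seed selection
#'
#' The chromosome is one `(row, col)` seed per tissue class; selection is by
#' tournament, crossover is a per-class uniform swap, and mutation resamples a
#' class's seed uniformly from that class's candidate mask. The hyperparameter
#' defaults are ordinary engineering choices for a search space of at most a
#' few thousand candidate pixels per class.
#'
#' @param population_size Integer >= 2.
#' @param generations Integer >= 1.
#' @param crossover_rate Probability in `[0, 1]` that a selected parent pair
#'   is crossed rather than copied.
#' @param mutation_rate Per-class resampling probability in `[0, 1]`.
#' @param elitism_count Integer >= 1, `< population_size`; the best
#'   individuals copied unchanged into the next generation, which makes the
#'   best-cost history non-increasing.
#' @param tournament_size Integer >= 2; tournaments are drawn uniformly with
#'   replacement.
#' @param stall_generations Early-stop patience: stop after this many
#'   generations without improvement of the best cost.
#' @param rng_seed Integer seed; the whole run is reproducible given it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 30L, generations = 50L,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      elitism_count = 2L, tournament_size = 3L,
                      stall_generations = 10L, rng_seed = 1L) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  elitism_count <- as.integer(elitism_count)
  tournament_size <- as.integer(tournament_size)
  if (population_size < 2L) config_error("population_size must be >= 2")
  if (generations < 1L) config_error("generations must be >= 1")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    config_error("crossover_rate and mutation_rate must be in [0, 1]")
  if (elitism_count < 1L || elitism_count >= population_size)
    config_error("elitism_count must be >= 1 and < population_size")
  if (tournament_size < 2L) config_error("tournament_size must be >= 2")
  structure(list(population_size = population_size, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = elitism_count,
                 tournament_size = tournament_size,
                 stall_generations = as.integer(stall_generations),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Per-class candidate seed masks by intensity thresholding
#'
#' Marks, for each class, the pixels whose intensity falls inside that class's
#' window; the GA draws and mutates each class's seed coordinate within its
#' mask. Windows must be pairwise disjoint so the masks are disjoint and every
#' chromosome's seeds are distinct by construction.
#'
#' @param image Numeric intensity matrix.
#' @param windows Named list of `c(lo, hi)` intensity windows (closed
#'   intervals), one per class.
#' @return Named list of logical candidate masks.
#' @export
candidate_seeds <- function(image, windows) {
  if (is.null(names(windows)) || any(names(windows) == ""))
    config_error("windows must be a named list of c(lo, hi) intervals")
  iv <- do.call(rbind, windows)
  if (any(iv[, 1] > iv[, 2])) config_error("each window needs lo <= hi")
  if (nrow(iv) > 1) {
    o <- order(iv[, 1])
    if (any(iv[o[-1], 1] <= iv[o[-nrow(iv)], 2]))
      config_error("intensity windows must be pairwise disjoint")
  }
  masks <- lapply(windows, function(w) image >= w[1] & image <= w[2])
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty))
    config_error(paste("empty candidate mask for class(es):",
                       paste(empty, collapse = ", "),
                       "- windows too narrow"))
  masks
}

#' Default intensity windows from class means
#'
#' Splits the intensity axis at the midpoints between consecutive sorted class
#' means; each tissue class's window runs from the midpoint below its mean to
#' the midpoint above (the extreme tissues extend by half the adjacent gap).
#' The background mean takes part in the midpoint computation but gets no
#' window.
#'
#' @param class_means Named numeric vector with `background`, `csf`, `gm`,
#'   `wm` entries (the [phantom_spec()] defaults if omitted).
#' @return Named list of `c(lo, hi)` windows for `csf`, `gm`, `wm`.
#' @export
default_windows <- function(class_means = c(background = 0, csf = 60,
                                            gm = 120, wm = 200)) {
  o <- order(class_means)
  m <- class_means[o]
  cuts <- (m[-1] + m[-length(m)]) / 2
  bounds <- c(2 * m[1] - cuts[1], cuts, 2 * m[length(m)] - cuts[length(cuts)])
  # windows are closed intervals; shave the shared midpoint off the upper
  # bound so consecutive windows stay disjoint
  wins <- lapply(seq_along(m), function(i)
    c(bounds[i], bounds[i + 1] - if (i < length(m)) 1e-9 else 0))
  names(wins) <- names(m)
  wins[setdiff(names(m), "background")]
}

#' Segmentation cost against a reference (squared-difference fitness)
#'
#' For each tissue class the predicted label map is binarized and compared
#' pixelwise against the reference binary map; on 0/1 maps the summed squared
#' difference equals the mismatch count. The total cost is the sum over the
#' three classes; it is zero iff the segmentation matches the reference on
#' every class map. Lower is fitter.
#'
#' @param pred Integer label matrix (as from [segment_image()]).
#' @param ref A `reference_segmentation` (see [as_reference()]).
#' @return List with `total_cost` and `per_class_cost`.
#' @export
seed_fitness <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref$labels)))
    data_error("prediction and reference shapes differ")
  per_class <- vapply(names(tissue_classes), function(cls) {
    sum((pred == tissue_classes[[cls]]) != ref[[cls]])
  }, numeric(1))
  list(total_cost = sum(per_class), per_class_cost = per_class)
}

#' Tournament selection
#'
#' Draws `tournament_size` indices uniformly with replacement and returns the
#' member with the lowest cost (ties broken by the earliest drawn index).
#'
#' @param population List of seed sets.
#' @param costs Numeric vector of their costs.
#' @param tournament_size Integer >= 1.
#' @return The selected seed set.
#' @export
tournament_select <- function(population, costs, tournament_size = 3L) {
  if (!length(population)) config_error("population is empty")
  idx <- sample.int(length(population), tournament_size, replace = TRUE)
  population[[idx[which.min(costs[idx])]]]
}

#' Per-class uniform crossover of two seed sets
#'
#' Each class's `(row, col)` coordinate is exchanged between the two children
#' with probability 0.5 independently; children stay in-bounds and
#' class-consistent by construction.
#'
#' @param a,b Seed sets with the same class names.
#' @return List of two children.
#' @export
crossover_seeds <- function(a, b) {
  if (!identical(names(a), names(b)))
    config_error("parents must share the same class order")
  c1 <- a; c2 <- b
  for (cls in names(a)) {
    if (runif(1) < 0.5) {
      c1[[cls]] <- b[[cls]]
      c2[[cls]] <- a[[cls]]
    }
  }
  list(c1, c2)
}

#' Candidate-constrained mutation of a seed set
#'
#' Each class's coordinate is independently resampled uniformly from that
#' class's candidate mask with probability `mutation_rate`.
#'
#' @param s Seed set (named list of `c(row, col)`).
#' @param candidates Named list of logical candidate masks.
#' @param mutation_rate Probability in `[0, 1]`.
#' @return The mutated seed set.
#' @export
mutate_seeds <- function(s, candidates, mutation_rate) {
  for (cls in names(s)) {
    if (runif(1) < mutation_rate) {
      ix <- which(candidates[[cls]])
      pick <- ix[sample.int(length(ix), 1L)]
      s[[cls]] <- as.integer(arrayInd(pick, dim(candidates[[cls]])))
    }
  }
  s
}

sample_seed_set <- function(candidates) {
  lapply(candidates, function(mask) {
    ix <- which(mask)
    as.integer(arrayInd(ix[sample.int(length(ix), 1L)], dim(mask)))
  })
}

#' Optimize seed placement with a genetic algorithm
#'
#' Evolves seed sets drawn from the candidate masks, scoring each individual
#' by the squared-difference cost of the segmentation it produces against the
#' reference. Elitism keeps the best `elitism_count` individuals unchanged, so
#' the best-cost history is non-increasing; the run stops after
#' `generations`, or once the best cost reaches zero, or after
#' `stall_generations` generations without improvement. The run is
#' reproducible given `ga_cfg$rng_seed`.
#'
#' @param image Numeric intensity matrix.
#' @param ref A `reference_segmentation`.
#' @param candidates Named list of candidate masks (one per class in
#'   `grow_cfg$class_order`), e.g. from [candidate_seeds()].
#' @param grow_cfg A [grow_config()].
#' @param ga_cfg A [ga_config()].
#' @return List with `best_seeds`, `best_cost`, `per_class_cost`, `history`
#'   (best cost after each generation, element 1 being the initial
#'   population's best) and `evaluations` (distinct seed sets scored).
#' @export
ga_optimize <- function(image, ref, candidates, grow_cfg = grow_config(),
                        ga_cfg = ga_config()) {
  missing <- setdiff(grow_cfg$class_order, names(candidates))
  if (length(missing))
    config_error(paste("missing candidate masks for:",
                       paste(missing, collapse = ", ")))
  candidates <- candidates[grow_cfg$class_order]
  if (!all(vapply(candidates, any, logical(1))))
    config_error("every class needs a non-empty candidate mask")

  cache <- new.env(parent = emptyenv())
  eval_cost <- function(s) {
    key <- paste(unlist(s), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cost <- seed_fitness(segment_image(image, s, grow_cfg), ref)$total_cost
    cache[[key]] <- cost
    cost
  }

  with_rng_seed(ga_cfg$rng_seed, {
    pop <- replicate(ga_cfg$population_size, sample_seed_set(candidates),
                     simplify = FALSE)
    costs <- vapply(pop, eval_cost, numeric(1))
    best_i <- which.min(costs)
    best <- pop[[best_i]]
    best_cost <- costs[best_i]
    history <- best_cost
    stall <- 0L
    for (g in seq_len(ga_cfg$generations)) {
      if (best_cost == 0 || stall >= ga_cfg$stall_generations) break
      ord <- order(costs)
      keep <- ord[seq_len(ga_cfg$elitism_count)]
      newpop <- pop[keep]
      while (length(newpop) < ga_cfg$population_size) {
        p1 <- tournament_select(pop, costs, ga_cfg$tournament_size)
        p2 <- tournament_select(pop, costs, ga_cfg$tournament_size)
        children <- if (runif(1) < ga_cfg$crossover_rate)
          crossover_seeds(p1, p2) else list(p1, p2)
        for (ch in children) {
          if (length(newpop) >= ga_cfg$population_size) break
          newpop[[length(newpop) + 1L]] <-
            mutate_seeds(ch, candidates, ga_cfg$mutation_rate)
        }
      }
      pop <- newpop
      costs <- vapply(pop, eval_cost, numeric(1))
      gen_best <- min(costs)
      if (gen_best < best_cost) {
        best_cost <- gen_best
        best <- pop[[which.min(costs)]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- c(history, best_cost)
      stopifnot(!is.unsorted(rev(history))) # elitism guarantee
    }
    fit <- seed_fitness(segment_image(image, best, grow_cfg), ref)
    list(best_seeds = best, best_cost = best_cost,
         per_class_cost = fit$per_class_cost, history = history,
         evaluations = length(ls(cache)))
  })
}

#' Naive manual-seed baseline
#'
#' The first pixel (in array scan order, i.e. down columns) falling inside
#' each class's intensity window — the kind of quick manual pick an operator
#' might make without inspecting the image. Used as the comparison baseline
#' for GA-optimized seeding.
#'
#' @param image Numeric intensity matrix.
#' @param windows Named list of intensity windows (see [candidate_seeds()]).
#' @return Named list of `c(row, col)` seeds.
#' @export
naive_seeds <- function(image, windows) {
  masks <- candidate_seeds(image, windows)
  lapply(masks, function(mask)
    as.integer(arrayInd(which(mask)[1L], dim(mask))))
}
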