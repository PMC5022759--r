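test_that("candidate masks equal a brute-force window scan", {
  img <- matrix(c(10, 60, 120, 200,
                  45, 75, 130, 210,
                  55, 90, 160, 240,
                  20, 100, 140, 190), 4, 4, byrow = TRUE)
  wins <- list(csf = c(51, 100), gm = c(101, 170), wm = c(171, 255))
  masks <- candidate_seeds(img, wins)
  for (cls in names(wins)) {
    oracle <- matrix(FALSE, 4, 4)
    for (i in 1:4) for (j in 1:4)
      oracle[i, j] <- img[i, j] >= wins[[cls]][1] & img[i, j] <= wins[[cls]][2]
    expect_identical(masks[[cls]], oracle)
  }
  # noise-free phantom with midpoint windows: candidates == ground truth
  ph <- generate_phantom(phantom_spec(shape = c(32, 32)))
  cands <- candidate_seeds(ph$image, default_windows())
  for (cls in c("csf", "gm", "wm"))
    expect_identical(cands[[cls]], ph$reference[[cls]])
})

test_that("overlapping or empty windows are configuration errors", {
  img <- matrix(100, 4, 4)
  expect_error(candidate_seeds(img, list(a = c(0, 60), b = c(50, 120))),
               class = "growseg_config_error")
  expect_error(candidate_seeds(img, list(a = c(0, 50), b = c(60, 99))),
               class = "growseg_config_error") # no pixel in either window
})

test_that("fitness counts binary mismatches per class", {
  ref_labels <- matrix(0L, 3, 3)
  ref_labels[1:2, 1:2] <- 2L # 4-pixel GM square
  ref_labels[3, 1] <- 1L
  ref_labels[3, 3] <- 3L
  ref <- as_reference(ref_labels)
  # prediction misses one GM pixel and adds another; other classes perfect
  pred <- ref_labels
  pred[2, 2] <- 0L
  pred[1, 3] <- 2L
  fit <- seed_fitness(pred, ref)
  expect_equal(unname(fit$per_class_cost), c(0, 2, 0))
  expect_equal(fit$total_cost, 2)
  # identical maps cost 0; all-background costs the foreground pixel count
  expect_equal(seed_fitness(ref_labels, ref)$total_cost, 0)
  expect_equal(seed_fitness(matrix(0L, 3, 3), ref)$total_cost,
               sum(ref_labels > 0))
  expect_error(seed_fitness(matrix(0L, 2, 2), ref),
               class = "growseg_data_error")
})

test_that("fitness is symmetric in prediction and reference class maps", {
  withr::with_seed(3, {
    a <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    b <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    expect_equal(seed_fitness(a, as_reference(b))$total_cost,
                 seed_fitness(b, as_reference(a))$total_cost)
  })
})

test_that("tournament selection favors low cost at the enumerated rate", {
  pop <- list(list(csf = c(1, 1)), list(csf = c(2, 2)))
  costs <- c(1, 2)
  # full tournament always returns the global best
  withr::with_seed(1, {
    for (i in 1:20)
      expect_identical(tournament_select(pop, costs, 2e2), pop[[1]])
  })
  # size-2 tournaments with replacement from 2 individuals: best wins 3/4
  withr::with_seed(2, {
    wins <- sum(replicate(1e4, identical(
      tournament_select(pop, costs, 2L), pop[[1]])))
  })
  expect_gt(wins / 1e4, 0.73)
  expect_lt(wins / 1e4, 0.77)
})

test_that("crossover enumerates per-class swaps and keeps parents' genes", {
  a <- list(csf = c(1, 1), gm = c(2, 2), wm = c(3, 3))
  b <- list(csf = c(9, 9), gm = c(8, 8), wm = c(7, 7))
  # identical parents produce identical children
  expect_identical(crossover_seeds(a, a), list(a, a))
  withr::with_seed(4, {
    seen <- character()
    for (i in 1:500) {
      ch <- crossover_seeds(a, b)
      for (cls in names(a)) {
        # each gene comes from a parent, and the children are complementary
        expect_true(identical(ch[[1]][[cls]], a[[cls]]) ||
                      identical(ch[[1]][[cls]], b[[cls]]))
        expect_true(identical(ch[[2]][[cls]],
                              if (identical(ch[[1]][[cls]], a[[cls]]))
                                b[[cls]] else a[[cls]]))
      }
      seen <- union(seen, paste(unlist(ch[[1]]), collapse = ","))
    }
    expect_equal(length(seen), 8) # all 2^3 swap patterns occur
  })
})

test_that("mutation is identity at rate 0 and uniform over the mask at rate 1", {
  s <- list(csf = c(2, 2))
  mask <- matrix(FALSE, 5, 5)
  mask[cbind(1:5, 1:5)] <- TRUE
  withr::with_seed(5, expect_identical(mutate_seeds(s, list(csf = mask), 0), s))
  # singleton mask: deterministic
  single <- matrix(FALSE, 5, 5); single[4, 2] <- TRUE
  withr::with_seed(5, expect_identical(
    mutate_seeds(s, list(csf = single), 1)$csf, c(4L, 2L)))
  # uniformity over a 5-pixel mask by chi-square at 1e4 draws
  withr::with_seed(6, {
    draws <- replicate(1e4, mutate_seeds(s, list(csf = mask), 1)$csf[1])
  })
  expect_gt(chisq.test(table(factor(draws, levels = 1:5)))$p.value, 0.001)
})

test_that("a perfect individual in the initial population yields final cost 0", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24)))
  cands <- candidate_seeds(ph$image, default_windows())
  res <- ga_optimize(ph$image, ph$reference, cands, grow_config(),
                     ga_config(population_size = 4, generations = 5,
                               rng_seed = 1))
  expect_equal(res$best_cost, 0)
  expect_equal(unname(res$per_class_cost), c(0, 0, 0))
})

test_that("GA attains the exhaustive-search minimum on a small fixture", {
  toy <- make_toy_image(n = 8, sigma = 25, seed = 10)
  cfg <- grow_config(t_min = 20)
  wins <- list(csf = c(45, 75), gm = c(105, 135), wm = c(190, 240))
  cands <- candidate_seeds(toy$image, wins)
  # keep the search space small enough to enumerate
  expect_true(all(sapply(cands, sum) <= 20))
  best <- exhaustive_best_cost(toy$image, toy$reference, cands, cfg)
  for (seed in 1:3) {
    res <- ga_optimize(toy$image, toy$reference, cands, cfg,
                       ga_config(population_size = 16, generations = 40,
                                 mutation_rate = 0.3, stall_generations = 40,
                                 rng_seed = seed))
    expect_equal(res$best_cost, best)
  }
})

test_that("single candidate per class returns that seed set", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24)))
  cands <- lapply(c(csf = 1L, gm = 2L, wm = 3L), function(id) {
    m <- matrix(FALSE, 24, 24)
    m[which(ph$reference$labels == id)[1]] <- TRUE
    m
  })
  res <- ga_optimize(ph$image, ph$reference, cands, grow_config(),
                     ga_config(population_size = 4, generations = 3,
                               rng_seed = 2))
  for (cls in names(cands))
    expect_true(cands[[cls]][res$best_seeds[[cls]][1],
                             res$best_seeds[[cls]][2]])
})

test_that("best-cost history is non-increasing and runs are reproducible", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32), noise_sigma = 12,
                                      rng_seed = 8))
  cands <- candidate_seeds(ph$image, default_windows())
  cfg <- ga_config(population_size = 10, generations = 8, rng_seed = 3)
  r1 <- ga_optimize(ph$image, ph$reference, cands, grow_config(), cfg)
  r2 <- ga_optimize(ph$image, ph$reference, cands, grow_config(), cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history) <= 0))
})

test_that("invalid GA configurations are rejected", {
  expect_error(ga_config(population_size = 1), class = "growseg_config_error")
  expect_error(ga_config(elitism_count = 30, population_size = 30),
               class = "growseg_config_error")
  expect_error(ga_config(mutation_rate = 1.5), class = "growseg_config_error")
})
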