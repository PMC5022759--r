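# Independent oracles used across the suite. Deliberately brute-force and
# slow: they share no code with the implementation paths they check.

# Population mean/sd recomputed from scratch over a vector.
batch_stats <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / length(x)))
}

# Plain flood fill: connected component of {|I - ref| <= tol} containing the
# seed, under a given neighborhood, restricted to `eligible`.
flood_fill_oracle <- function(image, seed, tol, ref_value,
                              neighborhood = "eight", eligible = NULL) {
  if (is.null(eligible)) eligible <- matrix(TRUE, nrow(image), ncol(image))
  ok <- abs(image - ref_value) <= tol & eligible
  ok[seed[1], seed[2]] <- TRUE # the seed is accepted unconditionally
  mask <- matrix(FALSE, nrow(image), ncol(image))
  stack <- list(seed)
  mask[seed[1], seed[2]] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (i in seq_len(nrow(nb <- neighbors(p, dim(image), neighborhood)))) {
      r <- nb[i, 1]; c <- nb[i, 2]
      if (ok[r, c] && !mask[r, c]) {
        mask[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  mask
}

# Is the TRUE set of `mask` connected under the neighborhood? BFS from the
# first TRUE pixel.
is_connected <- function(mask, neighborhood = "eight") {
  idx <- which(mask)
  if (length(idx) <= 1L) return(TRUE)
  start <- as.integer(arrayInd(idx[1], dim(mask)))
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  seen[start[1], start[2]] <- TRUE
  stack <- list(start)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nb <- neighbors(p, dim(mask), neighborhood)
    for (i in seq_len(nrow(nb))) {
      r <- nb[i, 1]; c <- nb[i, 2]
      if (mask[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  sum(seen) == length(idx)
}

# Exhaustive search over every combination of candidate seeds; returns the
# minimum segmentation cost.
exhaustive_best_cost <- function(image, ref, candidates, grow_cfg) {
  coord_list <- lapply(candidates, function(mask) {
    ix <- which(mask)
    lapply(ix, function(i) as.integer(arrayInd(i, dim(mask))))
  })
  grid <- expand.grid(lapply(coord_list, seq_along))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    seeds <- lapply(seq_along(coord_list), function(j)
      coord_list[[j]][[grid[i, j]]])
    names(seeds) <- names(coord_list)
    cost <- seed_fitness(segment_image(image, seeds, grow_cfg), ref)$total_cost
    if (cost < best) best <- cost
  }
  best
}

# Small noisy three-tissue toy image for GA tests: blocks of CSF/GM/WM plus
# noise strong enough that the seed choice matters.
make_toy_image <- function(n = 8, sigma = 25, seed = 1) {
  labels <- matrix(0L, n, n)
  labels[, 1:(n %/% 3)] <- 1L
  labels[, (n %/% 3 + 1):(2 * n %/% 3)] <- 2L
  labels[, (2 * n %/% 3 + 1):n] <- 3L
  means <- c(60, 120, 200)
  image <- matrix(means[labels], n, n)
  withr::with_seed(seed, image <- image + matrix(rnorm(n * n, 0, sigma), n, n))
  list(image = image, reference = as_reference(labels))
}
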