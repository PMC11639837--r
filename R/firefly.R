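# Discrete firefly search over k-band combinations. Each firefly is a
# sorted set of k distinct band indices; its luminance is the
# validation score of the spectral classifier trained on zero-masked
# spectra restricted to those bands. Movement uses the canonical
# attraction form beta0 * exp(-gamma * d^2) with an additive uniform
# step, followed by discrete repair (round, clamp, re-draw duplicates).

#' Firefly search parameters
#'
#' Defaults mirror the conventional small-population setup: 5 fireflies
#' of 3 bands each, maximum attraction 0.5, absorption coefficient 0.8,
#' step coefficient 0.6, 100 iterations.
#'
#' @param n population size (>= 2).
#' @param k bands per firefly (>= 1).
#' @param beta0 maximum attraction, in (0, 1].
#' @param gamma light-intensity absorption coefficient (> 0).
#' @param alpha random step coefficient (>= 0).
#' @param max_iterations iteration budget.
#' @param eval_epochs classifier epochs per luminance evaluation.
#' @param score one of `"accuracy"`, `"macro_f1"`: the validation score
#'   used as luminance.
#' @param eval_config optional [spectral_net_config()] template for the
#'   objective classifier; when `NULL` a scaled preset matching the data
#'   is built per evaluation.
#' @param seed global seed; per-evaluation seeds are derived from it
#'   and the band combination so identical combinations always score
#'   identically.
#' @return an object of class `firefly_params`.
#' @export
firefly_params <- function(n = 5, k = 3, beta0 = 0.5, gamma = 0.8, alpha = 0.6,
                           max_iterations = 100, eval_epochs = 15,
                           score = c("accuracy", "macro_f1"),
                           eval_config = NULL, seed = 1) {
  score <- match.arg(score)
  if (n < 2) abort_hsd("population size must be >= 2", "hsd_argument_error")
  if (k < 1) abort_hsd("k must be >= 1", "hsd_argument_error")
  if (!(beta0 > 0 && beta0 <= 1)) abort_hsd("beta0 must lie in (0, 1]", "hsd_argument_error")
  if (gamma <= 0) abort_hsd("gamma must be positive", "hsd_argument_error")
  if (alpha < 0) abort_hsd("alpha must be nonnegative", "hsd_argument_error")
  structure(list(n = n, k = k, beta0 = beta0, gamma = gamma, alpha = alpha,
                 max_iterations = max_iterations, eval_epochs = eval_epochs,
                 score = score, eval_config = eval_config, seed = seed),
            class = "firefly_params")
}

#' Initialize the firefly population
#'
#' @param params a [firefly_params()].
#' @param num_bands number of bands available (>= `k`).
#' @return list of fireflies, each `list(position, luminance = NA)`
#'   with `position` a sorted vector of k distinct 1-based indices.
#' @export
initialize_population <- function(params, num_bands) {
  if (num_bands < params$k)
    abort_hsd("num_bands must be at least k", "hsd_argument_error")
  with_seed(params$seed, {
    lapply(seq_len(params$n), function(i) {
      list(position = sort(sample.int(num_bands, params$k)), luminance = NA_real_)
    })
  })
}

#' Attractiveness at a given distance
#'
#' `beta = beta0 * exp(-gamma * d^2)`, monotone decreasing in distance.
#'
#' @param distance nonnegative Euclidean distance in band-index space.
#' @param beta0,gamma see [firefly_params()].
#' @return attraction in `(0, beta0]`.
#' @export
attractiveness <- function(distance, beta0, gamma) {
  if (any(distance < 0)) abort_hsd("distance must be nonnegative", "hsd_argument_error")
  beta0 * exp(-gamma * distance^2)
}

# Round, clamp, and re-draw duplicate indices uniformly from unused
# bands until the position is k distinct sorted valid indices.
repair_position <- function(pos, num_bands) {
  pos <- pmin(pmax(round(pos), 1), num_bands)
  while (anyDuplicated(pos)) {
    dup <- which(duplicated(pos))
    unused <- setdiff(seq_len(num_bands), pos)
    for (i in dup) pos[i] <- if (length(unused) == 1) unused else sample(unused, 1)
  }
  sort(as.integer(pos))
}

#' Move a dim firefly toward a brighter one
#'
#' Continuous update `x <- x + beta (x_bright - x) + alpha (u - 0.5)`
#' per coordinate with `u ~ U(0,1)` and `beta =
#' attractiveness(||x - x_bright||)`, then discrete repair. The update
#' runs in band-index coordinates normalized by the band count (the
#' conventional O(1) search domain): with raw indices spanning
#' hundreds of bands, `exp(-gamma d^2)` underflows and the unit-scale
#' alpha step rounds away, freezing the search.
#'
#' @param dim_fly,bright_fly fireflies (`bright_fly` must not be
#'   dimmer).
#' @param params a [firefly_params()].
#' @param num_bands number of available bands.
#' @return the moved firefly with `luminance = NA` (to be re-evaluated).
#' @export
move_firefly <- function(dim_fly, bright_fly, params, num_bands) {
  x <- as.numeric(dim_fly$position) / num_bands
  xb <- as.numeric(bright_fly$position) / num_bands
  d <- sqrt(sum((x - xb)^2))
  beta <- attractiveness(d, params$beta0, params$gamma)
  u <- stats::runif(length(x))
  xn <- x + beta * (xb - x) + params$alpha * (u - 0.5)
  list(position = repair_position(xn * num_bands, num_bands),
       luminance = NA_real_)
}

combo_key <- function(position) paste(position, collapse = "-")

#' Luminance of a band combination
#'
#' Trains the spectral classifier on spectra zero-masked to the
#' combination (reduced epochs, per-combination derived seed) and
#' returns the configured validation score. Scores are memoized by
#' combination through the `cache` environment: identical combinations
#' never retrain.
#'
#' @param position sorted distinct band indices.
#' @param data labeled spectrum collection (`spectra`, `labels`).
#' @param params a [firefly_params()].
#' @param cache environment used as a memo table (optional).
#' @return validation score in `[0, 1]`.
#' @export
evaluate_luminance <- function(position, data, params, cache = NULL) {
  key <- combo_key(position)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  masked <- list(spectra = mask_spectra(data$spectra, position),
                 labels = data$labels)
  eval_seed <- (hash_ints(c(params$seed, position)) %% 2000000000L)
  # the default objective net is deliberately small: it is retrained
  # for every distinct combination, so evaluation cost dominates the
  # search budget
  cfg <- params$eval_config %||%
    spectral_net_config(input_length = ncol(data$spectra),
                        blocks = list(c(8, 1), c(16, 1)), fc_width = 24,
                        n_classes = length(unique(data$labels)),
                        batch_size = 64)
  cfg$epochs <- params$eval_epochs
  cfg$seed <- eval_seed
  cfg$input_length <- ncol(data$spectra)
  model <- train_classifier(masked, cfg)
  score <- switch(params$score,
                  accuracy = model$val_accuracy,
                  macro_f1 = model$val_macro_f1)
  if (!is.null(cache)) {
    cache[[key]] <- score
    cache$.n_trainings <- (cache$.n_trainings %||% 0L) + 1L
  }
  score
}

#' Run the firefly band selection
#'
#' Loop: evaluate all fireflies, then for every ordered pair move the
#' dimmer toward the brighter; the globally brightest firefly takes a
#' pure random step (alpha term only). The best combination ever
#' evaluated is tracked and returned. Fully deterministic under the
#' parameter seed.
#'
#' @param data labeled spectrum collection (`spectra`, `labels`).
#' @param params a [firefly_params()].
#' @return object of class `selection_result`: `best` (position +
#'   luminance), `population` (final fireflies), `history` (data.frame
#'   iteration x firefly luminances + best-ever), `cache_stats`.
#' @export
run_selection <- function(data, params) {
  num_bands <- ncol(data$spectra)
  cache <- new.env(parent = emptyenv())
  pop <- initialize_population(params, num_bands)
  evaluate_all <- function(pop) {
    for (i in seq_along(pop))
      if (is.na(pop[[i]]$luminance))
        pop[[i]]$luminance <- evaluate_luminance(pop[[i]]$position, data, params, cache)
    pop
  }
  pop <- evaluate_all(pop)
  best <- pop[[which.max(vapply(pop, `[[`, 0, "luminance"))]]
  hist <- list()
  record <- function(iter, pop, best) {
    data.frame(iteration = iter,
               firefly = seq_along(pop),
               luminance = vapply(pop, `[[`, 0, "luminance"),
               best_ever = best$luminance)
  }
  with_seed(params$seed + 7L, {
    iter <- 0
    while (iter < params$max_iterations) {
      iter <- iter + 1
      # luminances are snapshotted at the start of the sweep; moves use
      # current positions but iteration-start brightness, so a firefly
      # moved mid-sweep still attracts with its evaluated luminance
      lum <- vapply(pop, `[[`, 0, "luminance")
      brightest <- which.max(lum)
      for (i in seq_along(pop)) {
        if (i == brightest) next
        for (j in seq_along(pop)) {
          if (lum[j] > lum[i])
            pop[[i]] <- move_firefly(pop[[i]], pop[[j]], params, num_bands)
        }
      }
      # the brightest performs a pure random walk (normalized scale)
      b <- pop[[brightest]]
      xn <- as.numeric(b$position) / num_bands +
        params$alpha * (stats::runif(params$k) - 0.5)
      pop[[brightest]] <- list(position = repair_position(xn * num_bands, num_bands),
                               luminance = NA_real_)
      pop <- evaluate_all(pop)
      cand <- pop[[which.max(vapply(pop, `[[`, 0, "luminance"))]]
      if (cand$luminance > best$luminance) best <- cand
      hist[[length(hist) + 1]] <- record(iter, pop, best)
    }
  })
  history <- if (length(hist)) {
    do.call(rbind, hist)
  } else {
    data.frame(iteration = integer(0), firefly = integer(0),
               luminance = numeric(0), best_ever = numeric(0))
  }
  structure(list(best = best, population = pop, history = history,
                 cache_stats = list(
                   distinct_combinations = length(setdiff(ls(cache), ".n_trainings")),
                   trainings = cache$.n_trainings %||% 0L),
                 params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> best bands: %s (luminance %.3f); %d distinct combinations evaluated\n",
              paste(x$best$position, collapse = ", "), x$best$luminance,
              x$cache_stats$distinct_combinations))
  invisible(x)
}

#' Random band-combination search baseline
#'
#' Evaluates `budget` uniformly drawn k-combinations with the same
#' luminance objective and memoization; the comparison baseline for
#' the firefly search at equal evaluation budget.
#'
#' @param data labeled spectrum collection.
#' @param params a [firefly_params()] (supplies k, objective and seed).
#' @param budget number of evaluations.
#' @return list with `best` and `n_evaluated`.
#' @export
random_search <- function(data, params, budget) {
  num_bands <- ncol(data$spectra)
  cache <- new.env(parent = emptyenv())
  combos <- with_seed(params$seed + 13L,
                      lapply(seq_len(budget),
                             function(i) sort(sample.int(num_bands, params$k))))
  best <- NULL
  for (pos in combos) {
    s <- evaluate_luminance(pos, data, params, cache)
    if (is.null(best) || s > best$luminance)
      best <- list(position = pos, luminance = s)
  }
  list(best = best, n_evaluated = budget)
}

#' Export a selection result as JSON
#'
#' Positions are reported both as band indices and as wavelengths.
#'
#' @param result a `selection_result`.
#' @param grid the [wavelength_grid()] the indices refer to.
#' @param path output JSON path.
#' @param history_csv optional path for the per-iteration luminance
#'   history table.
#' @export
write_selection_json <- function(result, grid, path, history_csv = NULL) {
  to_nm <- function(idx) grid$wavelengths_nm[idx]
  obj <- list(
    best = list(bands = result$best$position,
                wavelengths_nm = to_nm(result$best$position),
                luminance = result$best$luminance),
    population = lapply(result$population, function(f)
      list(bands = f$position, wavelengths_nm = to_nm(f$position),
           luminance = f$luminance)),
    cache_stats = result$cache_stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(history_csv))
    utils::write.csv(result$history, history_csv, row.names = FALSE)
  invisible(path)
}
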