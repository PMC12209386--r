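#' Hyperparameter search over the tuned ranges
#'
#' The search space mirrors the tuned ranges: hidden units and FC widths in
#' 10-300 by steps of 10, 1-3 fully connected layers, dropout in
#' \[1e-6, 1\], L2 in \[1e-5, 1\] (both log-uniform), batch size 16-128 by
#' steps of 4, optimizer SGD or Adam. The driver is sampler-agnostic; the
#' bundled sampler is seeded random search, which draws every trial
#' independently and uniformly from the space.
#'
#' @name hyperparameter-search
NULL

#' Define the hyperparameter search space
#'
#' @param hidden_units candidate LSTM widths.
#' @param dropout range of dropout probabilities (sampled log-uniformly).
#' @param l2 range of L2 factors (sampled log-uniformly).
#' @param fc_layers candidate fully-connected layer counts (the last layer
#'   is the softmax output; `n` layers means `n - 1` inner widths).
#' @param fc_width candidate inner FC widths.
#' @param batch_size candidate batch sizes.
#' @param optimizer candidate optimizers.
#' @return An object of class `search_space`.
#' @export
search_space <- function(hidden_units = seq(10L, 300L, by = 10L),
                         dropout = c(1e-6, 1.0),
                         l2 = c(1e-5, 1.0),
                         fc_layers = 1:3,
                         fc_width = seq(10L, 300L, by = 10L),
                         batch_size = seq(16L, 128L, by = 4L),
                         optimizer = c("sgd", "adam")) {
  structure(list(hidden_units = hidden_units, dropout = dropout, l2 = l2,
                 fc_layers = fc_layers, fc_width = fc_width,
                 batch_size = batch_size, optimizer = optimizer),
            class = "search_space")
}

.sample_config <- function(space) {
  loguni <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  n_fc <- sample(space$fc_layers, 1L)
  list(hidden = sample(space$hidden_units, 1L),
       dropout = loguni(space$dropout),
       l2 = loguni(space$l2),
       fc = if (n_fc > 1L) sample(space$fc_width, n_fc - 1L, replace = TRUE) else integer(0),
       batch_size = sample(space$batch_size, 1L),
       optimizer = sample(space$optimizer, 1L))
}

#' Run a seeded hyperparameter search
#'
#' Draws `budget` configurations from the space and scores each with the
#' user-supplied objective (by convention the mean cross-validation
#' accuracy, higher is better); returns the argmax trial plus the full log.
#'
#' @param space a [search_space()].
#' @param objective function taking one sampled configuration (a list with
#'   `hidden`, `dropout`, `l2`, `fc`, `batch_size`, `optimizer`) and
#'   returning a scalar score.
#' @param budget number of trials (>= 1).
#' @param seed integer seed.
#' @return List with `best` (the winning config), `best_score` and
#'   `trials` (a data.frame log of every trial).
#' @export
hyperparameter_search <- function(space, objective, budget = 20, seed = 1) {
  if (budget < 1) stop("search budget must be at least 1 trial")
  with_seed(seed, {
    trials <- vector("list", budget)
    scores <- numeric(budget)
    for (i in seq_len(budget)) {
      cfg <- .sample_config(space)
      scores[i] <- objective(cfg)
      trials[[i]] <- cfg
    }
    log <- data.frame(trial = seq_len(budget),
                      hidden = vapply(trials, `[[`, numeric(1), "hidden"),
                      dropout = vapply(trials, `[[`, numeric(1), "dropout"),
                      l2 = vapply(trials, `[[`, numeric(1), "l2"),
                      n_fc = vapply(trials, function(t) length(t$fc) + 1L, integer(1)),
                      batch_size = vapply(trials, `[[`, numeric(1), "batch_size"),
                      optimizer = vapply(trials, `[[`, character(1), "optimizer"),
                      score = scores, stringsAsFactors = FALSE)
    best <- which.max(scores)
    list(best = trials[[best]], best_score = scores[best], trials = log)
  })
}
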