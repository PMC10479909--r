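#' Task structure for the two-stage free/forced choice task
#'
#' The task has a first stage where subjects either experience (training) or
#' choose (test) one of two options: *free*, which grants a self-determined
#' choice between two terminal fractal targets, or *forced*, where the
#' computer mandates the terminal action. Extrinsic rewards (0/1) follow
#' terminal actions only. Reward probabilities are fixed within blocks and
#' unique fractals are used per block.
#'
#' Three experiment variants are implemented:
#' \describe{
#'   \item{exp1a}{3 blocks; maximal reward probability P identical for free
#'     and forced, P in \{0.5, 0.75, 1\}; the non-best free target is
#'     rewarded at 1 - P.}
#'   \item{exp1b}{4 blocks, P in \{0.5, 0.67, 0.83, 1\}, otherwise as exp1a.}
#'   \item{exp2}{3 blocks; free targets fixed at 0.75/0.25 while the forced
#'     target pays 0.75, 0.85, 0.95; the parity block (0.75) always first.}
#'   \item{exp3}{3 blocks; every terminal target pays 0.75; the displayed
#'     target is swapped with probability `incoherence` in \{0, 0.15, 0.3\};
#'     the fully coherent block always first. The forced option leads to a
#'     two-action terminal state (computer picks one of two fractals), giving
#'     the task 7 states instead of 6.}
#' }
#'
#' @name task
NULL

EXPERIMENTS <- c("exp1a", "exp1b", "exp2", "exp3")

new_block_spec <- function(block_index, p_forced, p_free_a1, p_free_a2,
                           incoherence = 0,
                           n_train_free = 48L, n_train_forced = 48L,
                           n_test = 48L) {
  probs <- c(p_forced = p_forced, p_free_a1 = p_free_a1, p_free_a2 = p_free_a2)
  if (any(probs < 0 | probs > 1)) {
    stop("reward probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (incoherence < 0 || incoherence >= 0.5) {
    stop("incoherence must lie in [0, 0.5)", call. = FALSE)
  }
  if (n_train_free != n_train_forced) {
    stop("training exposure must be equal for free and forced options",
         call. = FALSE)
  }
  structure(
    list(block_index = as.integer(block_index),
         p_forced = p_forced, p_free_a1 = p_free_a1, p_free_a2 = p_free_a2,
         incoherence = incoherence,
         n_train_free = as.integer(n_train_free),
         n_train_forced = as.integer(n_train_forced),
         n_test = as.integer(n_test)),
    class = "block_spec")
}

#' Build the canonical block schedule of one experiment
#'
#' Returns the published block set for the requested experiment, with
#' non-fixed blocks permuted by `seed`. In exp2 the parity block
#' (p_forced = 0.75) is always first; in exp3 the fully coherent block
#' (incoherence = 0) is always first; exp1a/exp1b blocks are freely permuted.
#'
#' @param experiment one of `"exp1a"`, `"exp1b"`, `"exp2"`, `"exp3"`.
#' @param seed integer seed controlling the block permutation.
#' @return a `task_config` object: list with `experiment`, `blocks`
#'   (list of block specs, `block_index` giving the canonical identity of
#'   each block) and `seed`.
#' @examples
#' cfg <- build_config("exp1a", seed = 1)
#' sapply(cfg$blocks, `[[`, "p_forced")
#' @export
build_config <- function(experiment, seed = 1L) {
  experiment <- match.arg(experiment, EXPERIMENTS)
  blocks <- switch(experiment,
    exp1a = list(
      new_block_spec(1, 0.50, 0.50, 0.50),
      new_block_spec(2, 0.75, 0.75, 0.25),
      new_block_spec(3, 1.00, 1.00, 0.00,
                     n_train_free = 24L, n_train_forced = 24L)),
    exp1b = list(
      new_block_spec(1, 0.50, 0.50, 0.50),
      new_block_spec(2, 0.67, 0.67, 0.33),
      new_block_spec(3, 0.83, 0.83, 0.17),
      new_block_spec(4, 1.00, 1.00, 0.00,
                     n_train_free = 24L, n_train_forced = 24L)),
    exp2 = list(
      new_block_spec(1, 0.75, 0.75, 0.25, n_train_free = 40L,
                     n_train_forced = 40L, n_test = 40L),
      new_block_spec(2, 0.85, 0.75, 0.25, n_train_free = 40L,
                     n_train_forced = 40L, n_test = 40L),
      new_block_spec(3, 0.95, 0.75, 0.25, n_train_free = 40L,
                     n_train_forced = 40L, n_test = 40L)),
    exp3 = list(
      new_block_spec(1, 0.75, 0.75, 0.75, incoherence = 0.00,
                     n_train_free = 40L, n_train_forced = 40L, n_test = 40L),
      new_block_spec(2, 0.75, 0.75, 0.75, incoherence = 0.15,
                     n_train_free = 40L, n_train_forced = 40L, n_test = 40L),
      new_block_spec(3, 0.75, 0.75, 0.75, incoherence = 0.30,
                     n_train_free = 40L, n_train_forced = 40L, n_test = 40L))
  )
  cfg <- structure(list(experiment = experiment, blocks = blocks,
                        seed = as.integer(seed)),
                   class = "task_config")
  permute_config(cfg, seed)
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>", x$experiment, "-", length(x$blocks), "blocks\n")
  for (b in x$blocks) {
    cat(sprintf(
      "  block %d: p_forced=%.2f free=%.2f/%.2f incoh=%.2f train=%d+%d test=%d\n",
      b$block_index, b$p_forced, b$p_free_a1, b$p_free_a2, b$incoherence,
      b$n_train_free, b$n_train_forced, b$n_test))
  }
  invisible(x)
}

# run `expr` under a temporary RNG state seeded by `seed`
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Re-permute the non-fixed blocks of a configuration
#'
#' Draws a fresh order for the movable blocks (fixed first blocks of the
#' relative-value and incoherence variants stay first). Used to randomize
#' block order across the subjects of a cohort, as in the published
#' designs.
#'
#' @param config a `task_config`.
#' @param seed integer seed for the permutation.
#' @return a `task_config` with the same block set.
#' @export
permute_config <- function(config, seed) {
  fixed_first <- config$experiment %in% c("exp2", "exp3")
  movable <- if (fixed_first) seq_along(config$blocks)[-1]
             else seq_along(config$blocks)
  if (length(movable) > 1) {
    ord <- local_rng(seed, sample(movable))
    config$blocks <- config$blocks[c(setdiff(seq_along(config$blocks),
                                             movable), ord)]
  }
  config$seed <- as.integer(seed %% .Machine$integer.max)
  config
}

#' State set of the task graph
#'
#' Experiments 1 and 2 use a 6-state graph (start, free cue, forced cue, one
#' forced terminal and two free terminals); experiment 3 adds a second forced
#' terminal so swaps can occur after forced selections too, for 7 states.
#'
#' @param config a `task_config` (or experiment name).
#' @return data.frame with columns `state` (s1..s7) and `role`.
#' @export
task_states <- function(config) {
  experiment <- if (inherits(config, "task_config")) config$experiment
                else match.arg(config, EXPERIMENTS)
  states <- data.frame(
    state = c("s1", "s2", "s3", "s4", "s5", "s6"),
    role = c("start", "free-cue", "forced-cue", "forced-terminal",
             "free-terminal-A", "free-terminal-B"),
    stringsAsFactors = FALSE)
  if (experiment == "exp3") {
    states <- rbind(states, data.frame(state = "s7",
                                       role = "forced-terminal-B",
                                       stringsAsFactors = FALSE))
  }
  states
}

# number of actions available at the forced 2nd-stage state
n_forced_actions <- function(config) {
  if (config$experiment == "exp3") 2L else 1L
}

#' Draw the outcome of one second-stage action
#'
#' With probability `block$incoherence` the displayed target is swapped to
#' the non-selected one (`coherent = FALSE`); the 0/1 reward is Bernoulli
#' with the probability attached to the *displayed* target. Uses the current
#' R random-number stream.
#'
#' @param block a block spec from [build_config()].
#' @param option `"free"` or `"forced"`.
#' @param action emitted action, `"a1"` or `"a2"`.
#' @return list with `displayed_target`, `coherent`, `reward`.
#' @export
draw_outcome <- function(block, option, action) {
  stopifnot(option %in% c("free", "forced"), action %in% c("a1", "a2"))
  coherent <- block$incoherence == 0 || stats::runif(1) >= block$incoherence
  displayed <- if (coherent) action else setdiff(c("a1", "a2"), action)
  p <- target_reward_prob(block, option, displayed)
  reward <- as.integer(stats::runif(1) < p)
  list(displayed_target = displayed, coherent = coherent, reward = reward)
}

# reward probability of a displayed target under a block
target_reward_prob <- function(block, option, displayed) {
  if (option == "forced") block$p_forced
  else if (displayed == "a1") block$p_free_a1
  else block$p_free_a2
}

#' Write / read a task configuration as JSON
#'
#' @param config a `task_config`.
#' @param path file path.
#' @return `read_task_config` returns a `task_config`.
#' @export
write_task_config <- function(config, path) {
  out <- list(experiment = config$experiment,
              seed = config$seed,
              blocks = lapply(config$blocks, function(b)
                b[c("block_index", "p_forced", "p_free_a1", "p_free_a2",
                    "incoherence", "n_train_free", "n_train_forced",
                    "n_test")]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$experiment) || is.null(raw$blocks)) {
    stop("not a task config file: ", path, call. = FALSE)
  }
  blocks <- lapply(raw$blocks, function(b)
    new_block_spec(b$block_index, b$p_forced, b$p_free_a1, b$p_free_a2,
                   b$incoherence, b$n_train_free, b$n_train_forced, b$n_test))
  structure(list(experiment = match.arg(raw$experiment, EXPERIMENTS),
                 blocks = blocks,
                 seed = as.integer(raw$seed %||% 1L)),
            class = "task_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
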