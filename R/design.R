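#' Gain and loss levels of the Loss Aversion Task
#'
#' The task offers mixed gambles with a 50/50 chance of winning one amount or
#' losing another. Gains run from $10 to $40 in $2 increments and losses from
#' $5 to $20 in $1 increments, giving a 16 x 16 grid of candidate gambles.
#'
#' @return `gain_levels()` and `loss_levels()` return integer vectors of the
#'   16 gain and 16 loss magnitudes (US dollars, losses as positive
#'   magnitudes).
#' @export
gain_levels <- function() seq(10L, 40L, by = 2L)

#' @rdname gain_levels
#' @export
loss_levels <- function() seq(5L, 20L, by = 1L)

#' Enumerate the full gamble grid
#'
#' @return A data frame with columns `gain` and `loss`, one row per cell of
#'   the 16 x 16 grid (256 gambles). The win probability is fixed at 0.5 for
#'   every gamble and is not stored.
#' @examples
#' nrow(enumerate_grid()) # 256
#' @export
enumerate_grid <- function() {
  grid <- expand.grid(loss = loss_levels(), gain = gain_levels(),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("gain", "loss")]
  grid <- grid[order(grid$gain, grid$loss), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Generate a task design
#'
#' Draws `n_trials` distinct gambles from the grid and shuffles their order.
#' The default, balanced sampler guarantees that each of the 16 gain levels
#' and each of the 16 loss levels appears equally often (8 times each at the
#' default 128 trials); it requires `n_trials` to be a multiple of 16. With
#' `balanced = FALSE` gambles are sampled uniformly without replacement.
#'
#' The balanced subsample is built from a cyclic Latin square on the grid:
#' cells whose (row + column) residue falls in a randomly chosen set of
#' `n_trials / 16` residues are selected after random relabelling of rows and
#' columns, which fixes both margins exactly while randomizing the subset.
#'
#' @param n_trials Number of trials (default 128; at most 256).
#' @param seed Integer seed; identical seeds reproduce the design exactly.
#' @param balanced Use the margin-balanced sampler (default `TRUE`).
#' @return A data frame of class `la_design` with columns
#'   `trial_index`, `gain`, `loss`.
#' @examples
#' d <- generate_design(128, seed = 1)
#' table(d$gain) # every gain level 8 times
#' @export
generate_design <- function(n_trials = 128L, seed = 1L, balanced = TRUE) {
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  grid <- enumerate_grid()
  if (n_trials > nrow(grid)) {
    stop(sprintf("n_trials = %d exceeds the %d-cell gamble grid",
                 n_trials, nrow(grid)), call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  if (balanced && n_trials %% 16L == 0L) {
    k <- n_trials %/% 16L
    gains <- sample(gain_levels())
    losses <- sample(loss_levels())
    residues <- sample(0:15, k)
    latin <- outer(0:15, 0:15, function(i, j) (i + j) %% 16L)
    cells <- which(matrix(latin %in% residues, 16L, 16L), arr.ind = TRUE)
    design <- data.frame(gain = gains[cells[, 1L]],
                         loss = losses[cells[, 2L]])
  } else {
    design <- grid[sample.int(nrow(grid), n_trials), , drop = FALSE]
  }
  design <- design[sample.int(nrow(design)), , drop = FALSE]
  out <- data.frame(trial_index = seq_len(nrow(design)),
                    gain = design$gain, loss = design$loss)
  rownames(out) <- NULL
  class(out) <- c("la_design", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  out
}

#' @noRd
validate_design <- function(design) {
  assert_columns(design, c("trial_index", "gain", "loss"), "design")
  grid <- enumerate_grid()
  key <- paste(design$gain, design$loss)
  if (!all(key %in% paste(grid$gain, grid$loss))) {
    stop("design contains gambles outside the task grid", call. = FALSE)
  }
  invisible(design)
}

#' Read or write a trial-list CSV
#'
#' The on-disk schema is `trial_index, gain, loss` with a header row and
#' 1-based trial indices.
#'
#' @param design A design as returned by [generate_design()].
#' @param path File path.
#' @return `read_design()` returns the validated design; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.csv(as.data.frame(design)[, c("trial_index", "gain", "loss")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  design <- utils::read.csv(path)
  validate_design(design)
  class(design) <- c("la_design", "data.frame")
  design
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
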