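#' Reproduction-task design
#'
#' Describes the block structure of the multi-duration reproduction task.
#' The standard design is 2 blocks of 120 trials in which each of the three
#' durations 1.17, 1.4 and 1.68 s is presented 40 times per block in random
#' order.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials in each block.
#' @param duration_levels Presented durations, in seconds.
#' @param presentations_per_level_per_block Occurrences of each level per
#'   block; defaults to `trials_per_block / length(duration_levels)` and must
#'   satisfy that identity exactly.
#'
#' @return A list of class `task_design`.
#' @examples
#' task_design()
#' @export
task_design <- function(n_blocks = 2L,
                        trials_per_block = 120L,
                        duration_levels = c(1.17, 1.4, 1.68),
                        presentations_per_level_per_block = NULL) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 1L || trials_per_block < 1L) {
    stop("n_blocks and trials_per_block must be positive", call. = FALSE)
  }
  if (length(duration_levels) < 1L || any(duration_levels <= 0) ||
      anyDuplicated(duration_levels)) {
    stop("duration_levels must be distinct positive durations", call. = FALSE)
  }
  k <- length(duration_levels)
  if (is.null(presentations_per_level_per_block)) {
    if (trials_per_block %% k != 0L) {
      stop("trials_per_block (", trials_per_block,
           ") is not divisible by the number of duration levels (", k, ")",
           call. = FALSE)
    }
    presentations_per_level_per_block <- trials_per_block %/% k
  }
  presentations_per_level_per_block <-
    as.integer(presentations_per_level_per_block)
  if (presentations_per_level_per_block * k != trials_per_block) {
    stop("trials_per_block must equal presentations_per_level_per_block ",
         "times the number of levels", call. = FALSE)
  }
  structure(
    list(n_blocks = n_blocks,
         trials_per_block = trials_per_block,
         duration_levels = as.numeric(duration_levels),
         presentations_per_level_per_block = presentations_per_level_per_block),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design> ", x$n_blocks, " block(s) x ", x$trials_per_block,
      " trials; levels {", paste(x$duration_levels, collapse = ", "),
      "} s, ", x$presentations_per_level_per_block,
      " presentations each per block\n", sep = "")
  invisible(x)
}
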