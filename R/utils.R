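#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across all_of n
#' @importFrom tibble tibble as_tibble
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers a user's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Named substreams: each pipeline stage draws from its own deterministic
# stream derived from the master seed, so stages are independently
# replayable and inserting a stage never shifts another stage's draws.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 1000003L)
}

#' Percent formatting used in reports
#'
#' Whole percents are truncated (686/2881 reports as 23, not 24); one-decimal
#' percents use round-half-even. Raw fractions are always returned by the
#' analysis functions themselves; formatting only happens at the report layer.
#'
#' @param x A fraction in \[0, 1\].
#' @param digits 0 for truncated whole percent, otherwise round-half-even to
#'   that many decimals.
#' @return A numeric percent value (not a string).
#' @examples
#' percent_value(686 / 2881)      # 23
#' percent_value(61 / 1698, 1)    # 3.6
#' @export
percent_value <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  if (digits == 0) {
    trunc(100 * x)
  } else {
    round(100 * x, digits)
  }
}
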