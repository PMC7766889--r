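# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

# coerce a signature-score data.frame (or named numeric) to a named vector
as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("sample", "score") %in% names(scores))) {
      stop2("score data.frame must have columns 'sample' and 'score'")
    }
    stats::setNames(scores$score, scores$sample)
  } else if (is.numeric(scores)) {
    if (is.null(names(scores)) && length(scores) > 0) {
      names(scores) <- paste0("S", seq_along(scores))
    }
    scores
  } else {
    stop2("scores must be a numeric vector or a signature-score data.frame")
  }
}
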