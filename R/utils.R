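#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded helpers do not disturb the global random
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve of a score against a truth flag
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive gene scores higher than a randomly chosen negative gene, with
#' ties counted 1/2. Used to quantify recovery of planted
#' differential-correlation modules.
#'
#' @param score Numeric vector; larger values mean stronger evidence.
#' @param truth Logical vector of the same length (TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
score_auc <- function(score, truth) {
  stopifnot(length(score) == length(truth), is.logical(truth))
  if (!any(truth) || all(truth)) stop("need both positive and negative labels")
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
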