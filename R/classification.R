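as_score_df <- function(scores) {
  scores <- as.data.frame(scores)
  stopifnot(all(c("fly_id", "score") %in% names(scores)), nrow(scores) >= 1)
  if (anyDuplicated(scores$fly_id)) stop("duplicate fly_id in scores", call. = FALSE)
  scores
}

#' Classify flies against a fixed decision threshold
#'
#' Flies whose combined score is greater than or equal to `theta` are called
#' GFP, the rest non-GFP (boundary inclusive on the GFP side). The margin is
#' the distance of the score from the threshold, a per-fly confidence proxy
#' for downstream QC.
#'
#' @param scores `data.frame` with `fly_id` and `score`.
#' @param theta decision threshold.
#' @return identity-call `data.frame`: `fly_id, label, score, margin`,
#'   ordered by fly id.
#' @export
classify_by_threshold <- function(scores, theta) {
  scores <- as_score_df(scores)
  out <- data.frame(fly_id = scores$fly_id,
                    label = ifelse(scores$score >= theta, "GFP", "non-GFP"),
                    score = scores$score,
                    margin = abs(scores$score - theta))
  out <- out[order(out$fly_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify flies using the expected number of GFP animals
#'
#' Sorts combined scores in descending order and labels the top `n_gfp` flies
#' GFP and the remainder non-GFP, exploiting prior knowledge of the group
#' composition. Ties at the cut are broken by ascending fly id, so the result
#' is invariant to input order. The margin is the distance of each score from
#' the cut value, the midpoint between the scores at ranks `n_gfp` and
#' `n_gfp + 1` (or the extreme score itself when `n_gfp` is 0 or the group
#' size).
#'
#' @param scores `data.frame` with `fly_id` and `score`.
#' @param n_gfp expected number of GFP flies, between 0 and the group size.
#' @return identity-call `data.frame`: `fly_id, label, score, margin`,
#'   ordered by fly id.
#' @export
classify_by_prior_count <- function(scores, n_gfp) {
  scores <- as_score_df(scores)
  n <- nrow(scores)
  if (n_gfp < 0 || n_gfp > n) {
    stop(sprintf("n_gfp must be between 0 and %d (got %s)", n, n_gfp), call. = FALSE)
  }
  ord <- order(-scores$score, scores$fly_id)
  s <- scores$score[ord]
  gfp <- rep(FALSE, n)
  if (n_gfp >= 1) gfp[ord[seq_len(n_gfp)]] <- TRUE
  cut <- if (n_gfp == 0) s[1] else if (n_gfp == n) s[n] else (s[n_gfp] + s[n_gfp + 1]) / 2
  out <- data.frame(fly_id = scores$fly_id,
                    label = ifelse(gfp, "GFP", "non-GFP"),
                    score = scores$score,
                    margin = abs(scores$score - cut))
  out <- out[order(out$fly_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
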