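#' @include accessors.R
NULL

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form of the AUC: the probability that a randomly
#' chosen presence receives a higher score than a randomly chosen absence,
#' with ties contributing one half. Threshold-independent; 0.5 means
#' predictions no better than random and 1 means perfect separation.
#'
#' @param labels 0/1 vector (1 = presence); both classes must be present.
#' @param scores numeric prediction scores, same length.
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(1, 1, 0, 0), c(0.9, 0.4, 0.8, 0.2))  # 0.75
#' @export
aucScore <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("labels and scores must be parallel", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
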