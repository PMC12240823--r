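#' ROC curve and AUC for a response-classification score
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counted 1/2 (equivalently the normalized
#' Mann-Whitney U; also the trapezoidal area under the ROC polygon). The
#' reported AUC always refers to the stated positive class; when it falls
#' below 0.5 the `direction` field records that larger scores favour the
#' negative class — the curve is never silently flipped.
#'
#' @param scores Numeric classification scores.
#' @param labels Class labels.
#' @param positive The label treated as positive (default
#'   `"responder"` if present, else the first level).
#' @return Object of class `roc_result`: descending `thresholds`, `fpr`,
#'   `tpr`, `auc`, class counts and direction metadata.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.character(labels[keep])
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present")
  if (length(classes) > 2) stop("more than two classes")
  if (is.null(positive))
    positive <- if ("responder" %in% classes) "responder" else classes[1]
  if (!positive %in% classes) stop("positive class not present")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  # DeLong structural-component variance and Wald 95% CI
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (n_pos >= 2 && n_neg >= 2) {
    comp <- delong_components(scores, pos)
    se <- sqrt(stats::var(comp$v10) / n_pos + stats::var(comp$v01) / n_neg)
    ci <- pmin(pmax(auc + c(-1.96, 1.96) * se, 0), 1)
  }
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 se = se, ci_low = ci[1], ci_high = ci[2],
                 n_pos = n_pos, n_neg = n_neg, positive = positive,
                 direction = if (auc >= 0.5) "higher-score-positive"
                 else "higher-score-negative"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (positive = %s, n = %d/%d, %s)\n",
              x$auc, x$positive, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

# DeLong structural components for one score
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test comparing two correlated ROC curves
#'
#' Paired DeLong test: per-positive (V10) and per-negative (V01)
#' structural components are computed for both scores on the same
#' subjects; the covariance of the two AUCs follows from the component
#' sample covariances, and `z = (auc1 - auc2) / sqrt(var(delta))` is
#' referred to the standard normal. Identical scores give `delta = 0`,
#' `p = 1`. The components are rank-based, so any strictly monotone
#' transform of a score leaves its AUC and the test unchanged.
#'
#' @param scores1,scores2 Two scores for the same subjects.
#' @param labels Class labels.
#' @param positive Positive class (see [roc_auc()]).
#' @return Object of class `delong_result` with `auc1`, `auc2`, `delta`,
#'   `z`, two-sided `p` and the 2x2 AUC covariance matrix.
#' @export
delong_compare <- function(scores1, scores2, labels, positive = NULL) {
  keep <- !is.na(scores1) & !is.na(scores2) & !is.na(labels)
  scores1 <- scores1[keep]; scores2 <- scores2[keep]
  labels <- as.character(labels[keep])
  classes <- unique(labels)
  if (length(classes) != 2) stop("exactly two classes required")
  if (is.null(positive))
    positive <- if ("responder" %in% classes) "responder" else classes[1]
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m < 2 || n < 2) stop("need >= 2 subjects per class")
  c1 <- delong_components(scores1, pos)
  c2 <- delong_components(scores2, pos)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  delta <- c1$auc - c2$auc
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_delta <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = c1$auc, auc2 = c2$auc, delta = delta, z = z,
                 p = p, cov = S, positive = positive),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(
    "delong_result: AUC1 = %.3f, AUC2 = %.3f, delta = %.3f, z = %.3f, p = %.4g\n",
    x$auc1, x$auc2, x$delta, x$z, x$p))
  invisible(x)
}

#' Classify treatment response from deviation summary scores
#'
#' Builds ROC curves for a set of per-subject scores against the response
#' label and, optionally, DeLong comparisons of every score against a
#' reference score (e.g. striatal Ki).
#'
#' @param scores Data frame of per-subject numeric scores (columns are
#'   score names).
#' @param labels Response labels (`responder` / `nonresponder`; subjects
#'   labelled `unknown` are dropped).
#' @param reference Optional column name compared against all others with
#'   the DeLong test.
#' @return List with `roc` (named list of [roc_auc()] results), `table`
#'   (tidy AUC data frame) and `delong` (tidy comparison table or NULL).
#' @export
classify_response <- function(scores, labels, reference = NULL) {
  scores <- as.data.frame(scores)
  keep <- labels %in% c("responder", "nonresponder")
  scores <- scores[keep, , drop = FALSE]; labels <- labels[keep]
  roc <- lapply(scores, roc_auc, labels = labels)
  tab <- data.frame(score = names(roc),
                    auc = vapply(roc, `[[`, numeric(1), "auc"),
                    n_pos = vapply(roc, `[[`, numeric(1), "n_pos"),
                    n_neg = vapply(roc, `[[`, numeric(1), "n_neg"),
                    row.names = NULL, stringsAsFactors = FALSE)
  dl <- NULL
  if (!is.null(reference)) {
    if (!reference %in% names(scores)) stop("unknown reference score")
    others <- setdiff(names(scores), reference)
    dl <- do.call(rbind, lapply(others, function(s) {
      d <- delong_compare(scores[[s]], scores[[reference]], labels)
      data.frame(score = s, reference = reference, auc = d$auc1,
                 auc_ref = d$auc2, delta = d$delta, z = d$z, p = d$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(roc = roc, table = tab, delong = dl)
}
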