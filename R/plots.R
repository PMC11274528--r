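#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means, with the mean
#' difference and the 95% limits of agreement drawn as horizontal lines.
#'
#' @param x,y the two measurement series
#' @param xlab,ylab,main axis and title labels
#' @return invisibly, the [bland_altman()] summary
#' @export
plot_bland_altman <- function(x, y, xlab = "mean of methods",
                              ylab = "difference (x - y)",
                              main = "Bland-Altman") {
  ba <- bland_altman(x, y)
  mn <- (x + y) / 2
  d <- x - y
  plot(mn, d, pch = 19, col = "#00000080", xlab = xlab, ylab = ylab,
       main = main,
       ylim = range(c(d, ba$loa_low, ba$loa_high), finite = TRUE))
  abline(h = ba$mean_diff, col = "steelblue", lwd = 2)
  abline(h = c(ba$loa_low, ba$loa_high), col = "firebrick", lty = 2)
  invisible(ba)
}

#' ROC curve plot
#'
#' Draws the empirical ROC curve from [roc_optimal_threshold()] and marks
#' the optimal operating point.
#'
#' @param roc result of [roc_optimal_threshold()]
#' @param main plot title
#' @return invisibly, `roc`
#' @export
plot_roc <- function(roc, main = "ROC") {
  cv <- roc$curve[order(roc$curve$fpr, roc$curve$tpr), ]
  plot(cv$fpr, cv$tpr, type = "l", lwd = 2, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity", main = main)
  abline(0, 1, lty = 3, col = "grey50")
  points(1 - roc$specificity / 100, roc$sensitivity / 100, pch = 19,
         col = "firebrick", cex = 1.3)
  legend("bottomright", bty = "n",
         legend = c(sprintf("AUC = %.3f", roc$auc),
                    sprintf("optimal > %.1f%%", roc$threshold)))
  invisible(roc)
}
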