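#' Panel of landmark estimates from multiple raters
#'
#' Holds one landmark estimate per image per rater, in a single metric
#' (distance in microns or cell count). Rater 0 is the computer; the
#' remaining columns are human experts.
#'
#' @param estimates Numeric matrix or data frame, rows = images,
#'   columns = raters, with the computer first. Column names are kept if
#'   present; otherwise `computer`, `expert1`, ... are assigned.
#' @param metric `"distance_um"` or `"cell_count"`.
#' @return An object of class `rater_panel`.
#' @export
rater_panel <- function(estimates, metric = c("distance_um", "cell_count")) {
  metric <- match.arg(metric)
  m <- as.matrix(estimates)
  if (!is.numeric(m)) stop("estimates must be numeric")
  if (ncol(m) < 3)
    stop("a panel needs the computer plus at least 2 experts")
  if (any(!is.finite(m))) stop("estimates must be finite, with no missing cells")
  if (is.null(colnames(m)))
    colnames(m) <- c("computer", paste0("expert", seq_len(ncol(m) - 1)))
  structure(list(estimates = m, metric = metric,
                 n_experts = ncol(m) - 1L),
            class = "rater_panel")
}

#' @export
print.rater_panel <- function(x, ...) {
  cat(sprintf("<rater_panel> %d images x (computer + %d experts), %s\n",
              nrow(x$estimates), x$n_experts, x$metric))
  invisible(x)
}

#' Read a rater panel from CSV
#'
#' Expects a header row naming the raters, a first column of image ids,
#' and a column named `computer` (moved first if not already).
#'
#' @param path CSV path.
#' @param metric Passed to [rater_panel()].
#' @return A [rater_panel].
#' @export
read_panel <- function(path, metric = c("distance_um", "cell_count")) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- df[, -1, drop = FALSE]
  if (!"computer" %in% names(vals))
    stop("panel CSV must have a column named 'computer'")
  vals <- vals[, c("computer", setdiff(names(vals), "computer")),
               drop = FALSE]
  rater_panel(as.matrix(vals), metric = match.arg(metric))
}

#' Pairwise rater disagreements
#'
#' The disagreement D between two raters is their mean absolute difference
#' across images. Returns the computer-to-expert vector `D0` and the
#' expert-to-expert matrix `Dpair` (symmetric; only the upper triangle is
#' meaningful). A zero disagreement anywhere is an error, because the
#' Williams Index takes reciprocals of every D.
#'
#' @param panel A [rater_panel].
#' @return An object of class `disagreement_matrix` with elements `D0`
#'   (length n) and `Dpair` (n x n, diagonal `NA`).
#' @export
pairwise_disagreement <- function(panel) {
  stopifnot(inherits(panel, "rater_panel"))
  m <- panel$estimates
  n <- panel$n_experts
  D0 <- vapply(seq_len(n) + 1L,
               function(j) mean(abs(m[, 1] - m[, j])), numeric(1))
  names(D0) <- colnames(m)[-1]
  Dpair <- matrix(NA_real_, n, n, dimnames = list(colnames(m)[-1],
                                                  colnames(m)[-1]))
  for (j in seq_len(n - 1))
    for (k in (j + 1):n) {
      Dpair[j, k] <- mean(abs(m[, j + 1] - m[, k + 1]))
      Dpair[k, j] <- Dpair[j, k]
    }
  if (any(D0 == 0) || any(Dpair[upper.tri(Dpair)] == 0))
    stop(paste("zero pairwise disagreement: the Williams Index is",
               "undefined (identical raters)"))
  structure(list(D0 = D0, Dpair = Dpair, n = n),
            class = "disagreement_matrix")
}

#' @export
print.disagreement_matrix <- function(x, ...) {
  cat(sprintf("<disagreement_matrix> computer vs %d experts\n", x$n))
  cat("D0:", format(x$D0, digits = 4), "\n")
  invisible(x)
}

#' Williams Index of computer-to-expert agreement
#'
#' The ratio of the average computer-to-expert agreement to the average
#' inter-expert agreement,
#' \deqn{I' = \frac{\frac{1}{n}\sum_j 1/D_{0,j}}
#'                 {\frac{2}{n(n-1)}\sum_{j<j'} 1/D_{j,j'}},}
#' where agreement is the reciprocal of disagreement. An index of 1 (or
#' above) means the computer agrees with the experts as much as the
#' experts agree with one another.
#'
#' @param dm A [disagreement_matrix].
#' @return The scalar index I'.
#' @export
williams_index <- function(dm) {
  stopifnot(inherits(dm, "disagreement_matrix"))
  n <- dm$n
  num <- mean(1 / dm$D0)
  denom <- 2 / (n * (n - 1)) * sum(1 / dm$Dpair[upper.tri(dm$Dpair)])
  num / denom
}

#' Jackknife confidence interval for the Williams Index
#'
#' Leave-one-image-out jackknife over the panel rows; an extension beyond
#' the bare index (which by itself carries no uncertainty statement).
#'
#' @param panel A [rater_panel] with >= 3 images.
#' @param conf Confidence level (default 0.95).
#' @return List with `index`, `lower`, `upper` and `se`.
#' @export
williams_ci <- function(panel, conf = 0.95) {
  stopifnot(inherits(panel, "rater_panel"))
  m <- nrow(panel$estimates)
  if (m < 3) stop("jackknife CI needs at least 3 images")
  full <- williams_index(pairwise_disagreement(panel))
  loo <- vapply(seq_len(m), function(i) {
    p <- rater_panel(panel$estimates[-i, , drop = FALSE],
                     metric = panel$metric)
    williams_index(pairwise_disagreement(p))
  }, numeric(1))
  se <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(index = full, lower = full - z * se, upper = full + z * se, se = se)
}

#' Simulated rater-panel study
#'
#' Builds a synthetic panel in which each expert reports the true landmark
#' plus independent Gaussian noise, while the computer's estimates are
#' supplied by the caller, and returns the Williams Index. Useful for
#' checking that a truth-tracking computer scores above 1 against
#' inter-expert scatter.
#'
#' @param truth True landmark value per image.
#' @param expert_noise_sd Standard deviation of expert noise (same units).
#' @param n_experts Number of simulated experts (>= 2).
#' @param computer_values Computer estimate per image (same length as
#'   `truth`).
#' @param seed RNG seed.
#' @return The scalar Williams Index of the simulated panel.
#' @export
panel_study <- function(truth, expert_noise_sd, n_experts,
                        computer_values, seed) {
  if (length(computer_values) != length(truth))
    stop("computer_values and truth must have the same length")
  set.seed(seed)
  experts <- vapply(seq_len(n_experts), function(j)
    truth + stats::rnorm(length(truth), 0, expert_noise_sd),
    numeric(length(truth)))
  panel <- rater_panel(cbind(computer = computer_values, experts))
  williams_index(pairwise_disagreement(panel))
}
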