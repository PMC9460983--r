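# Model performance metrics: zero-intercept regression of observed on
# modelled transpiration, per-tree (N)RMSE, and the residual versus
# water-table-temperature correlation.

#' Zero-intercept regression of observed on modelled values
#'
#' Fits `obs = b * mod` by least squares; the slope has the closed form
#' \eqn{b = \sum xy / \sum x^2}. Two R-squared conventions are available
#' for the through-origin fit: `"centered"` (default),
#' \eqn{1 - \sum(y - bx)^2 / \sum(y - \bar y)^2}, which compares against
#' the mean model and can be negative; and `"uncentered"`,
#' \eqn{1 - \sum(y - bx)^2 / \sum y^2}.
#'
#' @param obs,mod Aligned numeric vectors; pairs with a non-finite member
#'   are dropped.
#' @param r2 R-squared convention.
#' @return list `slope, r_squared, n, p_value` (two-sided slope test).
#' @export
zero_intercept_fit <- function(obs, mod, r2 = c("centered", "uncentered")) {
  r2 <- match.arg(r2)
  ok <- is.finite(obs) & is.finite(mod)
  x <- mod[ok]; y <- obs[ok]
  n <- length(x)
  if (n < 2 || all(x == 0)) stop("need >= 2 points with non-zero model values")
  b <- sum(x * y) / sum(x * x)
  rss <- sum((y - b * x)^2)
  tss <- if (r2 == "centered") sum((y - mean(y))^2) else sum(y^2)
  se <- sqrt(rss / (n - 1) / sum(x * x))
  tval <- b / se
  list(slope = b, r_squared = 1 - rss / tss, n = n,
       p_value = 2 * stats::pt(-abs(tval), df = n - 1))
}

#' Per-tree root-mean-square error statistics
#'
#' \eqn{RMSE_i = \sqrt{\sum_j \varepsilon_{ij}^2 / N_i}} and its
#' normalization by the tree's mean observation,
#' \eqn{NRMSE_i = 100\, RMSE_i / \bar E_i^{(O)}} (percent).
#'
#' @param obs,mod (day x tree) matrices, `NA` where unobserved.
#' @param tree_id Optional tree labels (defaults to column order).
#' @return data.frame `tree_id, n, rmse, nrmse`.
#' @export
pf_tree_errors <- function(obs, mod, tree_id = NULL) {
  obs <- as.matrix(obs); mod <- as.matrix(mod)
  stopifnot(all(dim(obs) == dim(mod)))
  if (is.null(tree_id)) tree_id <- as.character(seq_len(ncol(obs)))
  out <- lapply(seq_len(ncol(obs)), function(j) {
    ok <- is.finite(obs[, j]) & is.finite(mod[, j])
    eps <- obs[ok, j] - mod[ok, j]
    rmse <- sqrt(mean(eps^2))
    data.frame(tree_id = tree_id[j], n = sum(ok), rmse = rmse,
               nrmse = 100 * rmse / mean(obs[ok, j]))
  })
  do.call(rbind, out)
}

#' Correlation of model residuals with water-table temperature
#'
#' Pearson correlation between the transpiration residuals and the water
#' temperature in the WTD tubes, on the full data and within masks (cold
#' water, shallow water table). Masks with fewer than 3 paired points
#' give `NA` with a message.
#'
#' @param eps Residual vector.
#' @param wtt Water-table temperature vector (degrees C), aligned.
#' @param masks Named list of logical vectors aligned with `eps`; the
#'   full-data correlation is always reported under `"full"`.
#' @return data.frame `mask, n, r, p_value`.
#' @export
residual_wtt_correlation <- function(eps, wtt, masks = list()) {
  stopifnot(length(eps) == length(wtt))
  masks <- c(list(full = rep(TRUE, length(eps))), masks)
  out <- lapply(names(masks), function(nm) {
    keep <- masks[[nm]] & is.finite(eps) & is.finite(wtt)
    if (sum(keep) < 3) {
      message("mask '", nm, "' has fewer than 3 points; r = NA")
      return(data.frame(mask = nm, n = sum(keep), r = NA_real_,
                        p_value = NA_real_))
    }
    ct <- stats::cor.test(eps[keep], wtt[keep])
    data.frame(mask = nm, n = sum(keep), r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Evaluate a fitted model on the full and shallow-WTD subsets
#'
#' The overall performance view: zero-intercept regression of observed on
#' MAP-modelled transpiration on all data and restricted to
#' shallow-water-table days (depth above `delta_star - 10`, the hypoxic
#' decline region of the fitted model), plus per-tree error statistics.
#' For the variant without a belowground model (RM1) or when no
#' `delta_star` is available the shallow subset is skipped.
#'
#' @param fit A [pf_fit()] object.
#' @param delta_star Shallow-subset threshold origin; defaults to the
#'   fitted MAP `delta_star` (FM only).
#' @param r2 R-squared convention, see [zero_intercept_fit()].
#' @return list `full, shallow` (regression reports; `shallow` may be
#'   `NULL`) and `tree_errors`.
#' @export
pf_evaluate <- function(fit, delta_star = NULL, r2 = "centered") {
  al <- .aligned_obs_mod(fit)
  full <- zero_intercept_fit(al$obs, al$mod, r2)
  if (is.null(delta_star) && fit$variant == "FM") {
    delta_star <- decode_params(fit$map, fit$priors)$delta_star
  }
  shallow <- NULL
  if (!is.null(delta_star)) {
    sh <- matrix(al$delta < delta_star - 10, length(al$delta),
                 nrow(fit$trees))
    keep <- al$ok & sh
    if (sum(keep) >= 2) {
      shallow <- zero_intercept_fit(al$obs_mat[keep], al$mod_mat[keep], r2)
      shallow$threshold_cm <- delta_star - 10
    }
  }
  list(full = full, shallow = shallow,
       tree_errors = pf_tree_errors(al$obs_mat, al$mod_mat,
                                    fit$trees$tree_id))
}
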