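## Reconstruction quality metrics: relative error, Pearson correlation,
## structural similarity, and per-phase Dice over thresholded inclusion
## masks, plus grouped reporting.

.metric_pixels <- function(x, mask = NULL) {
  if (is.null(mask)) as.vector(x) else as.vector(x)[as.vector(mask)]
}

#' Relative error
#'
#' l2 norm of the reconstruction error over the l2 norm of the truth,
#' computed over in-disk pixels.
#'
#' @param x truth image (matrix).
#' @param x_hat reconstructed image.
#' @param mask logical mask of pixels to include (default: all).
#' @return scalar RE >= 0.
#' @export
relative_error <- function(x, x_hat, mask = NULL) {
  xv <- .metric_pixels(x, mask); hv <- .metric_pixels(x_hat, mask)
  den <- sqrt(sum(xv^2))
  if (den == 0) stop("zero-norm truth image in relative error", call. = FALSE)
  sqrt(sum((hv - xv)^2)) / den
}

#' Pearson correlation coefficient between images
#'
#' @inheritParams relative_error
#' @return CC in [-1, 1]; `NA` (with a warning) if either image is constant.
#' @export
corr_coeff <- function(x, x_hat, mask = NULL) {
  xv <- .metric_pixels(x, mask); hv <- .metric_pixels(x_hat, mask)
  if (stats::sd(xv) == 0 || stats::sd(hv) == 0) {
    warning("constant image: correlation undefined")
    return(NA_real_)
  }
  stats::cor(xv, hv)
}

#' Structural similarity index
#'
#' Mean local SSIM over sliding uniform windows with stability constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, where `L` is the dynamic range of
#' the truth image.  `window = NULL` computes the single-window (global)
#' statistic.
#'
#' @param x truth image (matrix).
#' @param x_hat reconstructed image of the same size.
#' @param window odd window edge length (default 7), or NULL for global.
#' @param L dynamic range; default `max(x) - min(x)` (1 if degenerate).
#' @return scalar SSIM (1 for identical images).
#' @export
ssim <- function(x, x_hat, window = 7L, L = NULL) {
  if (!all(dim(x) == dim(x_hat))) stop("image size mismatch", call. = FALSE)
  if (is.null(L)) {
    L <- diff(range(x))
    if (L == 0) L <- 1
  }
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  one <- function(a, b) {
    mx <- mean(a); my <- mean(b)
    vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
    cxy <- mean((a - mx) * (b - my))
    ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  if (is.null(window)) return(one(as.vector(x), as.vector(x_hat)))
  w <- as.integer(window)
  n <- nrow(x); m <- ncol(x)
  if (w > n || w > m) stop("SSIM window larger than image", call. = FALSE)
  ## sliding-window moments via cumulative sums
  slide_mean <- function(img) {
    cs <- apply(apply(img, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
    cs <- t(cs)
    pad <- matrix(0, n + 1, m + 1)
    pad[-1, -1] <- cs
    i1 <- 1:(n - w + 1); j1 <- 1:(m - w + 1)
    (pad[i1 + w, j1 + w, drop = FALSE] - pad[i1, j1 + w, drop = FALSE] -
       pad[i1 + w, j1, drop = FALSE] + pad[i1, j1, drop = FALSE]) / (w * w)
  }
  mx <- slide_mean(x); my <- slide_mean(x_hat)
  mxx <- slide_mean(x * x); myy <- slide_mean(x_hat * x_hat)
  mxy <- slide_mean(x * x_hat)
  vx <- mxx - mx^2; vy <- myy - my^2
  cxy <- mxy - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Threshold a conductivity-change image into inclusion masks
#'
#' The positive-phase mask contains pixels strictly above half the image
#' maximum and the negative-phase mask pixels strictly below half the image
#' minimum; a phase is only extracted when the corresponding extreme exceeds
#' 5% of the phantom contrast scale, otherwise its mask is empty.
#'
#' @param image conductivity-change image.
#' @param contrast_scale scale against which the 5% floor is applied
#'   (default 0.9 S/m, the smallest nominal inclusion contrast of the
#'   phantom family; use ~1 for model-unit images).
#' @return list(positive, negative) logical masks.
#' @export
binarize_for_dice <- function(image, contrast_scale = 0.9) {
  floor_ <- 0.05 * contrast_scale
  hi <- max(image); lo <- min(image)
  pos <- if (hi > floor_) image > 0.5 * hi else array(FALSE, dim(image))
  neg <- if (lo < -floor_) image < 0.5 * lo else array(FALSE, dim(image))
  list(positive = pos, negative = neg)
}

.dice_masks <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Dice overlap between reconstructed and true inclusions
#'
#' Images are thresholded with [binarize_for_dice()]; Dice is computed per
#' conductivity phase present in the truth and averaged over those phases.
#' A truth with no phase at all scores 1 against an empty reconstruction and
#' 0 otherwise.
#'
#' @inheritParams relative_error
#' @param contrast_scale passed to [binarize_for_dice()].
#' @return scalar Dice in [0, 1].
#' @export
dice <- function(x, x_hat, contrast_scale = 0.9) {
  mt <- binarize_for_dice(x, contrast_scale)
  mh <- binarize_for_dice(x_hat, contrast_scale)
  present <- c(positive = sum(mt$positive) > 0, negative = sum(mt$negative) > 0)
  if (!any(present)) {
    return(as.numeric(sum(mh$positive) + sum(mh$negative) == 0))
  }
  vals <- c(
    if (present["positive"]) .dice_masks(mt$positive, mh$positive),
    if (present["negative"]) .dice_masks(mt$negative, mh$negative))
  mean(vals)
}

#' Encode background / low / high masks as a reference label map
#'
#' @param background,low,high disjoint, covering logical masks.
#' @return integer matrix with labels 0 (background), 1 (low-conductivity
#'   inclusion), 2 (high-conductivity inclusion).
#' @export
encode_reference_map <- function(background, low, high) {
  if (any(background & low) || any(background & high) || any(low & high)) {
    stop("masks overlap", call. = FALSE)
  }
  if (!all(background | low | high)) stop("masks do not cover the image", call. = FALSE)
  out <- matrix(0L, nrow(background), ncol(background))
  out[low] <- 1L
  out[high] <- 2L
  out
}

#' Decode a reference label map back into masks
#' @param labels integer matrix of 0/1/2 labels.
#' @return list(background, low, high) logical masks.
#' @export
decode_reference_map <- function(labels) {
  if (!all(labels %in% 0:2)) stop("labels must be 0, 1 or 2", call. = FALSE)
  list(background = labels == 0L, low = labels == 1L, high = labels == 2L)
}

#' Per-sample metrics and grouped summary report
#'
#' Computes RE, CC, SSIM and Dice for each (truth, reconstruction) pair and
#' aggregates mean and sample standard deviation over grouping keys, the
#' layout used to compare reconstruction methods.
#'
#' @param truth res x res x N array of true conductivity changes.
#' @param recon res x res x N array of reconstructions.
#' @param groups data.frame of per-sample keys (e.g. method, subset, snr_db);
#'   `NULL` for a single group.
#' @param mask in-disk mask applied to RE/CC.
#' @param contrast_scale passed to [dice()].
#' @return a `metrics_report`: list(per_sample = data.frame, summary =
#'   data.frame with mean/sd/n per metric and group).
#' @export
evaluate_recons <- function(truth, recon, groups = NULL, mask = NULL,
                            contrast_scale = 0.9) {
  if (!all(dim(truth) == dim(recon))) stop("array shape mismatch", call. = FALSE)
  N <- dim(truth)[3]
  per <- data.frame(
    RE = vapply(seq_len(N), function(i)
      relative_error(truth[, , i], recon[, , i], mask), numeric(1)),
    CC = vapply(seq_len(N), function(i)
      corr_coeff(truth[, , i], recon[, , i], mask), numeric(1)),
    SSIM = vapply(seq_len(N), function(i)
      ssim(truth[, , i], recon[, , i]), numeric(1)),
    Dice = vapply(seq_len(N), function(i)
      dice(truth[, , i], recon[, , i], contrast_scale), numeric(1)))
  if (is.null(groups)) groups <- data.frame(group = rep("all", N))
  per <- cbind(groups, per)
  keys <- names(groups)
  agg <- stats::aggregate(per[c("RE", "CC", "SSIM", "Dice")], per[keys],
                          function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = stats::sd(v),
                                        n = sum(!is.na(v))))
  ## flatten the matrix columns produced by aggregate
  summary <- agg[keys]
  for (m in c("RE", "CC", "SSIM", "Dice")) {
    summary[[paste0(m, "_mean")]] <- agg[[m]][, "mean"]
    summary[[paste0(m, "_sd")]] <- agg[[m]][, "sd"]
  }
  summary$n <- agg$RE[, "n"]
  structure(list(per_sample = per, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  s <- x$summary
  keys <- setdiff(names(s), c(outer(c("RE", "CC", "SSIM", "Dice"),
                                    c("_mean", "_sd"), paste0), "n"))
  cat("<metrics_report> mean +/- sd by group\n")
  for (i in seq_len(nrow(s))) {
    cat(" ", paste(unlist(s[i, keys, drop = FALSE]), collapse = " / "), ": ")
    cat(sprintf("RE %.3f+/-%.3f  CC %.3f+/-%.3f  SSIM %.3f+/-%.3f  Dice %.3f+/-%.3f (n=%d)\n",
                s$RE_mean[i], s$RE_sd[i], s$CC_mean[i], s$CC_sd[i],
                s$SSIM_mean[i], s$SSIM_sd[i], s$Dice_mean[i], s$Dice_sd[i],
                s$n[i]))
  }
  invisible(x)
}

#' Write a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(per_sample = report$per_sample,
                            summary = report$summary),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
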