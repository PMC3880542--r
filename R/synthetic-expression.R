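# Synthetic one-colour array generator with planted fold changes.

#' Generate a synthetic expression matrix with planted fold changes
#'
#' Emulates the pooled-replicate design of the screen: `n_control` DMSO and
#' `n_treated` DAPT arrays (4 + 4 by default, mirroring four independent
#' culture sets per condition). Per-gene baselines are log-normal; control
#' intensities are the baseline under multiplicative log-normal noise;
#' treated intensities are additionally multiplied by the planted ratio
#' (`fc` if `fc > 0`, else `1/|fc|`). Each array is then multiplied by a
#' random global scale factor (log-uniform in `scale_factor_range`) so the
#' percentile-normalization stage has real work to do.
#'
#' Planted genes are given baselines outside the central quartile band of
#' the unplanted baseline distribution (upregulated above Q3, downregulated
#' below Q1). Planting therefore never moves a gene across the array
#' median, the 50th-percentile normalizer stays pinned by unplanted genes,
#' and with `noise_sd = 0` every planted fold change is recovered exactly
#' after normalization.
#'
#' @param truth a [ground_truth()]; `truth$planted_fc` supplies the effect
#'   sizes.
#' @param n_control,n_treated replicate arrays per condition (>= 1).
#' @param n_genes total genes on the array; must be at least
#'   `4 * length(truth$planted_fc)` so the quartile band stays pinned.
#' @param noise_sd standard deviation of the log-scale (natural log)
#'   multiplicative noise; `>= 0`. Default 0.1, the calibrated
#'   between-replicate spread of the noisy study condition.
#' @param scale_factor_range range of per-array global scale factors,
#'   drawn log-uniformly; use `c(1, 1)` for unit factors.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline intensities.
#' @param seed integer seed (defaults to `truth$seed`).
#' @return an [expression_matrix()]; attribute `"scale_factors"` records
#'   the per-array factors and `"baselines"` the per-gene baselines.
#' @examples
#' gt <- ground_truth(c(Hes5 = -56.83, Dll1 = 2.26), seed = 1)
#' em <- generate_expression(gt, n_genes = 100, noise_sd = 0)
#' em
#' @export
generate_expression <- function(truth,
                                n_control = 4L, n_treated = 4L,
                                n_genes = 2000L, noise_sd = 0.1,
                                scale_factor_range = c(0.5, 2),
                                baseline_meanlog = log(500),
                                baseline_sdlog = 1,
                                seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_control < 1L || n_treated < 1L) {
    stop("need at least one replicate per condition", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  }
  planted <- truth$planted_fc
  n_planted <- length(planted)
  if (n_genes < max(1L, 4L * n_planted)) {
    stop(
      "`n_genes` must be at least 4x the number of planted genes (",
      4L * n_planted, ")",
      call. = FALSE
    )
  }
  if (length(scale_factor_range) != 2L || any(scale_factor_range <= 0) ||
    scale_factor_range[1] > scale_factor_range[2]) {
    stop("`scale_factor_range` must be positive and ordered", call. = FALSE)
  }

  with_seed(seed, {
    n_bg <- n_genes - n_planted
    bg_genes <- sprintf("gene_%04d", seq_len(n_bg))
    genes <- c(names(planted), bg_genes)

    baseline <- setNames(numeric(n_genes), genes)
    baseline[bg_genes] <- rlnorm(n_bg, baseline_meanlog, baseline_sdlog)
    if (n_planted > 0L) {
      qs <- quantile(baseline[bg_genes], c(0.25, 0.75),
        names = FALSE, type = 7
      )
      up <- planted > 0
      # upregulated genes seated above Q3, downregulated below Q1; the
      # jitter width keeps them clear of the quartile boundaries
      baseline[names(planted)[up]] <-
        qs[2] * exp(runif(sum(up), 0.25, 1.5))
      baseline[names(planted)[!up]] <-
        qs[1] * exp(-runif(sum(!up), 0.25, 1.5))
    }

    ratio <- setNames(rep(1, n_genes), genes)
    if (n_planted > 0L) {
      ratio[names(planted)] <- ifelse(planted > 0, planted, 1 / abs(planted))
    }

    n_samples <- n_control + n_treated
    samples <- c(
      sprintf("ctrl_%d", seq_len(n_control)),
      sprintf("dapt_%d", seq_len(n_treated))
    )
    condition <- setNames(
      rep(c("control", "treated"), c(n_control, n_treated)), samples
    )
    expected <- matrix(baseline,
      nrow = n_genes, ncol = n_samples,
      dimnames = list(genes, samples)
    )
    expected[, condition == "treated"] <-
      expected[, condition == "treated"] * ratio
    noise <- if (noise_sd > 0) {
      matrix(exp(rnorm(n_genes * n_samples, 0, noise_sd)),
        nrow = n_genes
      )
    } else {
      1
    }
    sf <- exp(runif(n_samples, log(scale_factor_range[1]),
      log(scale_factor_range[2])
    ))
    mat <- expected * noise
    mat <- sweep(mat, 2L, sf, `*`)

    out <- expression_matrix(mat, condition)
    attr(out, "scale_factors") <- setNames(sf, samples)
    attr(out, "baselines") <- baseline
    out
  })
}
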