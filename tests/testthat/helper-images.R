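# Deterministic random image pairs used for the PSNR/SSIM reference
# comparison. The frozen expected values in ref-metrics.csv were computed with
# scikit-image 0.26 (peak_signal_noise_ratio with data_range=1;
# structural_similarity with data_range=1, gaussian_weights=TRUE, sigma=1.5,
# use_sample_covariance=FALSE) on exactly these pairs.
make_metric_pairs <- function(n = 20) {
  withr::with_seed(101, {
    lapply(seq_len(n), function(i) {
      h <- sample(32:64, 1)
      w <- sample(32:64, 1)
      ref <- matrix(runif(h * w), h, w)
      noise <- matrix(rnorm(h * w, 0, runif(1, 0.01, 0.2)), h, w)
      test <- pmin(pmax(ref + noise, 0), 1)
      list(ref = ref, test = test)
    })
  })
}
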