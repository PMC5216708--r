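# shared fixtures and independent oracles for the suite

# small acquisition geometry used by most simulation tests
tiny_acq <- function(n_lines = 24, n_samples = 700) {
  acq_params(n_lines = n_lines, n_samples = n_samples,
             sampling_rate = 40e6, line_pitch = 0.3e-3,
             depth_origin = 2e-3)
}

# geometry for the estimator-recovery experiments
recovery_acq <- function() {
  acq_params(n_lines = 40, n_samples = 1200, sampling_rate = 40e6,
             line_pitch = 0.3e-3, depth_origin = 2e-3)
}

simulate_sample_frame <- function(medium, acq, seed) {
  field <- sample_field(medium, acq_volume(acq, medium$sound_speed),
                        seed = seed)
  synthesize_rf(field, pulse_spec(), acq, medium, noise_seed = seed + 5000L)
}

# brute-force nearest-neighbor scan: independent of knn_predict internals
bf_knn <- function(train_x, train_labels, query, k) {
  train_x <- as.matrix(train_x)
  d <- sqrt(colSums((t(train_x) - query)^2))
  ord <- order(d, seq_along(d))
  nb <- as.character(train_labels)[ord[1:k]]
  tl <- sort(table(nb), decreasing = TRUE)
  if (length(tl) > 1 && tl[1] == tl[2]) {
    as.character(train_labels)[ord[1]]
  } else {
    names(tl)[1]
  }
}

# brute-force block-grid enumeration: walks candidate positions in mm and
# checks coverage directly against the mask
bf_block_count <- function(frame, mask, block_mm = 2, overlap = 0.8,
                           min_cov = 0.9) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) return(0L)
  mm_s <- rf_mm_per_sample(frame)
  mm_l <- 1e3 * frame$line_pitch
  nbs <- max(2L, round(block_mm / mm_s))
  nbl <- max(2L, round(block_mm / mm_l))
  ext_ax <- (max(cols) - min(cols) + 1) * mm_s
  ext_la <- (max(rows) - min(rows) + 1) * mm_l
  if (ext_ax < block_mm - 1e-9 || ext_la < block_mm - 1e-9) return(0L)
  stride <- (1 - overlap) * block_mm
  count <- 0L
  la <- 0
  while (la <= ext_la - block_mm + 1e-9) {
    ax <- 0
    r0 <- min(rows) + round(la / mm_l)
    while (ax <= ext_ax - block_mm + 1e-9) {
      c0 <- min(cols) + round(ax / mm_s)
      ri <- r0:(r0 + nbl - 1)
      ci <- c0:(c0 + nbs - 1)
      if (max(ri) <= nrow(mask) && max(ci) <= ncol(mask) &&
          mean(mask[ri, ci]) + 1e-12 >= min_cov) {
        count <- count + 1L
      }
      ax <- ax + stride
    }
    la <- la + stride
  }
  count
}

# direct O-E log-rank computation over event times (1-df, with ties)
bf_logrank <- function(time, event, group) {
  group <- as.character(group)
  gl <- sort(unique(group))
  stopifnot(length(gl) == 2)
  times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == gl[1])
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == gl[1])
    if (n < 2) next
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(list(chisq = 0, p = 1))
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# synthetic two-class feature table with a planted informative pair: a
# shared nuisance component g makes each planted feature weak alone but
# the (f1, f2) pair jointly separable, so a correct subset search must
# select both
planted_feature_table <- function(n_per_class = 16, n_noise = 5,
                                  effect = 1.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("responder", "non-responder"), each = n_per_class)
  d <- ifelse(labels == "responder", effect, -effect)
  g <- rnorm(n, 0, 2)
  x <- data.frame(f1 = d + g + rnorm(n, 0, 0.4),
                  f2 = d - g + rnorm(n, 0, 0.4))
  for (j in seq_len(n_noise)) x[[paste0("noise", j)]] <- rnorm(n)
  list(x = x, labels = labels)
}
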