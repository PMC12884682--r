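# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Exhaustive two-tailed sign-flip p-value by enumerating all 2^n sign
# assignments with expand.grid (n small).
perm_p_oracle <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  sums <- abs(signs %*% d)
  obs <- abs(sum(d))
  mean(sums >= obs - 1e-12 * (obs + sum(abs(d))))
}

# Frame-by-frame supra-threshold count.
event_rate_oracle <- function(trace, frames, frame_rate = 20, threshold = 0) {
  count <- 0
  for (f in frames) if (trace[f] > threshold) count <- count + 1
  count / (length(frames) / frame_rate)
}

# 2x2 Pearson chi-square closed form N(ad - bc)^2 / (r1 r2 c1 c2).
chisq_2x2_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Nearest-preceding-frame scan for time -> frame mapping.
frame_oracle <- function(t_img, frame_times) {
  idx <- rep(NA_integer_, length(t_img))
  for (i in seq_along(t_img)) {
    prec <- which(frame_times <= t_img[i] + 1e-9)
    if (length(prec)) idx[i] <- max(prec) - 1L  # 0-based
  }
  idx
}
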