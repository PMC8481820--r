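# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions so callers (and the pipeline driver) can react per class.
pleio_error <- function(msg, class) {
  stop(structure(
    class = c(class, "pleioscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_config <- function(msg) pleio_error(msg, "pleioscan_config_error")
abort_input <- function(msg) pleio_error(msg, "pleioscan_input_error")
abort_estimation <- function(msg) pleio_error(msg, "pleioscan_estimation_error")

#' Two-sided normal p-value for a Z statistic
#' @param z numeric vector of Z scores.
#' @return numeric vector of two-sided tail probabilities.
#' @keywords internal
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

BASES <- c("A", "C", "G", "T")

complement_allele <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(a1, a2) complement_allele(a1) == a2

# Deterministic per-stage substream of a single user seed: adding stages never
# perturbs the draws of earlier ones. Kept below 2^31 (R integer range).
substream_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483 # keep products < 2^53
  s <- abs(as.numeric(seed)) %% 2147483629
  as.integer((s * 69069 + h * 1000 + 1) %% 2147483629)
}

# Weighted least squares of y on (1, x): returns c(intercept, slope).
# Solved from the 2x2 normal equations; used by the LD-score regressions.
wls_coef <- function(sw, swx, swxx, swy, swxy) {
  det <- sw * swxx - swx * swx
  if (abs(det) < .Machine$double.eps * max(1, sw * swxx)) {
    abort_estimation("degenerate design: regressor is constant")
  }
  c(
    intercept = (swxx * swy - swx * swxy) / det,
    slope = (sw * swxy - swx * swy) / det
  )
}

# Per-jackknife-block sufficient statistics for WLS of y on (1, x).
wls_block_stats <- function(x, y, w, block_id) {
  list(
    sw = rowsum_vec(w, block_id),
    swx = rowsum_vec(w * x, block_id),
    swxx = rowsum_vec(w * x * x, block_id),
    swy = rowsum_vec(w * y, block_id),
    swxy = rowsum_vec(w * x * y, block_id)
  )
}

rowsum_vec <- function(v, g) {
  out <- rowsum(v, g, reorder = TRUE)
  stats::setNames(as.numeric(out), rownames(out))
}

# Delete-one-block jackknife SE of estimates theta_b (full-sample theta given).
jackknife_se <- function(theta_del) {
  b <- length(theta_del)
  m <- mean(theta_del)
  sqrt((b - 1) / b * sum((theta_del - m)^2))
}

# Contiguous jackknife block assignment for records already in genomic order.
contiguous_blocks <- function(n, n_blocks) {
  if (n < n_blocks) abort_config("fewer SNPs than jackknife blocks")
  as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}
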