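# Orthogonal periodized discrete wavelet transform with the sym8
# (Symlet-8, 16-tap) filter pair. Implemented in-package: the respiration
# separation needs only an analysis/zero-details/synthesis round trip, and
# the periodized pyramid below is exactly invertible (the synthesis step is
# the adjoint of the orthonormal analysis step).

SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609
)

SYM8_DEC_HI <- c(
  -0.0018899503327594609, -0.0003029205147213668, 0.01495225833704823,
  0.003808752013890615, -0.049137179673607506, -0.027219029917056003,
  0.05194583810770904, 0.3644418948353314, -0.7771857517005235,
  0.4813596512583722, 0.061273359067658524, -0.1432942383508097,
  -0.007607487324917605, 0.03169508781149298, 0.0005421323317911481,
  -0.0033824159510061256
)

# one analysis level over a periodized even-length signal
dwt_step <- function(x) {
  n <- length(x)
  half <- n / 2
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_along(SYM8_DEC_LO)) {
    idx <- (base + (m - 1)) %% n + 1
    a <- a + SYM8_DEC_LO[m] * x[idx]
    d <- d + SYM8_DEC_HI[m] * x[idx]
  }
  list(a = a, d = d)
}

# adjoint of dwt_step; exact inverse for the orthonormal pair
idwt_step <- function(a, d) {
  half <- length(a)
  n <- 2 * half
  y <- numeric(n)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_along(SYM8_DEC_LO)) {
    idx <- (base + (m - 1)) %% n + 1
    y[idx] <- y[idx] + SYM8_DEC_LO[m] * a + SYM8_DEC_HI[m] * d
  }
  y
}

# multi-level decomposition; input length must be divisible by 2^levels
dwt_sym8 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details)
}

idwt_sym8 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]])
  }
  a
}

#' Extract the respiratory waveform
#'
#' Subtracts the detected BCG component from the recording and isolates the
#' respiratory band with an 8-level discrete wavelet decomposition on the
#' sym8 basis: the residual is decomposed, and only the level-8
#' approximation plus those detail levels whose dyadic frequency band
#' overlaps the respiratory band (0.1–0.5 Hz) are reconstructed. The signal
#' is reflection-padded to a multiple of 2^8 before the periodized
#' transform and trimmed afterwards, so output length equals input length.
#'
#' @param rec The recording the BCG was extracted from (same length/rate).
#' @param bcg Output of [extract_bcg()] on `rec`.
#' @param levels Decomposition depth (8).
#' @param resp_band Respiratory frequency band retained, Hz.
#' @return A recording tibble holding the respiratory waveform.
#' @export
extract_respiration <- function(rec, bcg, levels = 8, resp_band = c(0.1, 0.5)) {
  rec <- as_recording(rec)
  bcg <- as_recording(bcg)
  if (nrow(rec) != nrow(bcg)) {
    rlang::abort("`rec` and `bcg` must have the same length")
  }
  fs <- sample_rate(rec)
  x <- rec$amplitude - bcg$amplitude

  n <- length(x)
  block <- 2^levels
  pad <- (block - n %% block) %% block
  if (pad > 0) {
    # reflect the tail so the periodized wrap does not splice a step edge
    tail_ref <- rev(x)[seq_len(min(pad, n))]
    if (length(tail_ref) < pad) tail_ref <- rep_len(tail_ref, pad)
    x <- c(x, tail_ref)
  }

  decomp <- dwt_sym8(x, levels)
  for (j in seq_len(levels)) {
    # detail level j spans [fs/2^(j+1), fs/2^j]
    band <- c(fs / 2^(j + 1), fs / 2^j)
    keep <- band[1] < resp_band[2] && band[2] > resp_band[1]
    if (!keep) decomp$details[[j]] <- numeric(length(decomp$details[[j]])) # zero out
  }
  y <- idwt_sym8(decomp)[seq_len(n)]
  with_amplitude(rec, y)
}
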