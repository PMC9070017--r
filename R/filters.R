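# Zero-phase IIR filtering as cascaded second-order sections.
#
# High-order Butterworth filters are designed here directly in zero-pole
# form and applied biquad-by-biquad: expanding an order-8 band edge near
# 1 Hz (normalized 0.007) into a single transfer function is numerically
# fragile, while each conjugate pole pair is well conditioned.

# analog Butterworth prototype poles, order n (left half-plane, |p| = 1)
butter_proto <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# second-order sections for a digital Butterworth low/high-pass.
# Returns a list of c(b0,b1,b2,a0,a1,a2), each section normalized to unit
# gain at DC (lowpass) or Nyquist (highpass).
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2 != 0) stop("`order` must be even")
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  wc <- 2 * fs * tan(pi * fc / fs)       # prewarped analog cutoff (rad/s)
  p <- butter_proto(order)
  s <- if (type == "low") wc * p else wc / p
  zpole <- (2 * fs + s) / (2 * fs - s)   # bilinear transform
  zzero <- if (type == "low") -1 else 1
  # pair conjugates: poles come in conjugate pairs for even order
  ord <- order(Re(zpole), Im(zpole))
  zpole <- zpole[ord]
  pairs <- vector("list", order / 2)
  used <- rep(FALSE, order)
  j <- 0
  for (i in seq_len(order)) {
    if (used[i]) next
    conj_i <- which(!used & abs(zpole - Conj(zpole[i])) < 1e-9)
    conj_i <- conj_i[conj_i != i][1]
    if (is.na(conj_i)) conj_i <- which(!used)[which(!used) != i][1]
    used[c(i, conj_i)] <- TRUE
    j <- j + 1
    pairs[[j]] <- c(zpole[i], zpole[conj_i])
  }
  eval_at <- if (type == "low") 1 + 0i else -1 + 0i   # z where gain must be 1
  lapply(pairs, function(pp) {
    a <- Re(c(1, -(pp[1] + pp[2]), pp[1] * pp[2]))
    b <- c(1, -2 * zzero, 1)
    g <- abs(sum(a * eval_at^(0:-2)) / sum(b * eval_at^(0:-2)))
    c(b = b * g, a = a)
  })
}

# forward-backward filtering through a cascade of biquads
sos_filtfilt <- function(sos, x) {
  for (sec in sos)
    x <- signal::filtfilt(sec[1:3], sec[4:6], x)
  x
}

# RBJ second-order notch, quality factor q
notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(c(b / a[1], a / a[1]))
}
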