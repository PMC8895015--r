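# Internal grid and FFT helpers.
#
# Grid convention used throughout: the zero-frequency pixel of a shifted
# (display-order) array sits at 1-based index floor(N/2)+1 on each axis,
# i.e. index N/2 in 0-based terms for even N. Real-space images use the
# same centre for point inversion (Friedel twinning).

centre_index <- function(n) floor(n / 2L) + 1L

# source indices such that out[i] == in[i - k] (circular)
.roll_index <- function(n, k) ((seq_len(n) - 1L - k) %% n) + 1L

circshift2 <- function(x, s) {
  x[.roll_index(nrow(x), s[1L]), .roll_index(ncol(x), s[2L]), drop = FALSE]
}

fftshift2 <- function(x) circshift2(x, c(floor(nrow(x) / 2L), floor(ncol(x) / 2L)))

ifftshift2 <- function(x) circshift2(x, c(-floor(nrow(x) / 2L), -floor(ncol(x) / 2L)))

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# index map sending pixel f to its Friedel partner -f (shifted arrays)
conj_partner_index <- function(n) {
  ((2L * centre_index(n) - seq_len(n) - 1L) %% n) + 1L
}

# point inversion about the centre pixel; its own inverse
point_invert <- function(x) {
  x[conj_partner_index(nrow(x)), conj_partner_index(ncol(x)), drop = FALSE]
}

# distance (pixels) of every pixel from the centre pixel, shifted order
freq_radius <- function(shape) {
  dr <- seq_len(shape[1L]) - centre_index(shape[1L])
  dc <- seq_len(shape[2L]) - centre_index(shape[2L])
  sqrt(outer(dr^2, dc^2, `+`))
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if
      (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# integer circular shift s maximising sum(ref * circshift2(img, s)),
# found in closed form via the cross-correlation theorem
best_shift <- function(ref, img) {
  cc <- Re(stats::fft(Conj(stats::fft(ref)) * stats::fft(img), inverse = TRUE))
  k <- arrayInd(which.max(cc), dim(cc))
  list(shift = -(as.integer(k) - 1L), score = max(cc))
}

# block-average pooling onto a g x g grid
pool_average <- function(x, g) {
  ri <- as.integer(cut(seq_len(nrow(x)), g, labels = FALSE))
  ci <- as.integer(cut(seq_len(ncol(x)), g, labels = FALSE))
  s <- rowsum(t(rowsum(x, ri)), ci)          # g x g of sums (transposed)
  n <- tabulate(ri, g) %o% tabulate(ci, g)
  out <- t(s) / n
  dimnames(out) <- NULL
  out
}

is_square_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_sk <- function(...) stop(..., call. = FALSE)
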