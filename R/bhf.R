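# Binary histogram Fourier (BHF) texture operator.
#
# Concretized as the rotation-invariant local-binary-pattern histogram
# Fourier construction: (1) P-bit binary codes compare each circular
# neighbor (radius R, bilinear interpolation) against the center, ties
# (neighbor == center) counting as 1; (2) the normalized histogram of
# uniform patterns (<= 2 circular 0/1 transitions) grouped by (ones-count n,
# rotation index r), plus three special bins for all-zeros, all-ones and
# non-uniform codes; (3) a DFT along the rotation index of each ones-count
# row, keeping the magnitudes of frequencies 0..floor(P/2). Rotating the
# image circularly shifts each row, so the magnitudes are rotation
# invariant while the raw (n, r) histogram is not.

# classify every P-bit code once: type 0 all-zeros, 1 all-ones, 2 uniform
# (with ones-count n and rotation index r = start of the circular 1-run),
# 3 non-uniform
bhf_code_table <- function(P) {
  codes <- 0:(2^P - 1)
  bits <- t(vapply(codes, function(cd) as.integer(intToBits(cd))[1:P],
                   integer(P)))
  n <- rowSums(bits)
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  type <- integer(length(codes))
  r <- rep(NA_integer_, length(codes))
  type[n == 0] <- 0L
  type[n == P] <- 1L
  uni <- n > 0 & n < P & trans <= 2
  type[uni] <- 2L
  type[n > 0 & n < P & trans > 2] <- 3L
  prev <- bits[, c(P, 1:(P - 1)), drop = FALSE]
  for (i in which(uni)) r[i] <- which(bits[i, ] == 1 & prev[i, ] == 0) - 1L
  list(type = type, n = n, r = r)
}

# shift a numeric matrix by (dr, dc), padding NA
shift_num <- function(m, dr, dc) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) + dr
  cs <- seq_len(ncol(m)) + dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Compute the BHF texture vector of a masked region
#'
#' @param gray H x W gray-level matrix.
#' @param mask logical H x W region mask; only pixels whose whole sampled
#'   neighborhood lies inside the mask contribute (the mask is effectively
#'   eroded by the neighborhood support).
#' @param P number of circular neighbors (default 8).
#' @param R neighborhood radius in pixels (default 1).
#' @return list with `vector` (named numeric: `(P-1) * (floor(P/2)+1)`
#'   Fourier magnitudes `bhf_n{n}_f{u}`, then `bhf_all_zeros`,
#'   `bhf_all_ones`, `bhf_nonuniform`), `uniform_hist` (the pre-DFT
#'   `(P-1) x P` normalized histogram of uniform patterns), the three
#'   special-bin proportions, and `n_valid`.
#' @export
compute_bhf <- function(gray, mask, P = 8, R = 1) {
  stopifnot(P >= 4, R > 0, all(dim(gray) == dim(mask)))
  H <- nrow(gray); W <- ncol(gray)
  ang <- 2 * pi * (0:(P - 1)) / P
  dr <- -R * sin(ang)
  dc <- R * cos(ang)
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  dr <- snap(dr); dc <- snap(dc)

  code <- matrix(0, H, W)
  valid <- mask
  for (p in seq_len(P)) {
    fr <- floor(dr[p]); fc <- floor(dc[p])
    wr <- dr[p] - fr;   wc <- dc[p] - fc
    wts <- c((1 - wr) * (1 - wc), (1 - wr) * wc, wr * (1 - wc), wr * wc)
    offs <- list(c(fr, fc), c(fr, fc + 1), c(fr + 1, fc), c(fr + 1, fc + 1))
    nb <- matrix(0, H, W)
    ok <- matrix(TRUE, H, W)
    for (k in 1:4) {
      if (wts[k] == 0) next
      nb <- nb + wts[k] * shift_num(gray, offs[[k]][1], offs[[k]][2])
      ok <- ok & shift_mask(mask, offs[[k]][1], offs[[k]][2])
    }
    nb[is.na(nb)] <- -Inf
    code <- code + (nb >= gray) * 2^(p - 1) # tie counts as 1
    valid <- valid & ok
  }

  idx <- which(valid)
  if (!length(idx))
    stop("mask too small: no pixel has its full BHF neighborhood inside the mask")
  lut <- bhf_code_table(P)
  cd <- code[idx] + 1L
  n_valid <- length(idx)

  type <- lut$type[cd]
  hist_u <- matrix(0, P - 1, P,
                   dimnames = list(paste0("n", 1:(P - 1)), paste0("r", 0:(P - 1))))
  u_idx <- which(type == 2L)
  if (length(u_idx)) {
    tab <- table(factor(lut$n[cd[u_idx]], levels = 1:(P - 1)),
                 factor(lut$r[cd[u_idx]], levels = 0:(P - 1)))
    hist_u <- hist_u + unclass(tab) / n_valid
  }
  bin_all_zeros <- sum(type == 0L) / n_valid
  bin_all_ones <- sum(type == 1L) / n_valid
  bin_nonuniform <- sum(type == 3L) / n_valid

  nf <- floor(P / 2) + 1
  mags <- t(apply(hist_u, 1, function(row) Mod(stats::fft(row))[seq_len(nf)]))
  vec <- as.vector(t(mags))
  names(vec) <- as.vector(t(outer(1:(P - 1), 0:(nf - 1),
                                  function(n, u) sprintf("bhf_n%d_f%d", n, u))))
  vec <- c(vec, bhf_all_zeros = bin_all_zeros, bhf_all_ones = bin_all_ones,
           bhf_nonuniform = bin_nonuniform)

  list(vector = vec, uniform_hist = hist_u,
       bin_all_zeros = bin_all_zeros, bin_all_ones = bin_all_ones,
       bin_nonuniform = bin_nonuniform, n_valid = n_valid)
}
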