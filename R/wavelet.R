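# Separable 3-D orthonormal Haar wavelet transform used by the
# structural-functional resolution-recovery correction. Exactly invertible;
# volumes are zero-padded to dyadic-compatible sizes and cropped afterwards.

haar_split <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(x, perm)
  dim(m) <- c(n, prod(d[perm][-1]))
  o <- m[seq(1, n, 2), , drop = FALSE]
  e <- m[seq(2, n, 2), , drop = FALSE]
  lo <- (o + e) / sqrt(2)
  hi <- (o - e) / sqrt(2)
  reshape <- function(y) {
    dim(y) <- c(n / 2L, d[perm][-1])
    aperm(y, order(perm))
  }
  list(lo = reshape(lo), hi = reshape(hi))
}

haar_merge <- function(lo, hi, axis) {
  d <- dim(lo)
  n <- d[axis] * 2L
  perm <- c(axis, setdiff(1:3, axis))
  ml <- aperm(lo, perm); dim(ml) <- c(n / 2L, prod(d[perm][-1]))
  mh <- aperm(hi, perm); dim(mh) <- c(n / 2L, prod(d[perm][-1]))
  m <- matrix(0, n, ncol(ml))
  m[seq(1, n, 2), ] <- (ml + mh) / sqrt(2)
  m[seq(2, n, 2), ] <- (ml - mh) / sqrt(2)
  d2 <- d; d2[axis] <- n
  dim(m) <- d2[perm]
  aperm(m, order(perm))
}

dwt_step <- function(x) {
  bands <- list(x)
  bnames <- ""
  for (ax in 1:3) {
    nxt <- vector("list", 2L * length(bands))
    nnames <- character(2L * length(bands))
    for (i in seq_along(bands)) {
      sp <- haar_split(bands[[i]], ax)
      nxt[[2L * i - 1L]] <- sp$lo
      nxt[[2L * i]] <- sp$hi
      nnames[2L * i - 1L] <- paste0(bnames[i], "L")
      nnames[2L * i] <- paste0(bnames[i], "H")
    }
    bands <- nxt
    bnames <- nnames
  }
  names(bands) <- bnames
  bands
}

idwt_step <- function(bands) {
  for (ax in 3:1) {
    prefixes <- unique(substring(names(bands), 1, ax - 1))
    nxt <- vector("list", length(prefixes))
    names(nxt) <- prefixes
    for (i in seq_along(prefixes)) {
      nxt[[i]] <- haar_merge(bands[[paste0(prefixes[i], "L")]],
                             bands[[paste0(prefixes[i], "H")]], ax)
    }
    bands <- nxt
  }
  bands[[1]]
}

dwt3 <- function(x, levels) {
  details <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    if (any(dim(cur) %% 2L != 0L))
      stop("dwt3: dimensions (", paste(dim(cur), collapse = ","),
           ") not divisible by 2 at level ", l)
    bands <- dwt_step(cur)
    cur <- bands[["LLL"]]
    details[[l]] <- bands[names(bands) != "LLL"]
  }
  list(approx = cur, details = details)
}

idwt3 <- function(w) {
  cur <- w$approx
  for (l in rev(seq_along(w$details))) {
    bands <- w$details[[l]]
    bands[["LLL"]] <- cur
    cur <- idwt_step(bands)
  }
  cur
}

pad_dyadic <- function(x, levels) {
  d <- dim(x)
  unit <- 2L^levels
  d2 <- as.integer(ceiling(d / unit) * unit)
  if (any(d2 < unit))
    stop("wavelet decomposition: grid too small for ", levels, " levels")
  if (all(d2 == d)) return(list(x = x, orig = d))
  out <- array(0, d2)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  list(x = out, orig = d)
}

crop_to <- function(x, d) x[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                            drop = FALSE]

#' Wavelet blending configuration for SFS-RR
#'
#' @param n_levels Number of decomposition levels.
#' @param weighting_rule `"global_fraction"` blends every detail subband as
#'   `(1 - alpha) * functional + alpha * structural` with
#'   `alpha = structural_fraction`; `"per_subband_fit"` picks, per subband,
#'   the smallest alpha in `[0, 1]` for which the blended subband's energy
#'   matches the structural subband's energy (falling back to
#'   `structural_fraction` when no such root exists).
#' @param structural_fraction Global fraction of structural detail
#'   information, default 0.34.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(n_levels = 4L,
                           weighting_rule = c("global_fraction",
                                              "per_subband_fit"),
                           structural_fraction = 0.34) {
  weighting_rule <- match.arg(weighting_rule)
  if (n_levels < 1L) stop("wavelet_config: n_levels must be >= 1")
  if (structural_fraction < 0 || structural_fraction > 1)
    stop("wavelet_config: structural_fraction must be in [0, 1]")
  structure(list(n_levels = as.integer(n_levels),
                 weighting_rule = weighting_rule,
                 structural_fraction = structural_fraction),
            class = "wavelet_config")
}

blend_alpha <- function(df, ds, wcfg) {
  if (wcfg$weighting_rule == "global_fraction")
    return(wcfg$structural_fraction)
  FF <- sum(df * df); SS <- sum(ds * ds); CC <- sum(df * ds)
  a <- FF - 2 * CC + SS
  if (a <= .Machine$double.eps * (FF + SS))
    return(wcfg$structural_fraction)
  # energy-matching quadratic has alpha = 1 as one root; take the other
  alpha <- (FF - SS) / a
  if (!is.finite(alpha)) return(wcfg$structural_fraction)
  min(max(alpha, 0), 1)
}
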