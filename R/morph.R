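# Binary morphology on 3-D logical arrays with a 6-connected structuring
# element, implemented with index shifts (out-of-field treated as FALSE).

shift_mask <- function(mask, axis, by) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- function(a, i) {
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[a]] <- i
    idx
  }
  out <- do.call(`[<-`, c(list(out), ix(axis, dst),
                          list(do.call(`[`, c(list(mask), ix(axis, src))))))
  out
}

neighbor_union <- function(mask) {
  out <- mask
  for (a in 1:3) for (s in c(-1L, 1L)) out <- out | shift_mask(mask, a, s)
  out
}

morph_dilate <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- neighbor_union(mask)
  mask
}

morph_erode <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- !neighbor_union(!mask)
  mask
}
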