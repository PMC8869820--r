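#' Two-dimensional phase unwrapping
#'
#' Removes 2-pi ambiguities from a wrapped phase map by quality-guided
#' flood fill: unwrapping starts at the pixel with the most consistent
#' local wrapped gradients and grows outwards, always extending the region
#' at the highest-quality boundary pixel.  The output equals the input
#' modulo 2-pi at every pixel; in residue-free regions neighbouring output
#' values differ by less than pi.
#'
#' Maps whose raw neighbour differences never exceed pi carry no wrap
#' information and are returned unchanged, which also makes the operation
#' idempotent.
#'
#' @param wrapped Numeric matrix of wrapped phase values (radians).
#'
#' @return Numeric matrix of unwrapped phase, same shape as the input.
#' @examples
#' ramp <- matrix(seq(0, 6 * pi, length.out = 64), 64, 64, byrow = TRUE)
#' wrapped <- atan2(sin(ramp), cos(ramp))
#' unwrapped <- unwrap_phase(wrapped)
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped), is.numeric(wrapped))
  nr <- nrow(wrapped)
  nc <- ncol(wrapped)
  if (nr < 2 || nc < 2) return(wrapped)

  # Fast path: no neighbour jump exceeds pi, so there is nothing to unwrap.
  if (max(abs(diff(wrapped))) <= pi && max(abs(t(diff(t(wrapped))))) <= pi) {
    return(wrapped)
  }

  # Quality: negative sum of absolute wrapped gradients to the 4-neighbours.
  gx <- wrap_to_pi(cbind(wrapped[, -1] - wrapped[, -nc], 0)) # to right neighbour
  gy <- wrap_to_pi(rbind(wrapped[-1, ] - wrapped[-nr, ], 0)) # to bottom neighbour
  qual <- -(abs(gx) + abs(gy) +
              abs(cbind(0, gx[, -nc])) + abs(rbind(0, gy[-nr, ])))

  n <- nr * nc
  out <- wrapped
  done <- logical(n)

  # Binary max-heap over candidate pixels, keyed by quality; each entry
  # remembers the already-unwrapped neighbour it connects to.
  heap_px <- integer(n * 4L)
  heap_ref <- integer(n * 4L)
  heap_key <- numeric(n * 4L)
  heap_n <- 0L

  push <- function(px, ref) {
    heap_n <<- heap_n + 1L
    i <- heap_n
    heap_px[i] <<- px; heap_ref[i] <<- ref; heap_key[i] <<- qual[px]
    while (i > 1L) {
      p <- i %/% 2L
      if (heap_key[p] >= heap_key[i]) break
      swap(i, p); i <- p
    }
  }
  swap <- function(i, j) {
    tmp <- heap_px[i]; heap_px[i] <<- heap_px[j]; heap_px[j] <<- tmp
    tmp <- heap_ref[i]; heap_ref[i] <<- heap_ref[j]; heap_ref[j] <<- tmp
    tmpk <- heap_key[i]; heap_key[i] <<- heap_key[j]; heap_key[j] <<- tmpk
  }
  pop <- function() {
    top <- c(heap_px[1L], heap_ref[1L])
    heap_px[1L] <<- heap_px[heap_n]; heap_ref[1L] <<- heap_ref[heap_n]
    heap_key[1L] <<- heap_key[heap_n]
    heap_n <<- heap_n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      big <- i
      if (l <= heap_n && heap_key[l] > heap_key[big]) big <- l
      if (r <= heap_n && heap_key[r] > heap_key[big]) big <- r
      if (big == i) break
      swap(i, big); i <- big
    }
    top
  }

  neighbours <- function(px) {
    r <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, px - 1L)
    if (r < nr) out <- c(out, px + 1L)
    if (cc > 1L) out <- c(out, px - nr)
    if (cc < nc) out <- c(out, px + nr)
    out
  }

  start <- which.max(qual)
  done[start] <- TRUE
  for (nb in neighbours(start)) push(nb, start)

  while (heap_n > 0L) {
    top <- pop()
    px <- top[1]
    if (done[px]) next
    ref <- top[2]
    out[px] <- wrapped[px] + 2 * pi * round((out[ref] - wrapped[px]) / (2 * pi))
    done[px] <- TRUE
    for (nb in neighbours(px)) if (!done[nb]) push(nb, px)
  }
  out
}

wrap_to_pi <- function(x) {
  (x + pi) %% (2 * pi) - pi
}
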