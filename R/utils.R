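# Vectorized rolling primitives used by trigger evaluation. All operate on
# uniform 1-per-sample grids; NA marks missing data throughout.

# Rolling minimum over the trailing window [i - width + 1, i] (in samples,
# current sample included). NA values are ignored; a window with no finite
# value yields NA. O(n) block prefix/suffix algorithm.
.rollMinRight <- function(x, width) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  xx <- x
  xx[is.na(xx)] <- Inf
  if (width >= n) {
    out <- cummin(xx)
  } else {
    pad <- (-n) %% width
    xp <- c(xx, rep(Inf, pad))
    m <- matrix(xp, nrow = width)
    pref <- as.vector(apply(m, 2, cummin))
    suf <- as.vector(apply(m[width:1, , drop = FALSE], 2, cummin)[width:1, ,
                                                                  drop = FALSE])
    i <- seq_len(n)
    j <- i - width + 1L
    out <- numeric(n)
    full <- j >= 1L
    out[full] <- pmin(suf[j[full]], pref[i[full]])
    out[!full] <- cummin(xx)[i[!full]]
  }
  out[!is.finite(out)] <- NA_real_
  out
}

.rollMaxRight <- function(x, width) -.rollMinRight(-x, width)

# Extreme over the strictly-previous window [i - width, i - 1].
.rollExtremePrev <- function(x, width, max = FALSE) {
  r <- if (max) .rollMaxRight(x, width) else .rollMinRight(x, width)
  c(NA_real_, r[-length(r)])
}

# Right-aligned rolling median over [i - halfwin, i] (halfwin + 1 samples),
# NA-aware, partial windows at the left edge. Fast path re-aligns the C-level
# centred stats::runmed; indices whose window touches an NA are recomputed
# directly.
.rollMedianRight <- function(x, halfwin) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  halfwin <- as.integer(halfwin)
  if (halfwin < 1L) return(x)
  width <- halfwin + 1L
  if (width %% 2L == 0L) width <- width + 1L      # runmed needs odd k
  half <- (width - 1L) %/% 2L
  out <- rep(NA_real_, n)
  nas <- is.na(x)
  xfill <- x
  xfill[nas] <- 0
  if (n >= width) {
    cen <- stats::runmed(xfill, width, endrule = "keep")
    idx <- width:n
    out[idx] <- cen[idx - half]
  }
  head_idx <- seq_len(min(width - 1L, n))
  for (i in head_idx) {
    w <- x[max(1L, i - halfwin):i]
    out[i] <- if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }
  if (any(nas)) {
    touched <- unique(unlist(lapply(which(nas), function(b)
      b:min(n, b + halfwin)), use.names = FALSE))
    touched <- touched[touched > width - 1L]
    for (i in touched) {
      w <- x[max(1L, i - halfwin):i]
      out[i] <- if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
    }
  }
  out
}

# Maximal runs of TRUE in a logical vector (NA treated as FALSE); returns a
# two-column matrix of first/last indices.
.trueRuns <- function(sat) {
  sat[is.na(sat)] <- FALSE
  r <- rle(sat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Deterministic per-patient seed from a master seed (counter-based, stable
# under changes in patient count; stays below 2^31).
.deriveSeed <- function(masterSeed, counter) {
  as.integer((as.numeric(masterSeed) * 48271 + as.numeric(counter) * 16807) %%
               2147483647)
}

.fmtValue <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.6g", x))
  out
}
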